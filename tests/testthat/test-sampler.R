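test_that("gene conditional update matches the conjugate closed form", {
  set.seed(5)
  n <- 12
  x <- rep(c(0L, 1L), each = n / 2)
  y <- rnorm(n, 2 + 0.8 * x, sd = 1.3)
  h <- 0.5; lam <- 0.7; tau <- 1.4
  prior <- prior_spec(h, epsilon = 0.3, xi1 = 3, xi2 = 2)
  oracle <- nig_oracle(y, x, h, 3, 2, s0sq = 100, lt2 = (lam * tau)^2)

  M <- 20000
  state <- list(c = 0, beta = 0, sigma2 = 1, lambda = lam)
  beta <- cc <- s2 <- numeric(M)
  set.seed(99)
  for (m in seq_len(M)) {
    state <- gene_conditional_update(y, x, h, state, tau, prior,
                                     update_lambda = FALSE)
    state$lambda <- lam  # hold the local scale fixed
    beta[m] <- state$beta; cc[m] <- state$c; s2[m] <- state$sigma2
  }
  # with lambda, tau fixed the beta draws are i.i.d. Student-t: compare
  # mean and variance within 3 Monte-Carlo SEs of the closed form
  se_mean <- sd(beta) / sqrt(M)
  expect_lt(abs(mean(beta) - oracle$beta_mean), 3 * se_mean)
  kurt <- mean((beta - mean(beta))^4) / var(beta)^2
  se_var <- var(beta) * sqrt((kurt - 1) / M)
  expect_lt(abs(var(beta) - oracle$beta_var), 3 * se_var)
  expect_lt(abs(mean(cc) - oracle$c_mean), 3 * sd(cc) / sqrt(M))
  expect_lt(abs(mean(s2) - oracle$s2_mean), 3 * sd(s2) / sqrt(M))
})

test_that("beta draws concentrate at the prior center as lambda*tau -> 0", {
  set.seed(6)
  n <- 10
  x <- rep(c(0L, 1L), each = 5)
  y <- rnorm(n, 1 + 2 * x)
  prior <- prior_spec(h = -0.75, epsilon = 0.3, xi1 = 3, xi2 = 2)
  state <- list(c = 0, beta = 0, sigma2 = 1, lambda = 1e-7)
  b <- replicate(500, {
    state <<- gene_conditional_update(y, x, -0.75, state, tau = 1e-7, prior,
                                      update_lambda = FALSE)
    state$beta
  })
  expect_lt(max(abs(b - (-0.75))), 1e-4)
})

test_that("gene update rejects degenerate designs and non-finite data", {
  prior <- prior_spec(0, 0.3, 3, 2)
  st <- list(c = 0, beta = 0, sigma2 = 1, lambda = 1)
  expect_error(gene_conditional_update(c(1, 2, 3), c(1L, 1L, 1L), 0, st, 1,
                                       prior), "degenerate")
  expect_error(gene_conditional_update(c(1, NA, 3), c(0L, 1L, 1L), 0, st, 1,
                                       prior), "non-finite")
})

test_that("slice sampler is stationary for the half-Cauchy prior alone", {
  set.seed(11)
  M <- 30000
  x <- numeric(M); cur <- 1
  for (m in seq_len(M)) { cur <- slice_sample_scale(cur, function(z) 0); x[m] <- cur }
  expect_true(all(x > 0))
  # CDF F(q) = (2/pi) atan(q); compare at several quantiles
  for (q in c(0.3, 1, 3, 10))
    expect_equal(mean(x <= q), (2 / pi) * atan(q), tolerance = 0.02)
  expect_equal(median(x), 1, tolerance = 0.05)
})

test_that("slice sampler follows a dominating likelihood", {
  set.seed(12)
  cur <- 1
  for (m in 1:200) cur <- slice_sample_scale(cur, function(z) -1e6 * (z - 2)^2)
  expect_equal(cur, 2, tolerance = 1e-2)
})

test_that("slice sampler matches quadrature for a Gaussian scale term", {
  # single N(beta; h, sigma^2 x^2 tau^2) likelihood term with
  # (beta - h) = 1 and sigma * tau = 1
  loglik <- function(z) -log(z) - 1 / (2 * z^2)
  target_mean <- hc_target_mean(loglik)
  set.seed(13)
  M <- 30000
  x <- numeric(M); cur <- 1
  for (m in seq_len(M)) { cur <- slice_sample_scale(cur, loglik); x[m] <- cur }
  expect_equal(mean(x), target_mean, tolerance = 0.05 * target_mean)
  expect_error(slice_sample_scale(1, function(z) NaN), "NaN")
})

test_that("global tau transition matches quadrature and honors tau_fixed", {
  G <- 200
  beta <- rep(1, G); h <- rep(0, G); sigma2 <- rep(1, G); lambda <- rep(1, G)
  # target: (1+tau^2)^-1 tau^-G exp(-G/(2 tau^2))
  loglik <- function(z) -(G - 1) * log(z) - G / (2 * z^2)
  target_mean <- hc_target_mean(loglik)
  set.seed(14)
  M <- 5000
  x <- numeric(M); cur <- 1
  for (m in seq_len(M)) { cur <- sample_tau(beta, h, sigma2, lambda, cur); x[m] <- cur }
  expect_equal(mean(x), target_mean, tolerance = 0.02 * target_mean)
  # fixed tau passes through unchanged; empty gene set errors
  expect_identical(sample_tau(beta, h, sigma2, lambda, 1, tau_fixed = 0.37),
                   0.37)
  expect_error(sample_tau(numeric(0), numeric(0), numeric(0), numeric(0), 1),
               "empty")
  # boundary: a single on-center gene is guarded by the scale floor
  set.seed(15)
  tt <- replicate(200, sample_tau(0, 0, 1, 1, 1))
  expect_true(all(tt >= 1e-6))
})

test_that("run_mcmc is deterministic given the seed and keeps scales positive", {
  sim <- generate_dataset(G = 30, n_per_group = 6, p = 0.3, seed = 21)
  xi <- fit_variance_hyperparams(sim$data)
  prior <- prior_spec(sim$truth$h, log2(1.5), xi["xi1"], xi["xi2"])
  st <- mcmc_settings(600, 200, 2, seed = 77)
  d1 <- run_mcmc(sim$data, prior, st)
  d2 <- run_mcmc(sim$data, prior, st)
  expect_identical(d1$beta, d2$beta)
  expect_identical(d1$tau, d2$tau)
  expect_equal(ncol(d1$beta), 200)
  expect_true(all(d1$sigma2 > 0) && all(d1$lambda > 0) && all(d1$tau > 0))
})

test_that("posterior mean approaches the MLE under a weak prior", {
  # huge fixed global scale: the shrinkage prior is effectively flat, so
  # the posterior mean of beta must sit on the difference of group means
  sim <- generate_dataset(G = 40, n_per_group = 25, p = 0.5, seed = 31)
  xi <- fit_variance_hyperparams(sim$data)
  prior <- prior_spec(sim$truth$h, log2(1.5), xi["xi1"], xi["xi2"])
  st <- mcmc_settings(3000, 1000, 2, seed = 32, tau_fixed = 1e3)
  dr <- run_mcmc(sim$data, prior, st)
  Y <- sim$data$values; x <- sim$data$group
  mle <- rowMeans(Y[, x == 1]) - rowMeans(Y[, x == 0])
  pm <- rowMeans(dr$beta)
  mcse <- apply(dr$beta, 1, sd) / sqrt(ncol(dr$beta) / 5)  # conservative ESS
  expect_true(all(abs(pm - mle) < pmax(3 * mcse, 0.02)))
})

test_that("credible intervals achieve nominal coverage on model-generated data", {
  # data generated exactly from the hierarchical model (tau fixed at 1),
  # so 95% central intervals must cover the true effects at 95% on average
  set.seed(41)
  G <- 200; n_per <- 25
  xi1 <- 6; xi2 <- 10
  h <- rnorm(G, 0, 1)
  sigma2 <- 1 / rgamma(G, xi1, rate = xi2)
  lambda <- abs(rcauchy(G))
  beta <- rnorm(G, h, sqrt(sigma2) * lambda)
  cg <- rnorm(G, 0, 10 * sqrt(sigma2))
  x <- rep(c(0L, 1L), each = n_per)
  Y <- matrix(rnorm(G * 2 * n_per, sd = rep(sqrt(sigma2), 2 * n_per)),
              G, 2 * n_per) + cg + outer(beta, x)
  d <- expression_dataset(Y, x)
  prior <- prior_spec(h, log2(1.5), xi1, xi2)
  dr <- run_mcmc(d, prior, mcmc_settings(2000, 1000, 1, seed = 42,
                                         tau_fixed = 1))
  ci <- apply(dr$beta, 1, quantile, probs = c(0.025, 0.975))
  cover <- mean(beta >= ci[1, ] & beta <= ci[2, ])
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / G))
})

test_that("local scales grow with the prior-data discrepancy", {
  # genes whose prior center disagrees with the data must learn a larger
  # local scale (shrinkage fades as |mle - h| grows)
  set.seed(51)
  G <- 150; n_per <- 15
  x <- rep(c(0L, 1L), each = n_per)
  beta <- rep(0, G)
  h <- seq(0, 3, length.out = G)  # increasing discrepancy
  Y <- matrix(rnorm(G * 2 * n_per, 4, 1), G) + outer(beta, x)
  d <- expression_dataset(Y, x)
  xi <- fit_variance_hyperparams(d)
  prior <- prior_spec(h, log2(1.5), xi["xi1"], xi["xi2"])
  dr <- run_mcmc(d, prior, mcmc_settings(2000, 1000, 2, seed = 52))
  mle <- rowMeans(Y[, x == 1]) - rowMeans(Y[, x == 0])
  disc <- abs(mle - h)
  lam_pm <- rowMeans(dr$lambda)
  bins <- cut(disc, breaks = quantile(disc, seq(0, 1, 0.1)),
              include.lowest = TRUE)
  lam_bin <- tapply(lam_pm, bins, mean)
  disc_bin <- tapply(disc, bins, mean)
  expect_gt(cor(disc_bin, lam_bin, method = "spearman"), 0)
})
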