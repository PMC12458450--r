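# simulate from the two-component model: logistic detection, normal nonzero
# expression (any exact zero among detected cells is nudged off zero so the
# dropout mask stays Z = I(Y != 0))
simulate_sc <- function(G, cells_per_group, betaD, betaC, cD = 0.5, cC = 4,
                        sigma = 1, seed = 1) {
  set.seed(seed)
  n <- 2L * cells_per_group
  x <- rep(c(0L, 1L), each = cells_per_group)
  Y <- matrix(0, G, n)
  for (g in seq_len(G)) {
    eta <- cD + betaD[g] * x
    z <- rbinom(n, 1, plogis(eta))
    y <- rnorm(n, cC + betaC[g] * x, sigma)
    y[y == 0] <- 1e-9
    Y[g, ] <- z * y
  }
  sc_dataset(Y, x)
}

test_that("two-component sampler reduces to the univariate model when Z == 1", {
  set.seed(61)
  G <- 5; n_per <- 30
  x <- rep(c(0L, 1L), each = n_per)
  mu <- rnorm(G, 0, 0.5)
  Y <- matrix(rnorm(G * 2 * n_per, 5, 1), G) + outer(rnorm(G, 0, 0.6), x)
  Y[Y == 0] <- 1e-9
  d_uni <- expression_dataset(Y, x)
  d_sc <- sc_dataset(Y, x)
  expect_true(all(d_sc$zero_mask == 1))
  xi <- fit_variance_hyperparams(d_uni)
  st <- mcmc_settings(6000, 2000, 10, seed = 62)
  dr_uni <- run_mcmc(d_uni, prior_spec(mu, log2(1.5), xi["xi1"], xi["xi2"]),
                     st)
  dr_sc <- run_mcmc_sc(d_sc,
                       sc_prior_spec(mu, kappa = 1, eps1 = log2(1.5),
                                     eps2 = log2(1.5), xi1 = xi[["xi1"]],
                                     xi2 = xi[["xi2"]]),
                       mcmc_settings(6000, 2000, 10, seed = 63))
  # same target distribution for betaC: compare thinned draws per gene
  for (g in seq_len(G)) {
    ks <- suppressWarnings(ks.test(dr_uni$beta[g, ], dr_sc$betaC[g, ]))
    expect_gt(ks$p.value, 0.005)
  }
})

test_that("paired draws share iterations and dimensions", {
  d <- simulate_sc(G = 8, cells_per_group = 40, betaD = rnorm(8, 0, 0.5),
                   betaC = rnorm(8, 0, 0.5), seed = 64)
  pr <- sc_prior_spec(rep(0, 8), kappa = 1, eps1 = 0.3, eps2 = 0.3,
                      xi1 = 4, xi2 = 3)
  dr <- run_mcmc_sc(d, pr, mcmc_settings(600, 200, 2, seed = 65))
  expect_identical(dim(dr$betaD), dim(dr$betaC))
  expect_identical(dim(dr$betaD), dim(dr$lambdaD))
  expect_true(all(dr$lambdaD > 0) && all(dr$lambdaC > 0) &&
              all(dr$sigma2 > 0))
  # determinism under the seed
  dr2 <- run_mcmc_sc(d, pr, mcmc_settings(600, 200, 2, seed = 65))
  expect_identical(dr$betaD, dr2$betaD)
})

test_that("genes without enough nonzero cells are skipped with a warning", {
  set.seed(66)
  Y <- matrix(abs(rnorm(3 * 20, 4)), 3, 20)
  Y[2, 1:18] <- 0  # gene 2: almost everything dropped out
  d <- sc_dataset(Y, rep(c(0L, 1L), each = 10))
  pr <- sc_prior_spec(rep(0, 3), kappa = 1, eps1 = 0.3, eps2 = 0.3,
                      xi1 = 4, xi2 = 3)
  expect_warning(dr <- run_mcmc_sc(d, pr, mcmc_settings(400, 100, 1, seed = 6)),
                 "skipped")
  expect_identical(dr$skipped, "gene_2")
  expect_equal(nrow(dr$betaD), 2)
})

test_that("dropout-effect credible intervals reach nominal coverage", {
  # model-generated logistic data with known betaD: 95% intervals cover
  # ~95% of the true values (the adaptive Metropolis kernel is exact in
  # its stationary law)
  G <- 100
  set.seed(67)
  betaD <- rnorm(G, 0, 1)
  betaC <- rnorm(G, 0, 0.5)
  d <- simulate_sc(G, cells_per_group = 200, betaD = betaD, betaC = betaC,
                   seed = 68)
  pr <- sc_prior_spec(mu = betaC, kappa = 0, eps1 = 0.3, eps2 = 0.3,
                      xi1 = 4, xi2 = 3)
  dr <- run_mcmc_sc(d, pr, mcmc_settings(4000, 2000, 2, seed = 69))
  ci <- apply(dr$betaD, 1, quantile, probs = c(0.025, 0.975))
  keep <- match(dr$gene_ids, d$gene_ids)
  cover <- mean(betaD[keep] >= ci[1, ] & betaD[keep] <= ci[2, ])
  expect_gt(cover, 0.95 - 3 * sqrt(0.95 * 0.05 / G) - 0.02)
})

test_that("kappa steers the dropout prior center", {
  # true betaD = 0 everywhere; with kappa = 1 and a positive bulk prior mu
  # the dropout effects are pulled upward relative to kappa = 0 (center 0)
  G <- 12
  d <- simulate_sc(G = G, cells_per_group = 15, betaD = rep(0, G),
                   betaC = rep(0, G), seed = 70)
  st <- mcmc_settings(1500, 500, 2, seed = 71, tau_fixed = 1)
  pr0 <- sc_prior_spec(mu = rep(2, G), kappa = 0, eps1 = 0.3, eps2 = 0.3,
                       xi1 = 4, xi2 = 3)
  pr1 <- sc_prior_spec(mu = rep(2, G), kappa = 1, eps1 = 0.3, eps2 = 0.3,
                       xi1 = 4, xi2 = 3)
  pm0 <- mean(rowMeans(run_mcmc_sc(d, pr0, st)$betaD))
  pm1 <- mean(rowMeans(run_mcmc_sc(d, pr1, st)$betaD))
  expect_gt(pm1, pm0)
})

test_that("bivariate decisions follow the favored-category estimator", {
  # one decisive gene: all mass in the (+,+) quadrant
  dr <- structure(list(betaD = matrix(2, 1, 300), betaC = matrix(2, 1, 300),
                       gene_ids = "g1"),
                  class = "ScPosteriorDraws")
  pr <- sc_prior_spec(mu = 0, kappa = 1, eps1 = 0.3, eps2 = 0.3,
                      xi1 = 4, xi2 = 3)
  tab <- decide_sc(dr, pr, alpha = 0.05)
  expect_equal(tab$bcr, 0)
  expect_equal(tab$qvalue, 0)
  expect_equal(tab$decision, 1L)
  # hand case through the summary layer: (0.05, 0.80, 0.05, 0.05, 0.05)
  s <- data.frame(gene_id = "g", omega0 = 0.05, omega1 = 0.80,
                  omega2 = 0.05, omega3 = 0.05, omega4 = 0.05,
                  bcr = 0.05 / 0.95)
  class(s) <- c("GeneTestSummary", "data.frame")
  fav <- estimate_sign_set(s)
  expect_identical(fav, 1L)
  expect_equal(msfdr_estimate(s, fav, lambda = 0.5), 0.05 / 0.80)
  # mass entirely in mixed regions: bcr = 0 and favored probability 0.
  # Such a gene contributes nothing to either side of the estimator
  # (0/0 convention gives 0); its nominal rejection carries no mass.
  sm <- data.frame(gene_id = "g", omega0 = 0, omega1 = 0, omega2 = 0,
                   omega3 = 0, omega4 = 0, bcr = 0)
  class(sm) <- c("GeneTestSummary", "data.frame")
  expect_identical(msfdr_estimate(sm, estimate_sign_set(sm), 0.5), 0)
  # positive null mass with zero favored mass trips the +Inf guard
  si <- data.frame(gene_id = "g", omega0 = 0.3, omega1 = 0, omega2 = 0,
                   omega3 = 0, omega4 = 0, bcr = 0.3)
  class(si) <- c("GeneTestSummary", "data.frame")
  expect_warning(est <- msfdr_estimate(si, estimate_sign_set(si), 0.5),
                 "zero favored-tail")
  expect_identical(est, Inf)
})

test_that("an infinite dropout threshold reduces the null region to betaC", {
  set.seed(72)
  dr <- structure(list(betaD = matrix(rnorm(600), 2, 300),
                       betaC = matrix(rnorm(600, 0, 2), 2, 300),
                       gene_ids = c("a", "b")),
                  class = "ScPosteriorDraws")
  s_big <- summarize_posterior_sc(dr, eps1 = 1e9, eps2 = 0.5)
  # no draw exceeds eps1, so the four sign categories are empty and the
  # null mass equals the univariate null mass of betaC alone
  expect_true(all(s_big[, c("omega1", "omega2", "omega3", "omega4")] == 0))
  for (g in 1:2)
    expect_equal(s_big$omega0[g],
                 unname(tail_probs(dr$betaC[g, ], 0.5)["omega0"]))
})
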