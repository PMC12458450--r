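# Independent oracles used across tests. These recompute expected results
# by generic matrix algebra / quadrature / enumeration, never through the
# package's own sampling code paths.

# Closed-form normal-inverse-gamma posterior of the two-group regression
# y = c + x*beta + e with prior (c, beta) | s2 ~ N((0, h), s2*diag(s0sq, lt2)),
# s2 ~ IG(xi1, xi2).  Returns marginal moments of beta, c and s2.
nig_oracle <- function(y, x, h, xi1, xi2, s0sq, lt2) {
  X <- cbind(1, x)
  L0 <- diag(c(1 / s0sq, 1 / lt2))
  m0 <- c(0, h)
  Ln <- t(X) %*% X + L0
  bn <- t(X) %*% y + L0 %*% m0
  mn <- solve(Ln, bn)
  a_n <- xi1 + length(y) / 2
  b_n <- xi2 + 0.5 * (sum(y^2) + t(m0) %*% L0 %*% m0 - t(mn) %*% Ln %*% mn)[1]
  V <- solve(Ln)
  list(
    beta_mean = mn[2], beta_var = b_n / (a_n - 1) * V[2, 2],
    c_mean = mn[1], c_var = b_n / (a_n - 1) * V[1, 1],
    s2_mean = b_n / (a_n - 1),
    a_n = a_n, b_n = b_n, V = V, mn = mn
  )
}

# Mean of a positive scalar with density prop. to
# half-Cauchy(x) * exp(loglik(x)), by trapezoid quadrature on a log grid.
hc_target_mean <- function(loglik, lower = 1e-6, upper = 1e4, n = 20000) {
  u <- seq(log(lower), log(upper), length.out = n)
  x <- exp(u)
  lf <- -log1p(x^2) + vapply(x, loglik, 0) + u  # density in u
  lf <- lf - max(lf)
  w <- exp(lf)
  sum(w * x) / sum(w)
}

# Exhaustive-search minimizer of the expected sign-aware classification
# losses over all 2^G decision vectors.
# type 1/2: E L_k = sum_g (1-lam)*om0*d + lam*om_k*(1-d)
# type 3 (given S): k = 1 for g in S, 2 otherwise.
enumerate_optimal_decision <- function(om0, om1, om2, lam, type, in_S = NULL) {
  G <- length(om0)
  omk <- switch(type,
    `1` = om1,
    `2` = om2,
    `3` = ifelse(in_S, om1, om2))
  best <- NULL; best_loss <- Inf
  for (code in 0:(2^G - 1)) {
    d <- as.integer(intToBits(code)[1:G])
    loss <- sum((1 - lam) * om0 * d + lam * omk * (1 - d))
    if (loss < best_loss) { best_loss <- loss; best <- d }
  }
  list(decision = best, loss = best_loss)
}

# random well-separated probability triples (no ties that would make the
# minimizer non-unique)
random_triples <- function(n, seed) {
  set.seed(seed)
  m <- matrix(stats::rgamma(3 * n, 1), ncol = 3)
  m / rowSums(m)
}

# minimal GeneTestSummary builder for decision-layer tests
make_summaries <- function(om0, om1, om2, ids = NULL) {
  if (is.null(ids)) ids <- paste0("g", seq_along(om0))
  bcr <- ifelse(om0 <= 0, 0, om0 / (1 - pmin(om1, om2)))
  out <- data.frame(gene_id = ids, omega0 = om0, omega1 = om1, omega2 = om2,
                    bcr = bcr, beta_postmean = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("GeneTestSummary", "data.frame")
  out
}
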