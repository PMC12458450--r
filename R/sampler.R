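#' Run the blocked Gibbs sampler for the shrinkage model
#'
#' Samples the joint posterior of the per-gene parameters (intercept c_g,
#' effect beta_g, residual variance sigma_g^2, local scale lambda_g) and the
#' global scale tau under the heteroscedastic global-local shrinkage prior
#' beta_g ~ N(h_g, sigma_g^2 lambda_g^2 tau^2), lambda_g, tau ~
#' half-Cauchy(0,1), sigma_g^2 ~ IG(xi1, xi2), c_g ~ N(0, 100 sigma_g^2).
#'
#' Each sweep draws beta_g from its marginal conditional with the intercept
#' and variance integrated out (a scaled/shifted Student-t, which improves
#' mixing), then sigma_g^2 and c_g from their exact conditionals, then
#' slice-samples lambda_g; a single slice update of tau, aggregating all
#' genes, closes the iteration. Updates are serial and driven by R's RNG,
#' so runs are bit-reproducible given `settings$seed`.
#'
#' @param data An [expression_dataset()].
#' @param prior A [prior_spec()]; `prior$h` must have one entry per gene.
#' @param settings An [mcmc_settings()].
#' @return An object of class `PosteriorDraws`: list with G x M matrices
#'   `beta`, `lambda`, `sigma2`, `c`, length-M vector `tau`, plus
#'   `gene_ids` and `settings`.
#' @export
run_mcmc <- function(data, prior, settings = mcmc_settings()) {
  stopifnot(inherits(data, "ExpressionDataset"), inherits(prior, "PriorSpec"),
            inherits(settings, "McmcSettings"))
  G <- nrow(data$values)
  if (length(prior$h) != G) stop("prior$h length must equal gene count")
  tau_fixed <- !is.null(settings$tau_fixed)
  tau0 <- if (tau_fixed) settings$tau_fixed else 1.0
  set.seed(settings$seed)
  out <- .run_gibbs_cpp(data$values, as.integer(data$group), prior$h,
                        prior$xi1, prior$xi2, prior$intercept_sd_mult^2,
                        settings$n_iter, settings$burn_in, settings$thin,
                        tau0, tau_fixed)
  structure(c(out, list(gene_ids = data$gene_ids, settings = settings)),
            class = "PosteriorDraws")
}

#' @export
print.PosteriorDraws <- function(x, ...) {
  cat(sprintf("PosteriorDraws: %d genes, %d retained draws\n",
              nrow(x$beta), ncol(x$beta)))
  invisible(x)
}

#' One conditional-update sweep for a single gene
#'
#' Exposes the per-gene Gibbs kernel used internally by [run_mcmc()]:
#' beta from its Student-t marginal conditional (c, sigma^2 integrated out),
#' then sigma^2 (inverse-gamma) and c (normal) from their exact
#' conditionals, and optionally a slice transition for lambda. Intended for
#' diagnostics and for validating the conjugate algebra against closed-form
#' posteriors.
#'
#' @param y_g Numeric vector of expressions for one gene.
#' @param X Integer 0/1 group indicator of the same length.
#' @param h_g Prior effect center for the gene.
#' @param state List with elements `c`, `beta`, `sigma2`, `lambda`.
#' @param tau Current global scale (> 0).
#' @param prior A [prior_spec()] (uses `xi1`, `xi2`, `intercept_sd_mult`).
#' @param update_lambda If `FALSE`, lambda is held fixed (useful for
#'   conditional-distribution checks).
#' @return Updated state list.
#' @export
gene_conditional_update <- function(y_g, X, h_g, state, tau, prior,
                                    update_lambda = TRUE) {
  stopifnot(inherits(prior, "PriorSpec"), tau > 0,
            is.list(state), state$sigma2 > 0, state$lambda > 0)
  .gene_update_cpp(as.numeric(y_g), as.integer(X), h_g,
                   state$c, state$beta, state$sigma2, state$lambda,
                   tau, prior$xi1, prior$xi2, prior$intercept_sd_mult^2,
                   isTRUE(update_lambda))
}

#' One slice-sampling transition for a positive scale parameter
#'
#' Single transition of a stepping-out + shrinkage slice sampler (on the
#' log scale, width 1, at most 50 step-outs per side) whose stationary
#' density is proportional to `half-Cauchy(0,1)(x) * exp(loglik(x))`.
#' Values below the floor 1e-6 are given zero density, which guards the
#' improper spike at zero arising when `loglik` is flat.
#'
#' @param current Current positive value.
#' @param loglik Function of the scale returning a finite log-likelihood
#'   (up to a constant); must be finite at `current`.
#' @return A positive value, one Markov transition away from `current`.
#' @export
slice_sample_scale <- function(current, loglik) {
  floor_log <- log(1e-6)
  logf <- function(u) {
    if (u < floor_log) return(-Inf)
    x <- exp(u)
    ll <- loglik(x)
    if (is.nan(ll)) stop("loglik returned NaN")
    -log1p(x^2) + ll + u  # half-Cauchy kernel x Jacobian of u = log x
  }
  u0 <- max(log(current), floor_log)
  f0 <- logf(u0)
  if (!is.finite(f0)) stop("log-density not finite at 'current'")
  y <- f0 - stats::rexp(1)
  w <- 1.0; m <- 50L
  L <- u0 - w * stats::runif(1)
  R <- L + w
  j <- floor(m * stats::runif(1)); k <- m - 1 - j
  while (j > 0 && L > floor_log && logf(L) > y) { L <- L - w; j <- j - 1 }
  while (k > 0 && logf(R) > y) { R <- R + w; k <- k - 1 }
  L <- max(L, floor_log)
  repeat {
    u1 <- stats::runif(1, L, R)
    if (logf(u1) > y) return(exp(u1))
    if (u1 < u0) L <- u1 else R <- u1
  }
}

#' One slice transition for the global shrinkage scale tau
#'
#' The conditional of tau aggregates every gene's prior term:
#' proportional to `(1+tau^2)^-1 * prod_g tau^-1 exp(-(beta_g - h_g)^2 /
#' (2 sigma_g^2 lambda_g^2 tau^2))`, computed in log space.
#'
#' @param beta,h,sigma2,lambda Numeric vectors of current per-gene states.
#' @param tau Current value (> 0).
#' @param tau_fixed Optional; when non-NULL it is returned unchanged.
#' @return New tau value (>= 1e-6).
#' @export
sample_tau <- function(beta, h, sigma2, lambda, tau, tau_fixed = NULL) {
  if (!is.null(tau_fixed)) return(tau_fixed)
  if (length(beta) == 0L) stop("empty gene set")
  stopifnot(length(h) == length(beta), length(sigma2) == length(beta),
            length(lambda) == length(beta), tau > 0)
  .sample_tau_cpp(as.numeric(beta), as.numeric(h), as.numeric(sigma2),
                  as.numeric(lambda), tau)
}
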