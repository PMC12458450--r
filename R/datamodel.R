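#' Construct an expression dataset for two-group differential analysis
#'
#' Bundles a gene-by-sample matrix of normalized expression values
#' (log2(CPM+1) scale) with a binary group indicator. The univariate model
#' regresses each gene's expression on the indicator with gene-specific
#' residual variance, so the per-gene effect is the log2 fold change
#' between groups.
#'
#' @param values Numeric matrix, genes in rows, samples in columns,
#'   normalized expression (see [normalize_counts()]).
#' @param group Integer/numeric vector of 0/1 treatment indicators, one per
#'   sample (column). Each group must contain at least 2 samples.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   rownames of `values` or `gene_1..gene_G`.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values`, `group`, `gene_ids`.
#' @export
expression_dataset <- function(values, group, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains missing or non-finite entries")
  group <- as.integer(group)
  if (length(group) != ncol(values))
    stop("'group' length must equal the number of samples (columns)")
  if (!all(group %in% c(0L, 1L)))
    stop("'group' must contain only 0 and 1")
  if (sum(group == 0L) < 2L || sum(group == 1L) < 2L)
    stop("need at least 2 samples in each group")
  if (is.null(gene_ids)) {
    gene_ids <- rownames(values)
    if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  }
  gene_ids <- as.character(gene_ids)
  if (length(gene_ids) != nrow(values)) stop("'gene_ids' length must equal gene count")
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene ids: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  structure(list(values = values, group = group, gene_ids = gene_ids),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%d control, %d treated)\n",
              nrow(x$values), ncol(x$values), sum(x$group == 0), sum(x$group == 1)))
  invisible(x)
}

#' Prior specification for the shrinkage model
#'
#' Holds the per-gene prior effect centers `h` (log2-fold-change units,
#' typically estimated from another platform or species), the composite-null
#' half-width `epsilon`, and the inverse-gamma hyperparameters for the
#' residual variances. The effect prior for gene g is
#' N(h_g, sigma_g^2 lambda_g^2 tau^2) with half-Cauchy(0,1) hyperpriors on
#' the local scale lambda_g and the global scale tau.
#'
#' @param h Numeric vector of prior effect centers, one per gene. Finite.
#' @param epsilon Positive scalar: composite null is beta in (-epsilon,
#'   epsilon), log2 units. A common choice is `log2(1.5)` or `log2(1.2)`.
#' @param xi1,xi2 Inverse-gamma shape/scale for the residual variance prior;
#'   usually obtained from [fit_variance_hyperparams()]. `xi1` must exceed 2
#'   so the prior variance of sigma^2 is finite.
#' @param intercept_sd_mult Prior standard-deviation multiplier for the
#'   intercept: c_g ~ N(0, intercept_sd_mult^2 sigma_g^2). Default 10.
#' @return An object of class `PriorSpec`.
#' @export
prior_spec <- function(h, epsilon, xi1, xi2, intercept_sd_mult = 10) {
  h <- as.numeric(h)
  if (any(!is.finite(h))) stop("'h' must be finite for every gene")
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0)
    stop("'epsilon' must be a positive scalar")
  if (xi1 <= 2) stop("'xi1' must exceed 2 (finite prior variance of sigma^2)")
  if (xi2 <= 0) stop("'xi2' must be positive")
  if (intercept_sd_mult <= 0) stop("'intercept_sd_mult' must be positive")
  structure(list(h = h, epsilon = epsilon, xi1 = xi1, xi2 = xi2,
                 intercept_sd_mult = intercept_sd_mult),
            class = "PriorSpec")
}

#' MCMC run settings
#'
#' @param n_iter Total iterations. @param burn_in Discarded initial
#'   iterations (< n_iter). @param thin Keep every `thin`-th post-burn-in
#'   draw. @param seed Integer seed; every run is reproducible given the
#'   seed. @param tau_fixed Optional positive value; when supplied the
#'   global scale tau is held at this value instead of being sampled.
#' @return An object of class `McmcSettings`.
#' @details The retained draw count `(n_iter - burn_in) / thin` must be at
#'   least 200 so that tail probabilities are estimable.
#' @export
mcmc_settings <- function(n_iter = 4000L, burn_in = 2000L, thin = 2L,
                          seed = 1L, tau_fixed = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (n_iter <= 0L) stop("'n_iter' must be positive")
  if (burn_in < 0L || burn_in >= n_iter) stop("'burn_in' must be in [0, n_iter)")
  if (thin <= 0L) stop("'thin' must be positive")
  m <- (n_iter - burn_in) %/% thin
  if (m < 200L)
    stop("retained draw count (n_iter - burn_in)/thin must be >= 200, got ", m)
  if (!is.null(tau_fixed)) {
    if (!is.numeric(tau_fixed) || length(tau_fixed) != 1L || tau_fixed <= 0)
      stop("'tau_fixed' must be a positive scalar")
  }
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 seed = as.integer(seed), tau_fixed = tau_fixed),
            class = "McmcSettings")
}

#' Normalize raw counts to log2(CPM + 1)
#'
#' @param raw Matrix of non-negative integer counts, genes x samples.
#' @return Matrix of the same shape with entries
#'   `log2(raw / colsum * 1e6 + 1)`; all entries are >= 0.
#' @examples
#' m <- matrix(c(10, 0, 500, 10, 0, 500), nrow = 3)
#' normalize_counts(m + 0)[, 1]
#' @export
normalize_counts <- function(raw) {
  raw <- as.matrix(raw)
  if (!is.numeric(raw)) stop("counts must be numeric")
  if (anyNA(raw)) stop("counts contain missing values")
  if (any(raw < 0)) stop("counts must be non-negative")
  if (any(abs(raw - round(raw)) > 1e-8)) stop("counts must be integers")
  tot <- colSums(raw)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0)
    nm <- colnames(raw)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("sample(s) with zero total count: ", paste(nm, collapse = ", "))
  }
  out <- log2(sweep(raw, 2, tot, "/") * 1e6 + 1)
  dimnames(out) <- dimnames(raw)
  out
}

#' Fit inverse-gamma variance hyperparameters by moment matching
#'
#' Computes the per-gene pooled residual sample variances s_g^2 (residual to
#' the two group means, denominator n - 2) and chooses the inverse-gamma
#' shape/scale (xi1, xi2) so that the prior mean and variance of sigma_g^2
#' match the empirical mean m and variance v of the s_g^2:
#' `xi1 = m^2/v + 2`, `xi2 = m * (xi1 - 1)`.
#'
#' Genes whose within-group variance is exactly zero are retained but their
#' s_g^2 is replaced by the genome-wide mean for the fit only. When v falls
#' below the floor `1e-6 * m^2` (near-constant gene variances) the floor is
#' used so that the prior stays proper and weakly informative.
#'
#' @param data An [expression_dataset()].
#' @return Named numeric vector `c(xi1 = ..., xi2 = ...)`.
#' @export
fit_variance_hyperparams <- function(data) {
  stopifnot(inherits(data, "ExpressionDataset"))
  Y <- data$values; x <- data$group
  if (nrow(Y) < 2L) stop("need at least 2 genes")
  n <- ncol(Y)
  i1 <- x == 1L; i0 <- !i1
  mu1 <- rowMeans(Y[, i1, drop = FALSE])
  mu0 <- rowMeans(Y[, i0, drop = FALSE])
  rss <- rowSums((Y[, i1, drop = FALSE] - mu1)^2) +
         rowSums((Y[, i0, drop = FALSE] - mu0)^2)
  s2 <- rss / (n - 2)
  m <- mean(s2)
  if (m <= 0) stop("all genes have zero pooled variance (constant data)")
  zero <- s2 <= 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) with zero pooled variance; using the ",
            "genome-wide mean for hyperparameter fitting")
    s2[zero] <- m
    m <- mean(s2)
  }
  v <- stats::var(s2)
  v_floor <- 1e-6 * m^2
  if (!is.finite(v) || v < v_floor) {
    warning("variance of gene variances below floor; using v = 1e-6 * m^2")
    v <- v_floor
  }
  xi1 <- m^2 / v + 2
  xi2 <- m * (xi1 - 1)
  c(xi1 = xi1, xi2 = xi2)
}
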