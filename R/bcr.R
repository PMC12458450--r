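#' Posterior region probabilities for a composite null
#'
#' Partitions posterior draws of an effect into the null interval and the
#' two tails: `omega1 = Pr(beta <= -epsilon | D)`, `omega2 = Pr(beta >=
#' epsilon | D)`, `omega0 = Pr(-epsilon < beta < epsilon | D)`. Draws
#' landing exactly on a boundary are counted in the tail (closed tails,
#' open null interval), so the three fractions always sum to 1.
#'
#' @param draws Numeric vector of posterior draws (>= 200).
#' @param epsilon Positive composite-null half-width.
#' @return Named numeric vector `c(omega0, omega1, omega2)`.
#' @export
tail_probs <- function(draws, epsilon) {
  if (length(draws) == 0L) stop("empty draws")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  omega1 <- mean(draws <= -epsilon)
  omega2 <- mean(draws >= epsilon)
  c(omega0 = 1 - omega1 - omega2, omega1 = omega1, omega2 = omega2)
}

#' Bayesian Credible Ratio
#'
#' The test statistic `BCR = omega0 / (1 - min(omega1, omega2))`, comparing
#' the posterior null mass against the evidence left once the weaker tail
#' is discounted. Small values favor rejection; the null is rejected when
#' BCR falls below a threshold lambda in (0, 1). When `omega0 = 0` the
#' statistic is 0 by convention (the guarded division can only degenerate
#' there).
#'
#' @param omega0,omega1,omega2 Region probabilities summing to 1.
#' @return A value in `[0, 1]`.
#' @export
bcr_statistic <- function(omega0, omega1, omega2) {
  if (any(c(omega0, omega1, omega2) < 0)) stop("negative probabilities")
  if (abs(omega0 + omega1 + omega2 - 1) > 1e-8)
    stop("probabilities must sum to 1")
  if (omega0 == 0) return(0)
  omega0 / (1 - pmin(omega1, omega2))
}

#' Posterior region probabilities for the bivariate composite null
#'
#' For the two-component single-cell model the null region is the rectangle
#' `(-eps1, eps1) x (-eps2, eps2)` over (betaD, betaC), and the four
#' alternative categories require BOTH coordinates beyond their thresholds
#' with sign patterns (-,-), (+,+), (-,+), (+,-). Draws in mixed regions
#' (one coordinate inside, the other outside) belong to no category, so the
#' five reported fractions can sum to less than 1.
#'
#' @param drawsD,drawsC Paired posterior draws (same iterations) of the
#'   dropout-component and continuous-component effects.
#' @param eps1,eps2 Positive half-widths for betaD and betaC.
#' @return Named vector `c(omega0, omega1, omega2, omega3, omega4)`.
#' @export
tail_probs_bivariate <- function(drawsD, drawsC, eps1, eps2) {
  if (length(drawsD) != length(drawsC)) stop("paired draws length mismatch")
  if (length(drawsD) == 0L) stop("empty draws")
  if (eps1 <= 0 || eps2 <= 0) stop("epsilons must be positive")
  lo1 <- drawsD <= -eps1; hi1 <- drawsD >= eps1
  lo2 <- drawsC <= -eps2; hi2 <- drawsC >= eps2
  in1 <- !lo1 & !hi1; in2 <- !lo2 & !hi2
  c(omega0 = mean(in1 & in2),
    omega1 = mean(lo1 & lo2),
    omega2 = mean(hi1 & hi2),
    omega3 = mean(lo1 & hi2),
    omega4 = mean(hi1 & lo2))
}

#' Summarize posterior draws into per-gene test summaries
#'
#' Computes, for every gene, the region probabilities, the BCR, and the
#' posterior mean effect.
#'
#' @param draws A `PosteriorDraws` object from [run_mcmc()].
#' @param epsilon Composite-null half-width.
#' @return A data.frame of class `GeneTestSummary` with columns `gene_id`,
#'   `omega0`, `omega1`, `omega2`, `bcr`, `beta_postmean`,
#'   `lambda_postmean`.
#' @export
summarize_posterior <- function(draws, epsilon) {
  stopifnot(inherits(draws, "PosteriorDraws"))
  if (epsilon <= 0) stop("'epsilon' must be positive")
  B <- draws$beta
  omega1 <- rowMeans(B <= -epsilon)
  omega2 <- rowMeans(B >= epsilon)
  omega0 <- 1 - omega1 - omega2
  denom <- 1 - pmin(omega1, omega2)
  bcr <- ifelse(omega0 <= 0, 0, omega0 / denom)
  out <- data.frame(gene_id = draws$gene_ids,
                    omega0 = omega0, omega1 = omega1, omega2 = omega2,
                    bcr = bcr,
                    beta_postmean = rowMeans(B),
                    lambda_postmean = rowMeans(draws$lambda),
                    stringsAsFactors = FALSE)
  class(out) <- c("GeneTestSummary", "data.frame")
  out
}

#' Summarize paired two-component draws (bivariate test)
#'
#' @param draws Paired draws from [run_mcmc_sc()].
#' @param eps1,eps2 Half-widths for the dropout (betaD) and continuous
#'   (betaC) effects.
#' @return A data.frame of class `GeneTestSummary` with columns `gene_id`,
#'   `omega0`..`omega4`, `bcr`, `betaD_postmean`, `betaC_postmean`.
#' @export
summarize_posterior_sc <- function(draws, eps1, eps2) {
  stopifnot(inherits(draws, "ScPosteriorDraws"))
  if (eps1 <= 0 || eps2 <= 0) stop("epsilons must be positive")
  D <- draws$betaD; C <- draws$betaC
  lo1 <- D <= -eps1; hi1 <- D >= eps1
  lo2 <- C <= -eps2; hi2 <- C >= eps2
  in1 <- !lo1 & !hi1; in2 <- !lo2 & !hi2
  omega0 <- rowMeans(in1 & in2)
  om <- cbind(omega1 = rowMeans(lo1 & lo2), omega2 = rowMeans(hi1 & hi2),
              omega3 = rowMeans(lo1 & hi2), omega4 = rowMeans(hi1 & lo2))
  ca <- apply(om, 1, min)
  bcr <- ifelse(omega0 <= 0, 0, omega0 / (1 - ca))
  out <- data.frame(gene_id = draws$gene_ids, omega0 = omega0, om,
                    bcr = bcr,
                    betaD_postmean = rowMeans(D),
                    betaC_postmean = rowMeans(C),
                    stringsAsFactors = FALSE)
  class(out) <- c("GeneTestSummary", "data.frame")
  out
}
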