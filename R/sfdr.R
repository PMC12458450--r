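#' Estimate the sign-preference partition
#'
#' Each gene is assigned to the sign set S (negative effects favored upon
#' rejection) when its posterior negative-tail mass is at least the
#' positive-tail mass, `omega1 >= omega2`; ties go to S. For bivariate
#' (two-component) summaries the analogue is the favored category: the
#' argmax over the four sign-category probabilities, ties broken by lowest
#' index.
#'
#' @param summaries A `GeneTestSummary` data.frame.
#' @return Logical vector (`TRUE` = in S) for univariate summaries; integer
#'   vector in 1..4 (favored category) for bivariate summaries.
#' @export
estimate_sign_set <- function(summaries) {
  stopifnot(inherits(summaries, "data.frame"))
  if ("omega3" %in% names(summaries)) {
    om <- as.matrix(summaries[, c("omega1", "omega2", "omega3", "omega4")])
    return(apply(om, 1, which.max))  # which.max breaks ties by lowest index
  }
  summaries$omega1 >= summaries$omega2
}

# favored-tail posterior probability per gene: the denominator weight of
# the sign-adjusted FDR estimator
.favored_prob <- function(summaries, in_S) {
  if ("omega3" %in% names(summaries)) {
    om <- as.matrix(summaries[, c("omega1", "omega2", "omega3", "omega4")])
    om[cbind(seq_len(nrow(om)), as.integer(in_S))]
  } else {
    ifelse(in_S, summaries$omega1, summaries$omega2)
  }
}

# core estimator on a rejection set given per-gene null mass and favored
# tail mass; 0/0 -> 0, x/0 with x > 0 -> +Inf sentinel
.msfdr_core <- function(num, den) {
  if (den > 0) return(num / den)
  if (num == 0) 0 else Inf
}

#' Estimate the marginal sign-adjusted FDR at a threshold
#'
#' Unbiased plug-in estimator of the marginal sign-adjusted false discovery
#' rate of the rule "reject when BCR < lambda": the numerator sums the
#' posterior null mass `omega0` over rejected genes; the denominator sums
#' the favored-tail mass (`omega1` for genes in S, `omega2` otherwise; the
#' favored-category probability in the bivariate case). Empty rejection
#' sets give 0.
#'
#' @param summaries A `GeneTestSummary` data.frame.
#' @param in_S Output of [estimate_sign_set()].
#' @param lambda Rejection threshold in (0, 1).
#' @param denominator `"printed"` (default) uses the favored tail mass
#'   alone; `"with_null"` additionally adds `omega0` for each rejected
#'   gene, the literal expectation of the defining ratio's denominator.
#' @return Non-negative estimate (may exceed 1; `Inf` when every rejected
#'   gene has zero favored-tail mass but positive null mass).
#' @export
msfdr_estimate <- function(summaries, in_S, lambda,
                           denominator = c("printed", "with_null")) {
  denominator <- match.arg(denominator)
  if (lambda <= 0 || lambda >= 1) stop("'lambda' must be in (0, 1)")
  rej <- summaries$bcr < lambda
  if (!any(rej)) return(0)
  fav <- .favored_prob(summaries, in_S)
  den <- sum(fav[rej])
  if (denominator == "with_null") den <- den + sum(summaries$omega0[rej])
  est <- .msfdr_core(sum(summaries$omega0[rej]), den)
  if (is.infinite(est))
    warning("rejected genes carry zero favored-tail mass; estimator is +Inf")
  est
}

# estimator evaluated at every bcr tie-block boundary (ranks sorted by
# ascending bcr); returns block boundaries and the raw estimate per block
.msfdr_path <- function(summaries, in_S, denominator = "printed") {
  ord <- order(summaries$bcr)
  bcr <- summaries$bcr[ord]
  fav <- .favored_prob(summaries, in_S)[ord]
  om0 <- summaries$omega0[ord]
  den_w <- if (denominator == "with_null") fav + om0 else fav
  cnum <- cumsum(om0)
  cden <- cumsum(den_w)
  ends <- which(!duplicated(bcr, fromLast = TRUE))  # last rank of each tie block
  raw <- mapply(function(n, d) .msfdr_core(n, d), cnum[ends], cden[ends])
  list(ord = ord, bcr = bcr, block_end = ends, raw = raw,
       block_value = bcr[ends])
}

#' Select the largest rejection threshold controlling the sign-adjusted FDR
#'
#' The estimator is a step function with breakpoints at the distinct BCR
#' values, so the search is exact: each candidate threshold rejects all
#' genes with BCR strictly below it, and the selected `lambda_star` is the
#' largest candidate whose estimate stays below `alpha` (`1 - 1e-9` when
#' every gene can be rejected; below the minimum BCR when even the smallest
#' nonempty rejection set violates `alpha`, so that nothing is rejected).
#'
#' @inheritParams msfdr_estimate
#' @param alpha Nominal sign-adjusted FDR level in (0, 1).
#' @return `lambda_star` in (0, 1).
#' @export
select_lambda <- function(summaries, in_S, alpha,
                          denominator = c("printed", "with_null")) {
  denominator <- match.arg(denominator)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  path <- .msfdr_path(summaries, in_S, denominator)
  # candidate thresholds: each distinct bcr value (rejects the blocks
  # strictly below it) plus 1 - 1e-9 (rejects everything below that)
  cand <- c(path$block_value, 1 - 1e-9)
  # estimate for candidate j: raw over blocks with value < cand[j]
  nb <- length(path$raw)
  est <- numeric(nb + 1L)
  est[1L] <- 0  # rejecting nothing
  for (j in seq_len(nb)) {
    keep <- which(path$block_value < cand[j + 1L])
    est[j + 1L] <- if (length(keep)) path$raw[max(keep)] else 0
  }
  ok <- which(est < alpha)
  lambda_star <- cand[max(ok)]
  # clamp into (0, 1): a candidate equal to 0 rejects nothing anyway
  max(min(lambda_star, 1 - 1e-9), 1e-12)
}

#' Sign-adjusted FDR q-values
#'
#' The q-value of a gene is the smallest estimated sign-adjusted FDR among
#' rejection sets that include it: genes are ranked by ascending BCR, the
#' estimator is evaluated at every tie-block boundary, and the running
#' minimum from the bottom monotonizes the path (standard q-value
#' convention). Genes tied on BCR share a q-value. Values are capped at 1.
#'
#' @inheritParams msfdr_estimate
#' @return Numeric vector of q-values in the input gene order.
#' @export
q_values <- function(summaries, in_S,
                     denominator = c("printed", "with_null")) {
  denominator <- match.arg(denominator)
  path <- .msfdr_path(summaries, in_S, denominator)
  qblock <- rev(cummin(rev(path$raw)))
  qblock <- pmin(qblock, 1)
  # expand block q to ranks, then undo the ordering
  reps <- diff(c(0L, path$block_end))
  qrank <- rep(qblock, reps)
  q <- numeric(length(qrank))
  q[path$ord] <- qrank
  q
}

#' Realized sign-adjusted false discovery proportion
#'
#' Validates a decision vector against the true effect categories
#' (0 = null interval, 1 = negative tail, 2 = positive tail): the numerator
#' counts rejections of true nulls; the denominator counts rejections that
#' are not sign-inconsistent with the gene's estimated sign set (for g in
#' S, any rejection with omega_g != 2; for g outside S, omega_g != 1).
#' Returns 0 when nothing is rejected.
#'
#' @param decision 0/1 vector of rejections.
#' @param true_omega Integer vector in \{0, 1, 2\} of true categories.
#' @param in_S Logical sign-set membership.
#' @return Realized proportion in `[0, 1]`.
#' @export
realized_sfdr <- function(decision, true_omega, in_S) {
  stopifnot(length(decision) == length(true_omega),
            length(in_S) == length(decision))
  if (!all(true_omega %in% 0:2)) stop("true_omega codes must be 0, 1 or 2")
  d <- as.numeric(decision)
  num <- sum(d * (true_omega == 0))
  den <- sum(d[in_S] * (true_omega[in_S] != 2)) +
         sum(d[!in_S] * (true_omega[!in_S] != 1))
  if (den == 0) 0 else num / den
}

#' Threshold posterior summaries into final decisions
#'
#' Runs sign-set estimation, threshold selection and q-value computation,
#' returning the per-gene decision table. The decision is `BCR <
#' lambda_star` (strict).
#'
#' @inheritParams msfdr_estimate
#' @param alpha Nominal sign-adjusted FDR level.
#' @return A data.frame of class `DecisionTable` with columns `gene_id`,
#'   `bcr`, `in_S` (or favored category for bivariate input), `qvalue`,
#'   `decision`, and attributes `lambda_star` and `alpha`.
#' @export
decide <- function(summaries, alpha,
                   denominator = c("printed", "with_null")) {
  denominator <- match.arg(denominator)
  in_S <- estimate_sign_set(summaries)
  lambda_star <- select_lambda(summaries, in_S, alpha, denominator)
  q <- q_values(summaries, in_S, denominator)
  out <- data.frame(gene_id = summaries$gene_id,
                    bcr = summaries$bcr,
                    in_S = in_S,
                    qvalue = q,
                    decision = as.integer(summaries$bcr < lambda_star),
                    stringsAsFactors = FALSE)
  attr(out, "lambda_star") <- lambda_star
  attr(out, "alpha") <- alpha
  class(out) <- c("DecisionTable", "data.frame")
  out
}
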