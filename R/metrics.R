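# Partition agreement: the classification error rate (CER) over unordered
# unit pairs, and the concordance 1 - CER used to report recovery.

#' Classification error rate between two partitions
#'
#' Fraction of the \eqn{\binom{m}{2}} unordered unit pairs whose
#' co-membership status (same cluster / different clusters) differs between
#' the two labelings.  Invariant to relabeling of either partition; 0 means
#' the partitions are identical up to label permutation, and concordance is
#' \code{1 - cer}.  Computed from the contingency table in O(m + ab) rather
#' than by pair enumeration.
#'
#' @param a,b equal-length label vectors over the same units (length >= 2).
#' @return a number in [0, 1].
#' @examples
#' cer(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 4/6: only 2 of 6 pairs agree
#' @export
cer <- function(a, b) {
  if (length(a) != length(b))
    stop("label vectors have different lengths (", length(a), " vs ",
         length(b), ")")
  m <- length(a)
  if (m < 2L) stop("need at least two units to compare partitions")
  tab <- table(a, b)
  same_a <- sum(choose(rowSums(tab), 2))
  same_b <- sum(choose(colSums(tab), 2))
  same_both <- sum(choose(tab, 2))
  (same_a + same_b - 2 * same_both) / choose(m, 2)
}

#' Clustering concordance
#'
#' \code{1 - cer(a, b)}: 1 for identical partitions up to relabeling.
#'
#' @inheritParams cer
#' @export
concordance <- function(a, b) 1 - cer(a, b)

#' Recovery report against a synthetic ground truth
#'
#' Summarizes how well a fit recovered a generated dataset: row and column
#' concordance (1 - CER against the true labels), nonempty fitted cluster
#' counts, the estimated marginal variance and its error, iterations and
#' runtime.
#'
#' @param fit an \code{"spnmtf"} fit of the dataset.
#' @param truth the \code{"spnmtf_sim"} object that generated it.
#' @return a one-row data frame.
#' @export
recovery_report <- function(fit, truth) {
  stopifnot(inherits(fit, "spnmtf"), inherits(truth, "spnmtf_sim"))
  if (fit$n != truth$n || fit$p != truth$p)
    stop("fit and truth have different data shapes")
  data.frame(
    row_concordance = concordance(fit$F, truth$F),
    col_concordance = concordance(fit$G, truth$G),
    nonempty_row = fit$nonempty_row,
    nonempty_col = fit$nonempty_col,
    tau_hat = fit$tau,
    tau_true = truth$tau,
    tau_error = fit$tau - truth$tau,
    n_iter = fit$n_iter,
    runtime = fit$runtime
  )
}
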