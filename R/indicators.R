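# Hard cluster memberships travel through the package as integer label
# vectors; the dense 0/1 indicator form is materialized only where a matrix
# product needs it.

#' Dense cluster indicator matrix from labels
#'
#' @param labels integer vector of cluster indices in \code{1..C}.
#' @param C number of clusters (columns); defaults to \code{max(labels)}.
#'   Clusters with no members are legal and give zero columns.
#' @return an m x C matrix of zeros and ones with unit row sums.
#' @export
as_indicator <- function(labels, C = max(labels)) {
  labels <- as.integer(labels)
  m <- length(labels)
  if (m == 0L) stop("`labels` is empty")
  if (anyNA(labels) || any(labels < 1L) || any(labels > C))
    stop("labels must lie in 1..", C)
  M <- matrix(0, m, C)
  M[cbind(seq_len(m), labels)] <- 1
  M
}

#' Labels from a dense indicator matrix
#'
#' Inverse of [as_indicator()]; validates that every row has exactly one 1
#' and all other entries 0.
#'
#' @param M an m x C zero/one matrix with unit row sums.
#' @export
indicator_labels <- function(M) {
  M <- as.matrix(M)
  if (!all(M %in% c(0, 1)) || !all(rowSums(M) == 1))
    stop("not a valid indicator matrix: entries must be 0/1 with row sums 1")
  max.col(M, ties.method = "first")
}

#' Number of nonempty clusters
#'
#' Counts the clusters that contain at least one member.  Fitting with more
#' clusters than needed and letting the surplus empty is the supported route
#' to selecting the number of row and column clusters, so fitted and nonempty
#' ("estimated") cluster counts are reported separately throughout.
#'
#' @param x a label vector or a dense indicator matrix.
#' @export
count_nonempty <- function(x) {
  if (is.matrix(x)) sum(colSums(x != 0) > 0) else length(unique(as.integer(x)))
}
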