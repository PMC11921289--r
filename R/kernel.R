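# Spatial covariance structure: Sigma = tau * K(S; phi), K exponential in
# Euclidean distance, held in Cholesky-factored form.  All Sigma^{-1} products
# in the package go through triangular solves against the stored factor; an
# explicit inverse is never formed.

.validate_coords <- function(coords) {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (!is.matrix(coords) || ncol(coords) != 2L)
    stop("`coords` must be a matrix or data frame with two columns (x, y)")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords)))
    stop("`coords` contains non-finite values")
  coords
}

#' Exponential spatial correlation matrix
#'
#' Builds the p x p correlation matrix with entries
#' \eqn{\exp(-\|s_j - s_{j'}\| / \phi)}, where \eqn{s_j} are planar pixel
#' coordinates and \eqn{\phi > 0} is the kernel scale, in the same units as
#' the coordinates.  Distances are taken in the raw units of the input; no
#' internal rescaling is performed, so the interpretation of \code{phi} is
#' entirely determined by the coordinate units.
#'
#' @param coords matrix or data frame with two numeric columns (x, y), one
#'   row per pixel, in the column order of the data matrix.
#' @param phi positive kernel scale.
#' @return a symmetric p x p matrix with unit diagonal and entries in (0, 1].
#' @examples
#' s <- cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
#' K <- exp_corr(s, phi = 2)
#' K[1, 2]  # exp(-1/2)
#' @export
exp_corr <- function(coords, phi) {
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi <= 0)
    stop("`phi` must be a single positive number")
  coords <- .validate_coords(coords)
  D <- as.matrix(stats::dist(coords))
  K <- exp(-D / phi)
  dimnames(K) <- NULL
  K
}

#' Spatial kernel object
#'
#' Assembles and factors the column covariance \eqn{\Sigma = \tau K(S;\phi)}.
#' The object stores the correlation matrix, its lower Cholesky factor, the
#' factor of \eqn{\Sigma} itself and \eqn{\log|\Sigma|}.  If the correlation
#' matrix is numerically non-positive-definite (duplicated pixels, or a scale
#' far below the pixel spacing), a jitter of \code{jitter} on the diagonal is
#' added once and the factorization retried; a second failure is an error.
#'
#' @param coords pixel coordinates (ignored when \code{corr} is supplied).
#' @param phi positive kernel scale (recorded as \code{NA} for a supplied
#'   correlation matrix with no scale, e.g. the identity).
#' @param tau positive marginal variance.
#' @param corr optionally, a pre-built symmetric positive-definite correlation
#'   matrix; bypasses the exponential kernel construction.
#' @param jitter diagonal jitter used in the single retry on factorization
#'   failure.
#' @return an object of class \code{"spnmtf_kernel"}: a list with elements
#'   \code{phi}, \code{tau}, \code{corr}, \code{chol_corr} (lower factor of
#'   the correlation), \code{chol_lower} (lower factor of \eqn{\Sigma}),
#'   \code{log_det_corr}, \code{log_det_sigma}, \code{p} and \code{jittered}.
#' @seealso [whiten_columns()], [whiten_indicator()], [identity_kernel()]
#' @export
spatial_kernel <- function(coords = NULL, phi = NULL, tau = 1, corr = NULL,
                           jitter = 1e-8) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number")
  if (is.null(corr)) {
    corr <- exp_corr(coords, phi)
  } else {
    corr <- as.matrix(corr)
    if (nrow(corr) != ncol(corr)) stop("`corr` must be square")
    if (is.null(phi)) phi <- NA_real_
  }
  p <- nrow(corr)
  Lc <- tryCatch(t(chol(corr)), error = function(e) NULL)
  jittered <- FALSE
  if (is.null(Lc)) {
    Lc <- tryCatch(t(chol(corr + diag(jitter, p))), error = function(e) NULL)
    jittered <- TRUE
    if (is.null(Lc))
      stop("correlation matrix is not positive definite, even after adding ",
           format(jitter), " jitter")
  }
  log_det_corr <- 2 * sum(log(diag(Lc)))
  structure(list(
    phi = phi, tau = tau, corr = corr,
    chol_corr = Lc,
    chol_lower = sqrt(tau) * Lc,
    log_det_corr = log_det_corr,
    log_det_sigma = p * log(tau) + log_det_corr,
    p = p, jittered = jittered
  ), class = "spnmtf_kernel")
}

#' Identity-covariance kernel
#'
#' Convenience constructor for \eqn{\Sigma = \tau I_p}: the no-spatial-
#' correlation special case under which the whitened loss reduces to the plain
#' Frobenius coclustering loss.
#'
#' @param p number of pixels.
#' @param tau positive marginal variance.
#' @export
identity_kernel <- function(p, tau = 1) {
  spatial_kernel(corr = diag(p), tau = tau)
}

#' Replace the marginal variance of a kernel
#'
#' Rescales a factored kernel to a new \code{tau} without re-factoring the
#' correlation (the factor of \eqn{\tau K} is \eqn{\sqrt\tau} times the factor
#' of \eqn{K}).  Used every iteration after the closed-form variance update.
#'
#' @param kernel a \code{"spnmtf_kernel"} object.
#' @param tau new positive marginal variance.
#' @export
kernel_tau <- function(kernel, tau) {
  stopifnot(inherits(kernel, "spnmtf_kernel"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number")
  kernel$tau <- tau
  kernel$chol_lower <- sqrt(tau) * kernel$chol_corr
  kernel$log_det_sigma <- kernel$p * log(tau) + kernel$log_det_corr
  kernel
}

#' Whiten the columns of a matrix
#'
#' Computes \eqn{\tilde X = X (L^{-1})'} with \eqn{L} the lower Cholesky
#' factor of \eqn{\Sigma}, via a triangular solve.  The whitened matrix
#' satisfies \eqn{\tilde X L' = X}, and its squared Frobenius norm equals
#' \eqn{\mathrm{tr}(X \Sigma^{-1} X')}.
#'
#' @param X numeric matrix with p columns.
#' @param kernel a \code{"spnmtf_kernel"} over the same p pixels.
#' @export
whiten_columns <- function(X, kernel) {
  stopifnot(inherits(kernel, "spnmtf_kernel"))
  X <- as.matrix(X)
  if (ncol(X) != kernel$p)
    stop("`X` has ", ncol(X), " columns but the kernel is over ",
         kernel$p, " pixels")
  t(forwardsolve(kernel$chol_lower, t(X)))
}

#' Whiten an indicator matrix
#'
#' Computes \eqn{\tilde G = L^{-1} G} by triangular solve, so that
#' \eqn{L \tilde G = G}.
#'
#' @param G a p x R indicator matrix (or a length-p label vector, converted
#'   via [as_indicator()]).
#' @param kernel a \code{"spnmtf_kernel"} over the same p pixels.
#' @export
whiten_indicator <- function(G, kernel) {
  stopifnot(inherits(kernel, "spnmtf_kernel"))
  if (!is.matrix(G)) G <- as_indicator(G)
  if (nrow(G) != kernel$p)
    stop("`G` has ", nrow(G), " rows but the kernel is over ",
         kernel$p, " pixels")
  forwardsolve(kernel$chol_lower, G)
}

#' @export
print.spnmtf_kernel <- function(x, ...) {
  cat("Spatial kernel: Sigma = tau * K(S; phi)\n")
  cat("  pixels:", x$p, "\n")
  cat("  phi:   ", if (is.na(x$phi)) "(none: supplied correlation)"
      else format(x$phi), "\n")
  cat("  tau:   ", format(x$tau), "\n")
  cat("  log|Sigma|:", format(x$log_det_sigma), "\n")
  if (x$jittered) cat("  (diagonal jitter was required to factorize)\n")
  invisible(x)
}
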