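# Core trifactorization state and update steps.  The model approximates
# X (n x p) by F mu G' with F, G hard cluster indicators and mu a real-valued
# K x R centroid matrix (semi-NMTF: nonnegativity of mu is not imposed).
# The loss is || (X - F mu G') (L^{-1})' ||_F^2 with L L' = Sigma = tau*K(S;phi),
# i.e. the negative log-kernel of a matrix-variate Gaussian with identity row
# covariance and column covariance Sigma.

.block_mean_matrix <- function(mu, f, g) {
  mu[f, g, drop = FALSE]
}

.check_model_dims <- function(X, f, g, mu) {
  if (length(f) != nrow(X))
    stop("length of row labels (", length(f), ") != nrow(X) (", nrow(X), ")")
  if (length(g) != ncol(X))
    stop("length of column labels (", length(g), ") != ncol(X) (", ncol(X), ")")
  if (max(f) > nrow(mu) || max(g) > ncol(mu))
    stop("labels exceed the dimensions of `mu`")
}

#' Coclustering loss
#'
#' Squared Frobenius norm of the column-whitened residual,
#' \eqn{\|(X - F\mu G')(L^{-1})'\|_F^2}, computed by triangular solve.  It
#' equals the trace form \eqn{\mathrm{tr}[(X - F\mu G')\Sigma^{-1}(X - F\mu G')']}.
#' With \code{kernel = NULL} the covariance is the identity and the loss is
#' the plain Frobenius coclustering loss.
#'
#' @param X numeric n x p matrix.
#' @param f,g integer label vectors for the n rows and p columns.
#' @param mu K x R centroid matrix.
#' @param kernel a \code{"spnmtf_kernel"}, or \code{NULL} for \eqn{\Sigma = I}.
#' @return a nonnegative scalar.
#' @export
cocluster_loss <- function(X, f, g, mu, kernel = NULL) {
  X <- as.matrix(X)
  .check_model_dims(X, f, g, mu)
  E <- X - .block_mean_matrix(mu, f, g)
  if (is.null(kernel)) return(sum(E^2))
  stopifnot(inherits(kernel, "spnmtf_kernel"))
  sum(forwardsolve(kernel$chol_lower, t(E))^2)
}

#' Penalized coclustering loss
#'
#' Adds \eqn{n \log|\Sigma|} to [cocluster_loss()].  The penalty is the
#' \eqn{\Sigma}-dependent part of the matrix-variate Gaussian normalizing
#' constant; the penalized loss is (twice) the negative profile
#' log-likelihood up to an additive constant, and is the objective that the
#' closed-form variance update minimizes in \eqn{\tau}.
#'
#' @inheritParams cocluster_loss
#' @export
penalized_loss <- function(X, f, g, mu, kernel = NULL) {
  base <- cocluster_loss(X, f, g, mu, kernel)
  if (is.null(kernel)) base else base + nrow(as.matrix(X)) * kernel$log_det_sigma
}

#' Centroid update (Step 1)
#'
#' Minimizes the loss in \eqn{\mu} given the labels and the kernel:
#' \eqn{\mu \leftarrow (F'F)^{-1} F' X \Sigma^{-1} G (G'\Sigma^{-1}G)^{-1}}.
#' Empty clusters make \eqn{F'F} (or \eqn{G'\Sigma^{-1}G}) singular; the
#' update is computed over nonempty clusters only, and rows/columns of
#' \eqn{\mu} belonging to empty clusters keep their previous values
#' (\code{mu_prev}), or 0 when no previous centroids exist.  Since empty
#' clusters do not enter \eqn{F \mu G'}, this never increases the loss.
#'
#' The update does not depend on \eqn{\tau} (the scale cancels), only on the
#' correlation structure.
#'
#' @inheritParams cocluster_loss
#' @param K,R numbers of fitted row and column clusters.
#' @param mu_prev previous K x R centroid matrix used to fill entries of
#'   empty clusters, or \code{NULL}.
#' @return a K x R centroid matrix.
#' @export
update_centroids <- function(X, f, g, kernel = NULL, K = max(f), R = max(g),
                             mu_prev = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n == 0L || p == 0L) stop("cannot update centroids on an empty matrix")
  Fd <- as_indicator(f, K)
  Gd <- as_indicator(g, R)
  nk <- colSums(Fd)
  pr <- colSums(Gd)
  ke <- which(nk > 0)
  re <- which(pr > 0)
  if (length(ke) == 0L || length(re) == 0L)
    stop("invalid state: no nonempty row or column clusters")
  A <- if (is.null(kernel)) Gd else {
    # Sigma^{-1} G via two triangular solves against L
    backsolve(t(kernel$chol_lower),
              forwardsolve(kernel$chol_lower, Gd))
  }
  num <- crossprod(Fd, X) %*% A        # K x R:  F'X Sigma^{-1} G
  B <- crossprod(Gd, A)                # R x R:  G' Sigma^{-1} G
  mu <- if (is.null(mu_prev)) matrix(0, K, R) else {
    stopifnot(nrow(mu_prev) == K, ncol(mu_prev) == R)
    mu_prev
  }
  sub <- num[ke, re, drop = FALSE] / nk[ke]
  mu[ke, re] <- t(solve(B[re, re, drop = FALSE], t(sub)))
  mu
}

# Per-row assignment criteria ||Xt_i - mu_k Gt'||^2 up to the row-constant
# ||Xt_i||^2 (which cancels in both the argmin and the softmax).
.row_criteria <- function(X, mu, g, kernel) {
  R <- ncol(mu)
  Gd <- as_indicator(g, R)
  if (is.null(kernel)) {
    Xt <- as.matrix(X); Gt <- Gd
  } else {
    Xt <- whiten_columns(X, kernel)
    Gt <- forwardsolve(kernel$chol_lower, Gd)
  }
  M <- tcrossprod(mu, Gt)              # K x p, rows mu_k Gt'
  cr <- -2 * tcrossprod(Xt, M)         # n x K
  sweep(cr, 2L, rowSums(M^2), "+")
}

#' Row classification update (Step 2)
#'
#' Assigns each row i independently to
#' \eqn{\arg\min_k \|\tilde X_{i\cdot} - \mu_{k\cdot}\tilde G'\|^2}, with
#' \eqn{\tilde X = X(L^{-1})'} and \eqn{\tilde G = L^{-1}G}; this is the row-
#' wise minimizer of the full loss.  Ties go to the smallest cluster index.
#'
#' @inheritParams cocluster_loss
#' @return integer vector of n row labels.
#' @export
update_rows <- function(X, mu, g, kernel = NULL) {
  cr <- .row_criteria(X, mu, g, kernel)
  max.col(-cr, ties.method = "first")
}

#' Stochastic row update (Step 2S)
#'
#' Draws each row label from a categorical distribution with probabilities
#' proportional to \eqn{\exp(-c_{ik})}, \eqn{c_{ik}} the Step-2 criterion.
#' The per-row minimum criterion is subtracted before exponentiation (the raw
#' weights underflow at realistic loss magnitudes; the shift leaves the
#' probabilities unchanged).
#'
#' @inheritParams update_rows
#' @return integer vector of n row labels (consumes the R RNG stream).
#' @export
update_rows_stochastic <- function(X, mu, g, kernel = NULL) {
  cr <- .row_criteria(X, mu, g, kernel)
  K <- ncol(cr)
  w <- exp(-(cr - apply(cr, 1L, min)))
  vapply(seq_len(nrow(cr)), function(i) {
    sample.int(K, 1L, prob = w[i, ])
  }, integer(1))
}

# Sweep engine shared by the exact and stochastic column steps.
# For column j with current label r0, switching to label r changes the mean
# matrix in column j only, so the whitened residual changes by the rank-one
# term d_r z_j' with d_r = Fmu[, r0] - Fmu[, r] and z_j = L^{-1} e_j.  The
# full-loss difference of candidate r is 2 d_r' W z_j + ||d_r||^2 ||z_j||^2.
.col_sweep <- function(X, f, mu, g, kernel, order, choose) {
  X <- as.matrix(X)
  p <- ncol(X)
  R <- ncol(mu)
  g <- as.integer(g)
  .check_model_dims(X, f, g, mu)
  Cm <- mu[f, , drop = FALSE]                    # n x R composite centroids
  L <- kernel$chol_lower
  W <- t(forwardsolve(L, t(X - Cm[, g, drop = FALSE])))
  for (j in order) {
    ej <- numeric(p); ej[j] <- 1
    z <- forwardsolve(L, ej)
    Wz <- W %*% z
    D <- Cm[, g[j]] - Cm                         # n x R
    delta <- 2 * drop(crossprod(D, Wz)) + colSums(D^2) * sum(z^2)
    r_new <- choose(delta)
    if (r_new != g[j]) {
      W <- W + outer(D[, r_new], z)
      g[j] <- r_new
    }
  }
  g
}

#' Exact sequential column update (Step 3)
#'
#' Updates the column labels one at a time in \code{order}; each column takes
#' the label minimizing the full loss with all other labels held at their
#' current values, so the loss is non-increasing after every single-column
#' move.  Candidate losses are evaluated through a rank-one update of the
#' whitened residual rather than a full re-whitening.
#'
#' @inheritParams cocluster_loss
#' @param order sweep order over columns (default ascending).
#' @return integer vector of p column labels after one sweep.
#' @export
update_cols_exact <- function(X, f, mu, g, kernel, order = seq_len(ncol(X))) {
  .col_sweep(X, f, mu, g, kernel, order, choose = which.min)
}

#' Approximate parallel column update (Step 3A)
#'
#' Assigns each column j independently to
#' \eqn{\arg\min_r \|X_{\cdot j} - F\mu_{\cdot r}\|^2}, deliberately ignoring
#' the spatial covariance.  All columns can be updated in parallel, which is
#' what makes this the fast variant; the price is that the full (whitened)
#' loss is not guaranteed to decrease, so the fit driver tracks the best
#' state visited.
#'
#' @inheritParams cocluster_loss
#' @return integer vector of p column labels.
#' @export
update_cols_approx <- function(X, f, mu) {
  X <- as.matrix(X)
  Cm <- mu[f, , drop = FALSE]
  cr <- sweep(-2 * crossprod(X, Cm), 2L, colSums(Cm^2), "+")   # p x R
  max.col(-cr, ties.method = "first")
}

#' Stochastic sequential column update (Step 3S)
#'
#' As the exact step, but each column's new label is drawn from a multinomial
#' with probabilities proportional to \eqn{\exp(-\ell_r)} where \eqn{\ell_r}
#' is the full loss of candidate r.  The minimum candidate loss is subtracted
#' before exponentiation for numerical stability (the shift cancels in the
#' normalization).
#'
#' @inheritParams update_cols_exact
#' @return integer vector of p column labels (consumes the R RNG stream).
#' @export
update_cols_stochastic <- function(X, f, mu, g, kernel,
                                   order = seq_len(ncol(X))) {
  .col_sweep(X, f, mu, g, kernel, order, choose = function(delta) {
    w <- exp(-(delta - min(delta)))
    sample.int(length(delta), 1L, prob = w)
  })
}

#' Closed-form marginal variance update (Step 4)
#'
#' Returns \eqn{\mathrm{tr}[(X - F\mu G') K(S;\phi)^{-1} (X - F\mu G')'] / (np)},
#' the unique stationary point (and conditional minimum) of the penalized
#' loss in \eqn{\tau} with everything else fixed; equivalently the maximum
#' likelihood estimator of \eqn{\tau} under the matrix-variate Gaussian
#' model.  A zero residual returns 0; callers should treat that as a
#' degenerate fit and clamp before re-factoring the kernel.
#'
#' @inheritParams cocluster_loss
#' @export
update_tau <- function(X, f, g, mu, kernel = NULL) {
  X <- as.matrix(X)
  .check_model_dims(X, f, g, mu)
  E <- X - .block_mean_matrix(mu, f, g)
  q <- if (is.null(kernel)) sum(E^2) else
    sum(forwardsolve(kernel$chol_corr, t(E))^2)
  q / (nrow(X) * ncol(X))
}
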