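# S3 methods for fitted "spnmtf" models.

#' @export
print.spnmtf <- function(x, ...) {
  cat("Spatially informed semi-NMTF coclustering fit (variant ",
      x$variant, ")\n", sep = "")
  cat("  data: ", x$n, " signals x ", x$p, " pixels\n", sep = "")
  cat("  clusters: ", x$nonempty_row, "/", x$K, " row, ",
      x$nonempty_col, "/", x$R, " column (nonempty/fitted)\n", sep = "")
  cat("  kernel: phi =", format(x$phi), " tau =", format(x$tau, digits = 4),
      "\n")
  cat("  loss:", format(x$loss, digits = 6),
      " penalized:", format(x$penalized_loss, digits = 6), "\n")
  cat("  ", x$n_iter, " iterations, best of ", length(x$restart_losses),
      " restarts", if (!x$converged) " (hit max_iter)", "\n", sep = "")
  invisible(x)
}

#' @export
summary.spnmtf <- function(object, ...) {
  structure(list(
    fit = object,
    row_sizes = tabulate(object$F, object$K),
    col_sizes = tabulate(object$G, object$R),
    restart_quantiles = stats::quantile(object$restart_losses,
                                        c(0, .25, .5, .75, 1))
  ), class = "summary.spnmtf")
}

#' @export
print.summary.spnmtf <- function(x, ...) {
  print(x$fit)
  cat("\nRow cluster sizes:   ", paste(x$row_sizes, collapse = " "), "\n")
  cat("Column cluster sizes:", paste(x$col_sizes, collapse = " "), "\n")
  cat("\nPenalized loss across restarts:\n")
  print(x$restart_quantiles)
  invisible(x)
}

#' @export
coef.spnmtf <- function(object, ...) object$mu

#' @export
fitted.spnmtf <- function(object, ...) {
  object$mu[object$F, object$G, drop = FALSE]
}

#' @export
residuals.spnmtf <- function(object, whitened = FALSE, ...) {
  E <- object$X - fitted(object)
  if (!whitened) return(E)
  kern <- spatial_kernel(object$coords, object$phi, object$tau)
  whiten_columns(E, kern)
}

#' Matrix-variate Gaussian log-likelihood of a fit
#'
#' \eqn{-\tfrac12(\mathrm{loss} + n\log|\Sigma| + np\log 2\pi)} at the fitted
#' state; degrees of freedom count the centroids of nonempty blocks plus the
#' marginal variance.
#'
#' @param object an \code{"spnmtf"} fit.
#' @param ... unused.
#' @export
logLik.spnmtf <- function(object, ...) {
  val <- -0.5 * (object$penalized_loss +
                   object$n * object$p * log(2 * pi))
  structure(val,
            df = object$nonempty_row * object$nonempty_col + 1,
            nobs = object$n * object$p, class = "logLik")
}

#' Simulate from a fitted model
#'
#' Draws replicate experiment matrices from the fitted matrix-variate
#' Gaussian: mean \eqn{F\mu G'}, identity row covariance, fitted
#' \eqn{\tau K(S;\phi)} column covariance (identity when the model was fit
#' without coordinates).
#'
#' @param object an \code{"spnmtf"} fit.
#' @param nsim number of replicates.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of \code{nsim} matrices.
#' @export
simulate.spnmtf <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  M <- fitted(object)
  kern <- if (is.null(object$coords)) identity_kernel(object$p, object$tau)
          else spatial_kernel(object$coords, object$phi, object$tau)
  lapply(seq_len(nsim), function(i) sample_experiment(M, kern))
}

#' Plot a fitted segmentation
#'
#' Left: pixels colored by fitted column cluster at their coordinates (the
#' tissue segmentation).  When the model was fit without coordinates only
#' the centroid heatmap is drawn.
#'
#' @param x an \code{"spnmtf"} fit.
#' @param which \code{"segmentation"}, \code{"centroids"} or \code{"trace"}.
#' @param ... passed to the underlying plot call.
#' @export
plot.spnmtf <- function(x, which = c("segmentation", "centroids", "trace"),
                        ...) {
  which <- match.arg(which)
  if (which == "segmentation") {
    if (is.null(x$coords)) stop("fit has no coordinates to plot")
    graphics::plot(x$coords, col = x$G, pch = 15, asp = 1,
         xlab = "x", ylab = "y", main = "Fitted pixel clusters", ...)
  } else if (which == "centroids") {
    graphics::image(t(x$mu)[, rev(seq_len(x$K)), drop = FALSE],
                    axes = FALSE, main = "Cocluster centroids", ...)
  } else {
    graphics::plot(x$trace$iter, x$trace$penalized, type = "b", xlab = "iteration",
         ylab = "penalized loss", main = "Loss trace", ...)
  }
  invisible(x)
}
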