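# Synthetic data with the block-mean + matrix-variate Gaussian structure the
# fitting algorithm assumes: X = F mu G' + E, rows independent, columns
# correlated through an exponential kernel over a pixel grid on which
# same-cluster pixels form contiguous bands.

#' Random partition with a minimum cluster size
#'
#' Draws cluster sizes uniformly over the compositions of m into C parts of
#' size at least \code{min_size} (stars-and-bars on the excess), and returns
#' the labels in cluster-block order (cluster 1 first, then cluster 2, ...).
#' Shuffle the result if exchangeable units are wanted.
#'
#' @param m number of units.
#' @param C number of clusters.
#' @param min_size minimum size of every cluster; \code{C * min_size} must
#'   not exceed \code{m}.
#' @return integer vector of m labels (consumes the R RNG stream).
#' @export
random_partition <- function(m, C, min_size = 1L) {
  m <- as.integer(m); C <- as.integer(C); min_size <- as.integer(min_size)
  if (C < 1L || m < 1L) stop("`m` and `C` must be >= 1")
  if (C * min_size > m)
    stop("infeasible: ", C, " clusters of at least ", min_size,
         " units exceed m = ", m)
  extra <- m - C * min_size
  sizes <- rep(min_size, C)
  if (extra > 0L && C > 1L) {
    bars <- sort(sample.int(extra + C - 1L, C - 1L))
    sizes <- sizes + diff(c(0L, bars, extra + C)) - 1L
  } else if (C == 1L) {
    sizes <- m
  }
  rep(seq_len(C), sizes)
}

#' Lay out pixels on a grid with contiguous cluster bands
#'
#' Places the p pixels on an integer grid filling a near-square rectangle
#' column by column, visiting pixels in column-cluster order, so that the
#' pixels of each column cluster occupy a contiguous vertical band.  This
#' makes the within-cluster mean pairwise distance strictly smaller than the
#' between-cluster one, i.e. same-cluster pixels are the spatially most
#' correlated under any decreasing kernel.
#'
#' @param p number of pixels.
#' @param g integer vector of p column-cluster labels.
#' @return a p x 2 matrix of unique integer coordinates (columns x, y), row
#'   j giving the position of pixel j.
#' @export
layout_pixels <- function(p, g) {
  p <- as.integer(p)
  if (length(g) != p) stop("`g` must have length p")
  H <- max(1L, floor(sqrt(p)))
  ord <- order(g)                       # cluster-contiguous visiting order
  slot <- seq_len(p)
  x <- ceiling(slot / H)
  y <- (slot - 1L) %% H + 1L
  coords <- matrix(NA_real_, p, 2L, dimnames = list(NULL, c("x", "y")))
  coords[ord, 1L] <- x
  coords[ord, 2L] <- y
  coords
}

#' Default cocluster mean grid
#'
#' A maximally distinguishable K x R grid of a-priori block means,
#' \eqn{m_{k,r} = 4((k + r) \bmod \max(K,R)) - 2(\max(K,R) - 1)}: adjacent
#' blocks differ by at least 4, i.e. two total noise standard deviations at
#' the default generator settings (centroid sd 1, marginal variance 3).
#'
#' @param K,R numbers of row and column clusters.
#' @export
default_mean_matrix <- function(K, R) {
  C <- max(K, R)
  outer(seq_len(K), seq_len(R), function(k, r) 4 * ((k + r) %% C)) -
    2 * (C - 1)
}

#' Draw cocluster centroids around a mean grid
#'
#' Each centroid is drawn independently Normal(\eqn{m_{k,r}}, \code{sd}).
#'
#' @param mean_matrix K x R matrix of a-priori block means.
#' @param sd centroid standard deviation; 0 returns the means exactly.
#' @export
sample_centroids <- function(mean_matrix, sd = 1) {
  mean_matrix <- as.matrix(mean_matrix)
  if (!all(is.finite(mean_matrix))) stop("`mean_matrix` must be finite")
  mean_matrix + sd * matrix(stats::rnorm(length(mean_matrix)),
                            nrow(mean_matrix), ncol(mean_matrix))
}

#' Draw an experiment matrix around a mean
#'
#' Samples \eqn{X = M + c\, Z L'} with Z an n x p standard Gaussian matrix:
#' independent rows, column covariance \eqn{c^2 \Sigma} (the kernel's
#' \eqn{\tau} is inside \eqn{L}).  \code{kernel = NULL} gives independent
#' unit-variance noise; \code{noise_sd = 0} returns the mean exactly.
#'
#' @param mean n x p mean matrix (\eqn{F\mu G'} in the generator).
#' @param kernel a factored \code{"spnmtf_kernel"}, or \code{NULL} for
#'   \eqn{\Sigma = I}.
#' @param noise_sd scalar multiplier c on the noise (test hook; default 1).
#' @export
sample_experiment <- function(mean, kernel = NULL, noise_sd = 1) {
  mean <- as.matrix(mean)
  n <- nrow(mean); p <- ncol(mean)
  if (noise_sd == 0) return(mean)
  Z <- matrix(stats::rnorm(n * p), n, p)
  E <- if (is.null(kernel)) Z else {
    if (kernel$p != p) stop("kernel dimension does not match `mean`")
    Z %*% t(kernel$chol_lower)
  }
  mean + noise_sd * E
}

#' Generate a synthetic spatial coclustering dataset
#'
#' Composes the full generator: random row and column partitions with a
#' minimum cluster size, a pixel layout with spatially contiguous column-
#' cluster bands, centroids drawn around a block-mean grid, and a
#' matrix-variate Gaussian draw with identity row covariance and exponential-
#' kernel (or identity) column covariance.  The defaults are the simulation
#' conditions the method was validated under: 90 signals, 100 pixels, 3 row
#' and 4 column clusters, marginal variance 3, kernel scale 10, minimum
#' cluster size 5.
#'
#' @param n,p numbers of rows (signals) and columns (pixels).
#' @param K,R true numbers of row and column clusters.
#' @param tau true marginal variance of the spatial noise.
#' @param phi true kernel scale, in pixel-grid units.
#' @param spatial if \code{FALSE}, the column covariance is the identity
#'   (no spatial correlation scenario).
#' @param min_size minimum cluster size in both partitions.
#' @param mean_matrix K x R a-priori block means; default
#'   [default_mean_matrix()].
#' @param centroid_sd standard deviation of centroids around the means.
#' @param noise_sd scalar multiplier on the noise (0 = noiseless test hook).
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return an object of class \code{"spnmtf_sim"}: list with \code{X},
#'   \code{coords}, true labels \code{F}, \code{G}, \code{mu}, \code{tau},
#'   \code{phi}, \code{spatial}, \code{mean_matrix} and the config echo.
#' @examples
#' sim <- spnmtf_sim(seed = 1)
#' dim(sim$X)          # 90 x 100
#' table(sim$G)        # 4 contiguous pixel bands
#' @export
spnmtf_sim <- function(n = 90, p = 100, K = 3, R = 4, tau = 3, phi = 10,
                       spatial = TRUE, min_size = 5,
                       mean_matrix = NULL, centroid_sd = 1, noise_sd = 1,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mean_matrix)) mean_matrix <- default_mean_matrix(K, R)
  mean_matrix <- as.matrix(mean_matrix)
  stopifnot(nrow(mean_matrix) == K, ncol(mean_matrix) == R)
  f <- sample(random_partition(n, K, min_size))   # rows exchangeable
  g <- random_partition(p, R, min_size)           # columns stay band-ordered
  coords <- layout_pixels(p, g)
  mu <- sample_centroids(mean_matrix, centroid_sd)
  kernel <- if (spatial) spatial_kernel(coords, phi, tau) else NULL
  X <- sample_experiment(mu[f, g, drop = FALSE], kernel, noise_sd)
  structure(list(
    X = X, coords = coords, F = f, G = g, mu = mu,
    tau = if (spatial) tau else 1, phi = if (spatial) phi else NA_real_,
    spatial = spatial, min_size = min_size, mean_matrix = mean_matrix,
    centroid_sd = centroid_sd, noise_sd = noise_sd, seed = seed,
    n = n, p = p, K = K, R = R
  ), class = "spnmtf_sim")
}

#' @export
print.spnmtf_sim <- function(x, ...) {
  cat("Synthetic spatial coclustering dataset\n")
  cat("  X: ", x$n, " signals x ", x$p, " pixels\n", sep = "")
  cat("  true clusters: K =", x$K, "(rows), R =", x$R, "(columns)\n")
  if (x$spatial)
    cat("  noise: matrix-variate Gaussian, tau =", x$tau, ", phi =", x$phi, "\n")
  else
    cat("  noise: independent (identity column covariance)\n")
  invisible(x)
}

#' @describeIn spnmtf_sim plot the ground-truth pixel segmentation.
#' @param x,... plot method arguments.
#' @export
plot.spnmtf_sim <- function(x, ...) {
  graphics::plot(x$coords, col = x$G, pch = 15, asp = 1,
       main = "True column clusters", ...)
  invisible(x)
}
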