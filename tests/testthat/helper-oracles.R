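# Independent reference implementations used as oracles.  These deliberately
# use explicit inverses / double loops / pair enumeration: slow but
# transparently correct on small instances, and on a different code path
# from the package (which only ever does triangular solves).

oracle_corr <- function(coords, phi) {
  p <- nrow(coords)
  K <- matrix(NA_real_, p, p)
  for (j in seq_len(p)) {
    for (jj in seq_len(p)) {
      d <- sqrt(sum((coords[j, ] - coords[jj, ])^2))
      K[j, jj] <- exp(-d / phi)
    }
  }
  K
}

# Trace form of the loss with an explicit Sigma inverse.
oracle_loss <- function(X, f, g, mu, Sigma) {
  E <- X - mu[f, g, drop = FALSE]
  sum(diag(E %*% solve(Sigma) %*% t(E)))
}

oracle_penalized <- function(X, f, g, mu, Sigma) {
  oracle_loss(X, f, g, mu, Sigma) +
    nrow(X) * determinant(Sigma, logarithm = TRUE)$modulus[1]
}

# Exhaustive per-row assignment by full-loss evaluation.
oracle_rows <- function(X, f, g, mu, Sigma) {
  K <- nrow(mu)
  for (i in seq_len(nrow(X))) {
    losses <- vapply(seq_len(K), function(k) {
      fk <- f; fk[i] <- k
      oracle_loss(X, fk, g, mu, Sigma)
    }, numeric(1))
    f[i] <- which.min(losses)
  }
  f
}

# Sequential per-column assignment by full-loss evaluation (ascending j,
# each column updated against the labels chosen so far).
oracle_cols_sequential <- function(X, f, g, mu, Sigma) {
  R <- ncol(mu)
  for (j in seq_len(ncol(X))) {
    losses <- vapply(seq_len(R), function(r) {
      gr <- g; gr[j] <- r
      oracle_loss(X, f, gr, mu, Sigma)
    }, numeric(1))
    g[j] <- which.min(losses)
  }
  g
}

# Per-column nearest composite centroid, plain Euclidean.
oracle_cols_approx <- function(X, f, mu) {
  Cm <- mu[f, , drop = FALSE]
  vapply(seq_len(ncol(X)), function(j) {
    which.min(colSums((X[, j] - Cm)^2))
  }, integer(1))
}

# O(m^2) pairwise co-membership disagreement rate.
oracle_cer <- function(a, b) {
  m <- length(a)
  bad <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      if ((a[i] == a[j]) != (b[i] == b[j])) bad <- bad + 1L
    }
  }
  bad / choose(m, 2)
}

# Small random test instance with a factored kernel.
random_instance <- function(n, p, K, R, phi = 2, tau = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- cbind(stats::runif(p, 0, 6), stats::runif(p, 0, 6))
  if (is.null(tau)) tau <- stats::runif(1, 0.5, 3)
  list(
    X = matrix(stats::rnorm(n * p), n, p),
    f = sample.int(K, n, replace = TRUE),
    g = sample.int(R, p, replace = TRUE),
    mu = matrix(stats::rnorm(K * R, sd = 2), K, R),
    coords = coords,
    kernel = spatial_kernel(coords, phi, tau)
  )
}

sigma_of <- function(kernel) kernel$tau * kernel$corr
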