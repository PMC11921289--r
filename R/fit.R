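# Iterative fitting: initialization, the Step 1 -> row step -> column step ->
# Step 4 cycle, convergence, best-state tracking, random restarts and the
# kernel-scale grid.

.TAU_FLOOR <- 1e-12

.match_row_step <- function(row_step) {
  switch(toupper(substr(row_step[1L], 1L, 1L)),
         "C" = "classification", "S" = "stochastic",
         stop("`row_step` must be \"classification\" (C) or \"stochastic\" (S)"))
}

.match_col_step <- function(col_step) {
  key <- col_step[1L]
  key <- switch(toupper(substr(key, 1L, 1L)),
                "A" = "approx", "E" = "exact", "S" = "stochastic",
                # single-letter codes: C = exact classification
                "C" = "exact",
                stop("`col_step` must be \"approx\" (A), \"exact\" (C) or \"stochastic\" (S)"))
  key
}

.variant_code <- function(row_step, col_step) {
  paste0(switch(row_step, classification = "C", stochastic = "S"), ",",
         switch(col_step, exact = "C", approx = "A", stochastic = "S"))
}

# One run from one random start: G uniform over labels, a random centroid
# matrix mu, F by one row step against (mu, G), so that all three random
# starting objects shape the trajectory.  Two standard random-centroid
# families are used on alternating restarts to diversify the basins
# explored: Forgy-style exemplars (block profiles of K data rows drawn at
# random, so every row cluster is represented with probability proportional
# to its size) and moment-matched Gaussian draws.  `kernel0` carries the
# factored correlation at the fit's phi; tau is rescaled in place each
# iteration (cheap).
.fit_single <- function(X, kernel0, K, R, row_step, col_step,
                        rel_tol, patience, max_iter, seed,
                        init = c("exemplar", "gaussian")) {
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X); p <- ncol(X)
  kern <- kernel_tau(kernel0, 1)
  g <- sample.int(R, p, replace = TRUE)
  if (init == "exemplar") {
    Gd <- as_indicator(g, R)
    rows <- X[sample.int(n, K, replace = K > n), , drop = FALSE]
    mu <- sweep(rows %*% Gd, 2L, pmax(colSums(Gd), 1), "/")
  } else {
    s <- stats::sd(X)
    if (!is.finite(s) || s == 0) s <- 1
    mu <- matrix(stats::rnorm(K * R, mean(X), s), K, R)
  }
  f <- switch(row_step,
    classification = update_rows(X, mu, g, kern),
    stochastic     = update_rows_stochastic(X, mu, g, kern))
  mu <- update_centroids(X, f, g, kern, K, R, mu_prev = mu)
  degenerate <- FALSE
  tau <- update_tau(X, f, g, mu, kern)
  if (tau < .TAU_FLOOR) { tau <- .TAU_FLOOR; degenerate <- TRUE }
  kern <- kernel_tau(kern, tau)

  loss <- cocluster_loss(X, f, g, mu, kern)
  pen <- loss + n * kern$log_det_sigma
  trace <- list(data.frame(iter = 0L, loss = loss, penalized = pen,
                           tau = tau, changed = NA))
  best <- list(f = f, g = g, mu = mu, tau = tau, loss = loss, penalized = pen)
  pen_prev <- pen
  stable <- 0L
  converged <- FALSE
  n_iter <- 0L

  for (it in seq_len(max_iter)) {
    mu <- update_centroids(X, f, g, kern, K, R, mu_prev = mu)
    f_new <- switch(row_step,
      classification = update_rows(X, mu, g, kern),
      stochastic     = update_rows_stochastic(X, mu, g, kern))
    g_new <- switch(col_step,
      exact      = update_cols_exact(X, f_new, mu, g, kern),
      approx     = update_cols_approx(X, f_new, mu),
      stochastic = update_cols_stochastic(X, f_new, mu, g, kern))
    tau <- update_tau(X, f_new, g_new, mu, kern)
    if (tau < .TAU_FLOOR) { tau <- .TAU_FLOOR; degenerate <- TRUE }
    kern <- kernel_tau(kern, tau)

    loss <- cocluster_loss(X, f_new, g_new, mu, kern)
    pen <- loss + n * kern$log_det_sigma
    changed <- any(f_new != f) || any(g_new != g)
    f <- f_new; g <- g_new
    n_iter <- it
    trace[[it + 1L]] <- data.frame(iter = it, loss = loss, penalized = pen,
                                   tau = tau, changed = changed)

    if (pen <= best$penalized)
      best <- list(f = f, g = g, mu = mu, tau = tau, loss = loss,
                   penalized = pen)

    # Stop when an iteration changes the penalized loss by less than rel_tol
    # in relative terms (for the exact variant the change is a decrement, so
    # this is the classic relative-decrement rule), or when the labels have
    # been stable for `patience` iterations.
    if (abs(pen - pen_prev) / max(abs(pen_prev), 1) < rel_tol)
      converged <- TRUE
    pen_prev <- pen
    stable <- if (changed) 0L else stable + 1L
    if (stable >= patience) converged <- TRUE
    if (converged) break
  }

  list(f = best$f, g = best$g, mu = best$mu, tau = best$tau,
       loss = best$loss, penalized = best$penalized,
       trace = do.call(rbind, trace), n_iter = n_iter,
       converged = converged, degenerate = degenerate)
}

#' Fit a spatially informed coclustering model
#'
#' Minimizes \eqn{\|(X - F\mu G')(L^{-1})'\|_F^2} over the row indicator F
#' (n x K), the centroid matrix \eqn{\mu} (K x R, real-valued), the column
#' indicator G (p x R) and the marginal variance \eqn{\tau} of
#' \eqn{\Sigma = \tau K(S;\phi)}, with the kernel scale \eqn{\phi} held fixed
#' during a fit.  Iterates centroid update, row step, column step and the
#' closed-form \eqn{\tau} update from \code{n_restarts} random starting
#' points and returns the best run by penalized loss.
#'
#' The row step is the exact classification rule (\code{"classification"})
#' or a stochastic-EM draw (\code{"stochastic"}).  The column step is the
#' exact sequential rule (\code{"exact"}, loss-monotone but O(p) conditional
#' updates per sweep), the fast parallel approximation (\code{"approx"},
#' recommended default), or the stochastic-EM draw (\code{"stochastic"}).
#' For the non-monotone variants the minimum-penalized-loss state visited
#' during the run is returned, not the final state.
#'
#' Convergence is declared when an iteration changes the penalized loss by
#' less than \code{rel_tol} in relative terms, or when the labels are
#' unchanged for \code{patience} consecutive iterations, or at
#' \code{max_iter}.
#'
#' Start with generous K and R and let unneeded clusters empty: the number
#' of nonempty clusters (reported in the result) is the estimated number of
#' clusters.
#'
#' @param X numeric n x p matrix: n signals measured over p pixels.  For raw
#'   nonnegative abundances apply [log_transform()] first.
#' @param coords p x 2 matrix or data frame of pixel coordinates (column
#'   order of X).  May be \code{NULL} if \code{kernel} is supplied or
#'   \code{spatial = FALSE}-style identity fitting is wanted.
#' @param K,R numbers of fitted row and column clusters.
#' @param phi fixed kernel scale, in coordinate units.  Use [spnmtf_grid()]
#'   to compare several values.
#' @param row_step \code{"classification"} or \code{"stochastic"} (initial
#'   letter, or the letter code C/S).
#' @param col_step \code{"approx"}, \code{"exact"} or \code{"stochastic"}
#'   (codes A/C/S accepted).
#' @param n_restarts number of independent random starts.
#' @param rel_tol relative loss-improvement threshold (default 0.1\%).
#' @param patience iterations with unchanged labels declaring convergence.
#' @param max_iter hard iteration cap per restart.
#' @param seed integer master seed; restart r runs under \code{seed + r}.
#'   \code{NULL} leaves the RNG state alone (non-reproducible).
#' @param kernel optional pre-factored \code{"spnmtf_kernel"} (its tau is
#'   ignored; tau is estimated).  Overrides \code{coords}/\code{phi}.
#' @param jitter diagonal jitter policy for the kernel factorization.
#' @return an object of class \code{"spnmtf"}; see Details.  Key elements:
#'   \code{F}, \code{G} (label vectors), \code{mu}, \code{tau}, \code{phi},
#'   \code{loss}, \code{penalized_loss}, \code{trace}, \code{n_iter},
#'   \code{converged}, \code{nonempty_row}, \code{nonempty_col},
#'   \code{restart_losses}, \code{variant}, \code{runtime}.
#' @examples
#' sim <- spnmtf_sim(n = 30, p = 36, K = 2, R = 2, seed = 1)
#' fit <- spnmtf(sim$X, sim$coords, K = 2, R = 2, phi = sim$phi,
#'               n_restarts = 5, seed = 1)
#' concordance(fit$G, sim$G)
#' @export
spnmtf <- function(X, coords = NULL, K, R, phi = 1,
                   row_step = c("classification", "stochastic"),
                   col_step = c("approx", "exact", "stochastic"),
                   n_restarts = 50, rel_tol = 1e-3, patience = 5,
                   max_iter = 100, seed = NULL, kernel = NULL,
                   jitter = 1e-8) {
  t0 <- proc.time()[["elapsed"]]
  cl <- match.call()
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("`X` contains non-finite values")
  n <- nrow(X); p <- ncol(X)
  K <- as.integer(K); R <- as.integer(R)
  if (K < 1L || R < 1L) stop("`K` and `R` must be >= 1")
  if (K > n || R > p)
    warning("more fitted clusters than units (K > n or R > p)")
  row_step <- .match_row_step(row_step)
  col_step <- .match_col_step(col_step)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1")
  if (!(rel_tol > 0 && rel_tol < 1)) stop("`rel_tol` must be in (0, 1)")

  if (is.null(kernel)) {
    if (is.null(coords)) {
      kernel <- identity_kernel(p)
      phi <- NA_real_
    } else {
      kernel <- spatial_kernel(coords, phi, tau = 1, jitter = jitter)
    }
  } else {
    stopifnot(inherits(kernel, "spnmtf_kernel"))
    phi <- kernel$phi
  }
  if (kernel$p != p)
    stop("kernel/coordinates describe ", kernel$p, " pixels but X has ", p,
         " columns")

  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    runs[[r]] <- .fit_single(X, kernel, K, R, row_step, col_step,
                             rel_tol, patience, max_iter,
                             seed = if (is.null(seed)) NULL else seed + r,
                             init = if (r %% 2L) "exemplar" else "gaussian")
  }
  restart_losses <- vapply(runs, `[[`, numeric(1), "penalized")
  best_i <- which.min(restart_losses)
  best <- runs[[best_i]]
  if (best$degenerate)
    warning("estimated marginal variance fell below ", format(.TAU_FLOOR),
            " and was clamped: degenerate (near-exact) fit")

  structure(list(
    F = best$f, G = best$g, mu = best$mu, tau = best$tau, phi = phi,
    K = K, R = R,
    loss = best$loss, penalized_loss = best$penalized,
    trace = best$trace, n_iter = best$n_iter, converged = best$converged,
    degenerate = best$degenerate,
    nonempty_row = count_nonempty(best$f),
    nonempty_col = count_nonempty(best$g),
    restart_losses = restart_losses,
    restart_raw_losses = vapply(runs, `[[`, numeric(1), "loss"),
    best_restart = best_i,
    variant = .variant_code(row_step, col_step),
    row_step = row_step, col_step = col_step,
    n = n, p = p,
    X = X, coords = if (is.null(coords)) NULL else .validate_coords(coords),
    seed = seed, rel_tol = rel_tol, patience = patience, max_iter = max_iter,
    runtime = proc.time()[["elapsed"]] - t0,
    call = cl
  ), class = "spnmtf")
}

#' Fit over a grid of kernel scales
#'
#' Runs [spnmtf()] once per value of \code{phi} and tabulates, per scale:
#' variant, raw and penalized loss of the best run, iterations, estimated
#' \eqn{\tau}, and nonempty row/column cluster counts.  The selected model
#' minimizes the penalized loss across the grid (the penalized loss is the
#' negative profile log-likelihood up to a constant, so it is comparable
#' across scales; the raw loss is not, because the \eqn{\log|\Sigma|} term
#' changes with \eqn{\phi}).  Set \code{select = "raw"} to rank on the raw
#' loss instead.
#'
#' @inheritParams spnmtf
#' @param phi numeric vector of kernel scales to compare.
#' @param select \code{"penalized"} (default) or \code{"raw"}.
#' @param ... passed on to [spnmtf()].
#' @return an object of class \code{"spnmtf_grid"}: list with \code{table}
#'   (one row per scale), \code{fits}, \code{best} (index of the selected
#'   row) and \code{select}.
#' @export
spnmtf_grid <- function(X, coords, K, R, phi,
                        select = c("penalized", "raw"), ...) {
  select <- match.arg(select)
  phi <- as.numeric(phi)
  if (length(phi) < 1L) stop("`phi` grid is empty")
  fits <- lapply(phi, function(ph)
    spnmtf(X, coords, K = K, R = R, phi = ph, ...))
  table <- data.frame(
    phi = phi,
    variant = vapply(fits, `[[`, character(1), "variant"),
    loss = vapply(fits, `[[`, numeric(1), "loss"),
    penalized_loss = vapply(fits, `[[`, numeric(1), "penalized_loss"),
    n_iter = vapply(fits, `[[`, integer(1), "n_iter"),
    tau = vapply(fits, `[[`, numeric(1), "tau"),
    nonempty_row = vapply(fits, `[[`, integer(1), "nonempty_row"),
    nonempty_col = vapply(fits, `[[`, integer(1), "nonempty_col"),
    runtime = vapply(fits, `[[`, numeric(1), "runtime")
  )
  best <- if (select == "penalized") which.min(table$penalized_loss)
          else which.min(table$loss)
  structure(list(table = table, fits = fits, best = best, select = select),
            class = "spnmtf_grid")
}

#' @export
print.spnmtf_grid <- function(x, ...) {
  cat("Kernel-scale grid search (", nrow(x$table), " values of phi)\n\n",
      sep = "")
  print(x$table, row.names = FALSE, digits = 5)
  cat("\nSelected (min ", x$select, " loss): phi = ",
      format(x$table$phi[x$best]), "\n", sep = "")
  invisible(x)
}
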