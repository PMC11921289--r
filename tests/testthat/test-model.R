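test_that("whitened-Frobenius loss agrees with the explicit trace form", {
  set.seed(41)
  inst <- random_instance(6, 8, 2, 3)
  l1 <- cocluster_loss(inst$X, inst$f, inst$g, inst$mu, inst$kernel)
  l2 <- oracle_loss(inst$X, inst$f, inst$g, inst$mu, sigma_of(inst$kernel))
  expect_equal(l1, l2, tolerance = 1e-8)

  # exact reconstruction gives zero loss
  Xe <- inst$mu[inst$f, inst$g]
  expect_equal(cocluster_loss(Xe, inst$f, inst$g, inst$mu, inst$kernel), 0)

  # Sigma = I reduces to the plain Frobenius loss
  E <- inst$X - inst$mu[inst$f, inst$g]
  expect_equal(cocluster_loss(inst$X, inst$f, inst$g, inst$mu,
                              identity_kernel(8)),
               sum(E^2))
  expect_equal(cocluster_loss(inst$X, inst$f, inst$g, inst$mu, NULL),
               sum(E^2))
})

test_that("penalized loss adds n log|Sigma|", {
  # tau = 4, correlation = I, p = 3, n = 2: penalty = 2 log(4^3)
  X <- matrix(c(1, 0, -1, 2, 0.5, 1), 2, 3)
  mu <- matrix(0, 1, 1)
  kern <- identity_kernel(3, tau = 4)
  expect_equal(penalized_loss(X, c(1, 1), c(1, 1, 1), mu, kern) -
                 cocluster_loss(X, c(1, 1), c(1, 1, 1), mu, kern),
               2 * log(4^3))
  # identity kernel: penalty vanishes
  kern1 <- identity_kernel(3)
  expect_equal(penalized_loss(X, c(1, 1), c(1, 1, 1), mu, kern1),
               cocluster_loss(X, c(1, 1), c(1, 1, 1), mu, kern1))
})

test_that("centroid update gives block means under the identity kernel", {
  set.seed(42)
  X <- matrix(rnorm(7 * 9), 7, 9)
  f <- sample.int(2, 7, replace = TRUE)
  g <- sample.int(3, 9, replace = TRUE)
  mu <- update_centroids(X, f, g, NULL, 2, 3)
  for (k in 1:2) for (r in 1:3)
    expect_equal(mu[k, r], mean(X[f == k, g == r, drop = FALSE]))

  # K = R = 1: grand mean
  expect_equal(update_centroids(X, rep(1L, 7), rep(1L, 9), NULL, 1, 1)[1, 1],
               mean(X))
})

test_that("centroid update minimizes the loss given the labels", {
  set.seed(43)
  for (rep in 1:5) {
    inst <- random_instance(6, 7, 2, 3)
    before <- cocluster_loss(inst$X, inst$f, inst$g, inst$mu, inst$kernel)
    mu_new <- update_centroids(inst$X, inst$f, inst$g, inst$kernel, 2, 3,
                               mu_prev = inst$mu)
    after <- cocluster_loss(inst$X, inst$f, inst$g, mu_new, inst$kernel)
    expect_lte(after, before + 1e-10)

    # stationarity: numeric gradient ~ 0 at the update
    eps <- 1e-5
    for (idx in list(c(1, 1), c(2, 3))) {
      bump <- matrix(0, 2, 3); bump[idx[1], idx[2]] <- eps
      up <- cocluster_loss(inst$X, inst$f, inst$g, mu_new + bump, inst$kernel)
      dn <- cocluster_loss(inst$X, inst$f, inst$g, mu_new - bump, inst$kernel)
      expect_lt(abs(up - dn) / (2 * eps), 1e-4)
    }
  }
})

test_that("centroid update handles empty clusters by freezing their centroids", {
  set.seed(44)
  X <- matrix(rnorm(30), 5, 6)
  f <- c(1L, 1L, 2L, 2L, 2L)              # cluster 3 of K = 3 empty
  g <- c(1L, 1L, 2L, 2L, 2L, 2L)          # cluster 3 of R = 3 empty
  prev <- matrix(99, 3, 3)
  mu <- update_centroids(X, f, g, NULL, 3, 3, mu_prev = prev)
  expect_equal(mu[3, ], rep(99, 3))
  expect_equal(mu[, 3], rep(99, 3))
  for (k in 1:2) for (r in 1:2)
    expect_equal(mu[k, r], mean(X[f == k, g == r, drop = FALSE]))
})

test_that("row classification matches exhaustive full-loss assignment", {
  expect_equal(update_rows(matrix(rnorm(12), 3, 4),
                           matrix(0, 1, 2), rep(1:2, 2), NULL),
               rep(1L, 3))   # K = 1

  set.seed(45)
  for (rep in 1:8) {
    inst <- random_instance(5, 6, 3, 2)
    got <- update_rows(inst$X, inst$mu, inst$g, inst$kernel)
    want <- oracle_rows(inst$X, inst$f, inst$g, inst$mu, sigma_of(inst$kernel))
    expect_equal(got, want)
    # the update never increases the loss
    expect_lte(cocluster_loss(inst$X, got, inst$g, inst$mu, inst$kernel),
               cocluster_loss(inst$X, inst$f, inst$g, inst$mu, inst$kernel) +
                 1e-10)
  }
})

test_that("a row lying exactly on a centroid profile gets that cluster", {
  set.seed(46)
  inst <- random_instance(4, 5, 3, 2)
  Gt <- whiten_indicator(inst$g, inst$kernel)
  # construct row 2 so that its whitened profile equals centroid 3's
  profile <- drop(inst$mu[3, , drop = FALSE] %*% t(Gt))
  X <- inst$X
  X[2, ] <- profile %*% t(inst$kernel$chol_lower)
  expect_equal(update_rows(X, inst$mu, inst$g, inst$kernel)[2], 3L)
})

test_that("stochastic row update has the right categorical distribution", {
  set.seed(47)
  # dominant cluster: criterion smaller by far more than log(1e16)
  X <- matrix(5, 2, 3)
  mu <- matrix(c(5, -500), 2, 1)          # cluster 1 fits exactly
  g <- rep(1L, 3)
  draws <- replicate(50, update_rows_stochastic(X, mu, g, NULL))
  expect_true(all(draws == 1L))

  # identical centroids: uniform over K = 3
  mu3 <- matrix(1, 3, 1)
  X1 <- matrix(rnorm(4), 1, 4)
  draws <- replicate(10000, update_rows_stochastic(X1, mu3, rep(1L, 4), NULL))
  freq <- tabulate(draws, 3) / 10000
  expect_true(all(abs(freq - 1 / 3) < 0.02))

  # deterministic under a fixed seed
  inst <- random_instance(6, 5, 3, 2, seed = 470)
  set.seed(99); a <- update_rows_stochastic(inst$X, inst$mu, inst$g, inst$kernel)
  set.seed(99); b <- update_rows_stochastic(inst$X, inst$mu, inst$g, inst$kernel)
  expect_identical(a, b)
})

test_that("exact column sweep matches the sequential brute-force oracle", {
  set.seed(48)
  # R = 1: nothing to move
  inst1 <- random_instance(4, 5, 2, 1)
  expect_equal(update_cols_exact(inst1$X, inst1$f, inst1$mu, inst1$g,
                                 inst1$kernel),
               inst1$g)

  for (rep in 1:6) {
    inst <- random_instance(4, 6, 2, 3)
    got <- update_cols_exact(inst$X, inst$f, inst$mu, inst$g, inst$kernel)
    want <- oracle_cols_sequential(inst$X, inst$f, inst$g, inst$mu,
                                   sigma_of(inst$kernel))
    expect_equal(got, want)
    expect_lte(cocluster_loss(inst$X, inst$f, got, inst$mu, inst$kernel),
               cocluster_loss(inst$X, inst$f, inst$g, inst$mu, inst$kernel) +
                 1e-10)
  }

  # with Sigma = I the sweep equals sequential brute force on the plain loss
  inst <- random_instance(5, 7, 2, 3)
  kernI <- identity_kernel(7)
  expect_equal(update_cols_exact(inst$X, inst$f, inst$mu, inst$g, kernI),
               oracle_cols_sequential(inst$X, inst$f, inst$g, inst$mu,
                                      diag(7)))
})

test_that("approximate column update is the per-column nearest composite centroid", {
  set.seed(49)
  for (rep in 1:6) {
    inst <- random_instance(6, 5, 2, 3)
    expect_equal(update_cols_approx(inst$X, inst$f, inst$mu),
                 oracle_cols_approx(inst$X, inst$f, inst$mu))
  }
  # a column equal to F mu_{.,r} is assigned r
  inst <- random_instance(6, 5, 2, 3)
  X <- inst$X
  X[, 4] <- inst$mu[inst$f, 2]
  expect_equal(update_cols_approx(X, inst$f, inst$mu)[4], 2L)
})

test_that("exact and approximate column steps agree on a separable identity-kernel instance", {
  set.seed(50)
  mu <- matrix(c(0, 10, 10, 0, -10, 5), 2, 3)
  f <- rep(1:2, each = 4)
  g_true <- rep(1:3, times = c(3, 3, 3))
  X <- mu[f, g_true] + matrix(rnorm(8 * 9, sd = 0.05), 8, 9)
  kernI <- identity_kernel(9)
  g0 <- sample.int(3, 9, replace = TRUE)
  ga <- update_cols_approx(X, f, mu)
  ge <- g0
  for (s in 1:5) ge <- update_cols_exact(X, f, mu, ge, kernI)
  expect_equal(ge, ga)
  expect_equal(ga, g_true)
})

test_that("stochastic column update draws from the full-loss softmax", {
  set.seed(51)
  # dominated candidates: the exact choice is drawn with probability ~ 1
  mu <- matrix(c(0, 1000), 1, 2)
  X <- matrix(0, 2, 4)
  kern <- identity_kernel(4)
  draws <- replicate(30, update_cols_stochastic(X, c(1L, 1L), mu,
                                                rep(2L, 4), kern))
  expect_true(all(draws == 1L))

  # all candidates tied: empirical frequencies ~ 1/R
  muT <- matrix(c(2, 2, 2), 1, 3)
  X1 <- matrix(rnorm(2), 2, 1)
  kern1 <- identity_kernel(1)
  draws <- replicate(9000, update_cols_stochastic(X1, c(1L, 1L), muT,
                                                  1L, kern1))
  freq <- tabulate(draws, 3) / 9000
  expect_true(all(abs(freq - 1 / 3) < 0.025))

  # bitwise-identical sweeps under the same seed
  inst <- random_instance(5, 6, 2, 3, seed = 510)
  set.seed(7); a <- update_cols_stochastic(inst$X, inst$f, inst$mu, inst$g,
                                           inst$kernel)
  set.seed(7); b <- update_cols_stochastic(inst$X, inst$f, inst$mu, inst$g,
                                           inst$kernel)
  expect_identical(a, b)
})

test_that("the tau update is the stationary minimum of the penalized loss", {
  # zero residual
  set.seed(52)
  inst <- random_instance(4, 5, 2, 2)
  Xe <- inst$mu[inst$f, inst$g]
  expect_equal(update_tau(Xe, inst$f, inst$g, inst$mu, inst$kernel), 0)

  # scalar case: n = p = 1, unit correlation, residual e -> tau = e^2
  kern1 <- identity_kernel(1)
  X1 <- matrix(2.5, 1, 1)
  mu1 <- matrix(1, 1, 1)
  expect_equal(update_tau(X1, 1L, 1L, mu1, kern1), 1.5^2)

  # grid-scan oracle: penalized loss over tau is minimized at the update
  for (rep in 1:5) {
    inst <- random_instance(5, 6, 2, 3)
    tau_hat <- update_tau(inst$X, inst$f, inst$g, inst$mu, inst$kernel)
    pen_at <- function(tau) {
      kern <- kernel_tau(inst$kernel, tau)
      penalized_loss(inst$X, inst$f, inst$g, inst$mu, kern)
    }
    grid <- tau_hat * exp(seq(-0.5, 0.5, length.out = 201))
    expect_equal(grid[which.min(vapply(grid, pen_at, numeric(1)))],
                 tau_hat, tolerance = 5e-3)
    # 1-D numeric minimizer agrees to 4 significant digits
    opt <- stats::optimize(pen_at, c(tau_hat / 10, tau_hat * 10))$minimum
    expect_equal(opt, tau_hat, tolerance = 1e-4)
  }
})
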