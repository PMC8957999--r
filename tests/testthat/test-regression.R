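# Kernel regressors: RBF Gram properties, eps-SVR, LAD-SVR and grid search.

test_that("RBF Gram matrices are symmetric PSD with unit diagonal", {
  for (s in 1:5) {
    X <- with_seed(s, matrix(rnorm(20 * 3), 20L))
    K <- rbf_kernel(X, X, sigma = 1.3)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_equal(diag(K), rep(1, 20L))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(rbf_kernel(matrix(1, 2, 2), matrix(1, 2, 2), sigma = 0), "positive")
})

test_that("eps-SVR: flat data, tube fitting and dual feasibility", {
  X <- matrix(seq(0, 1, length.out = 20L), ncol = 1L)
  m <- fit_svr(X, rep(3.7, 20L), epsilon = 0.1, C = 10, sigma = 0.5)
  expect_equal(predict(m, X), rep(3.7, 20L), tolerance = 1e-6)

  # noise-free smooth target, tiny tube, large C -> training RMSE <= eps + 1e-3
  y <- sin(2 * pi * X[, 1L])
  m2 <- fit_svr(X, y, epsilon = 1e-3, C = 1e4, sigma = 0.3, tolerance = 1e-7)
  rmse <- sqrt(mean((predict(m2, X) - y)^2))
  expect_lte(rmse, 1e-3 + 1e-3)
  # dual coefficients live in the box [-C, C]
  expect_lte(max(abs(m2$coefficients)), 1e4 + 1e-6)
})

test_that("predictions are the explicit kernel expansion", {
  with_seed(10, {
    X <- matrix(rnorm(30 * 2), 30L)
    y <- X[, 1L]^2 + rnorm(30, 0, 0.1)
  })
  m <- fit_svr(X, y, epsilon = 0.05, C = 5, sigma = 1)
  Xn <- matrix(rnorm(10 * 2), 10L)
  manual <- as.vector(rbf_kernel(Xn, m$support, m$sigma) %*% m$coefficients) +
    m$bias
  expect_equal(predict(m, Xn), manual, tolerance = 1e-10)
  # duplicate rows give duplicate predictions
  Xd <- Xn[c(1, 1, 2, 2), ]
  pd <- predict(m, Xd)
  expect_identical(pd[1L], pd[2L])
  expect_identical(pd[3L], pd[4L])
  expect_error(predict(m, Xn[, 1L, drop = FALSE]), "dimension mismatch")
})

test_that("both kernel fitters are invariant to row permutation", {
  with_seed(11, {
    X <- matrix(rnorm(40 * 2), 40L)
    y <- sin(X[, 1L]) + 0.1 * rnorm(40)
    perm <- sample(40L)
  })
  grid_pts <- matrix(seq(-2, 2, length.out = 15L), ncol = 1L)
  Xg <- cbind(grid_pts, 0)
  m1 <- fit_svr(X, y, 0.1, 10, 1, tolerance = 1e-9)
  m2 <- fit_svr(X[perm, ], y[perm], 0.1, 10, 1, tolerance = 1e-9)
  expect_lt(max(abs(predict(m1, Xg) - predict(m2, Xg))), 1e-8)
  l1 <- fit_lad_svr(X, y, C = 10, sigma = 1)
  l2 <- fit_lad_svr(X[perm, ], y[perm], C = 10, sigma = 1)
  expect_lt(max(abs(predict(l1, Xg) - predict(l2, Xg))), 1e-8)
})

test_that("LAD-SVR: zero targets, monotone Newton descent, gradient exit", {
  X <- with_seed(12, matrix(rnorm(15 * 2), 15L))
  m0 <- fit_lad_svr(X, rep(0, 15L), C = 3, sigma = 1)
  expect_equal(m0$coefficients, rep(0, 15L))
  expect_equal(m0$bias, 0)

  with_seed(13, {
    Xr <- matrix(runif(35 * 2), 35L)
    yr <- Xr[, 1L] - 2 * Xr[, 2L] + 0.2 * rnorm(35)
  })
  m <- fit_lad_svr(Xr, yr, C = 8, sigma = 0.7)
  expect_true(all(diff(m$objective_trace) <= 1e-10))
  # gradient norm at the solution is below tolerance
  K <- rbf_kernel(Xr, Xr, 0.7)
  r <- yr - as.vector(K %*% m$coefficients) - m$bias
  psi <- pmax(pmin(r, m$delta), -m$delta)
  g <- c(as.vector(K %*% (m$coefficients - m$C * psi)), -m$C * sum(psi))
  expect_lt(max(abs(g)), 1e-5)
  expect_error(fit_lad_svr(Xr, yr, C = 1, sigma = 1, delta = 0), "delta")
})

test_that("grid search: singleton grid, determinism and bandwidth recovery", {
  with_seed(14, {
    X <- matrix(runif(60), ncol = 1L)
    y <- sin(4 * X[, 1L]) + 0.1 * rnorm(60)
  })
  g1 <- grid_search_cv(fit_svr, X, y,
                       expand.grid(epsilon = 0.1, C = 10, sigma = 0.5),
                       seed = 1L)
  expect_equal(g1$best$C, 10)
  expect_equal(g1$best$sigma, 0.5)
  grid <- expand.grid(epsilon = 0.1, C = c(1, 10), sigma = c(0.1, 0.5, 2))
  g2 <- grid_search_cv(fit_svr, X, y, grid, seed = 5L)
  g3 <- grid_search_cv(fit_svr, X, y, grid, seed = 5L)
  expect_identical(g2$best, g3$best)
  expect_identical(g2$folds, g3$folds)
  expect_error(grid_search_cv(fit_svr, X, y, grid[0, ], seed = 1L), "empty")

  # the CV winner's bandwidth tracks an oracle validated on independent data
  sig_grid <- c(0.05, 0.15, 0.45, 1.35, 4)
  agree <- 0L
  reps <- 30L
  for (r in seq_len(reps)) {
    with_seed(3000 + r, {
      Xtr <- matrix(runif(60), ncol = 1L)
      ytr <- sin(4 * Xtr[, 1L]) + 0.15 * rnorm(60)
      Xva <- matrix(runif(300), ncol = 1L)
      yva <- sin(4 * Xva[, 1L]) + 0.15 * rnorm(300)
    })
    gg <- grid_search_cv(fit_svr, Xtr, ytr,
                         expand.grid(epsilon = 0.1, C = 10, sigma = sig_grid),
                         seed = 3000 + r)
    val_err <- vapply(sig_grid, function(sg) {
      mm <- fit_svr(Xtr, ytr, 0.1, 10, sg)
      mean((yva - predict(mm, Xva))^2)
    }, 0)
    best_oracle <- which.min(val_err)
    best_cv <- match(gg$best$sigma, sig_grid)
    agree <- agree + (abs(best_cv - best_oracle) <= 1L)
  }
  expect_gte(agree / reps, 0.8)
})
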