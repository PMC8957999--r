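# Statistical machinery: Friedman, one-sided Wilcoxon, Pearson, size
# accuracy, improvement summary and sample-size calculation.

test_that("Friedman: degenerate, hand-computed and base-R cross-checks", {
  m <- matrix(rep(c(2, 5, 7, 1), times = 3L), 4L)   # identical columns
  f <- friedman_test(m)
  expect_equal(f$statistic[["chisq"]], 0)
  expect_equal(f$p.value, 1)

  # hand-computed tie-free example: ranks per row known, statistic =
  # 12/(nk(k+1)) * sum Rj^2 - 3n(k+1) with n = 4, k = 3
  x <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(1, 2, 3))
  R <- c(1 + 1 + 2 + 1, 2 + 3 + 1 + 2, 3 + 2 + 3 + 3)
  hand <- 12 / (4 * 3 * 4) * sum(R^2) - 3 * 4 * 4
  f2 <- friedman_test(x, exact = FALSE)
  expect_equal(unname(f2$statistic), hand, tolerance = 1e-12)
  expect_equal(f2$p.value, pchisq(hand, 2, lower.tail = FALSE))
  # base-R agreement on tie-free data
  with_seed(1, {
    y <- matrix(rnorm(8 * 4), 8L)
  })
  fr <- stats::friedman.test(y)
  mine <- friedman_test(y, exact = FALSE)
  expect_equal(unname(mine$statistic), unname(fr$statistic), tolerance = 1e-10)
  expect_equal(mine$p.value, fr$p.value, tolerance = 1e-10)
})

test_that("Friedman exact mode matches a brute-force permutation oracle", {
  with_seed(2, {
    m <- matrix(rnorm(4 * 3), 4L)
  })
  mine <- friedman_test(m, exact = TRUE)
  # oracle: enumerate all within-row permutations, computing each statistic
  # through stats::friedman.test (an independent implementation)
  perms <- kneeplan:::all_permutations(3L)
  combos <- expand.grid(rep(list(seq_len(nrow(perms))), 4L))
  obs <- unname(stats::friedman.test(m)$statistic)
  stats_all <- apply(combos, 1L, function(idx) {
    mm <- m
    for (i in 1:4) mm[i, ] <- m[i, perms[idx[i], ]]
    unname(stats::friedman.test(mm)$statistic)
  })
  p_oracle <- mean(stats_all >= obs - 1e-12)
  expect_equal(mine$p.value, p_oracle, tolerance = 1e-6)
})

test_that("one-sided Wilcoxon: degenerate, exact and approximate branches", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_warning(p <- wilcoxon_one_sided(a, a), "zero")
  expect_equal(p, 1)
  expect_error(wilcoxon_one_sided(a, a + c(1, 0, 0, 0, 0, 0)), "at least 5")

  # uniformly smaller by a constant, n = 20 -> W = 0, normal approximation
  # closed form: z = (0 - n(n+1)/4 + 1/2) / sqrt(n(n+1)(2n+1)/24)
  n <- 20L
  a2 <- seq_len(n); b2 <- a2 + seq(1, 3, length.out = n)  # distinct |d|
  z <- (0 - n * (n + 1) / 4 + 0.5) / sqrt(n * (n + 1) * (2 * n + 1) / 24)
  expect_equal(wilcoxon_one_sided(a2, b2), pnorm(z), tolerance = 1e-10)

  # n <= 12, no ties: exact enumeration over all 2^n sign assignments
  for (s in 1:5) {
    d <- with_seed(50 + s, round(rnorm(10L, -0.3, 1), 3))
    d <- d[d != 0]
    n1 <- length(d)
    W_obs <- sum(rank(abs(d))[d > 0])
    signs <- expand.grid(rep(list(c(0L, 1L)), n1))
    r <- rank(abs(d))
    W_all <- as.matrix(signs) %*% r
    p_oracle <- mean(W_all <= W_obs)
    expect_equal(wilcoxon_one_sided(d, rep(0, n1)), p_oracle, tolerance = 1e-6)
  }
  # sanity bound: the two one-sided p-values cannot both be small
  with_seed(3, {
    x <- rnorm(15L); y <- rnorm(15L)
  })
  expect_gte(wilcoxon_one_sided(x, y) + wilcoxon_one_sided(y, x), 1 - 1e-9)
})

test_that("Friedman statistic is invariant under monotone row transforms", {
  with_seed(4, {
    m <- matrix(rexp(6 * 4), 6L)
  })
  f1 <- friedman_test(m, exact = FALSE)
  m2 <- t(apply(m, 1L, function(r) exp(2 * r) + 7))   # strictly monotone
  f2 <- friedman_test(m2, exact = FALSE)
  expect_equal(f1$statistic, f2$statistic, tolerance = 1e-12)
})

test_that("Pearson correlation: closed forms, formula recompute and errors", {
  x <- c(1, 2, 4, 8)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  with_seed(5, {
    u <- rnorm(50L); v <- rnorm(50L)
  })
  manual <- sum((u - mean(u)) * (v - mean(v))) /
    sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  expect_equal(pearson(u, v), manual, tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "constant")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("size accuracy counts exact per-component matches", {
  p1 <- random_plan(1); p2 <- random_plan(2)
  make <- function(p, fs, ts) {
    v <- unclass(p); v["femur_size"] <- fs; v["tibia_size"] <- ts
    implant_plan(v)
  }
  pred <- list(make(p1, 3, 4), make(p1, 2, 5), make(p2, 6, 1), make(p2, 0, 2))
  true <- list(make(p1, 3, 4), make(p1, 3, 5), make(p2, 6, 1), make(p2, 1, 2))
  acc <- size_accuracy(pred, true)
  expect_equal(unname(acc["femoral"]), 50)
  expect_equal(unname(acc["tibial"]), 100)
  expect_equal(unname(size_accuracy(true, true)), c(100, 100))
  expect_error(size_accuracy(list(), list()), "empty")
  # brute-force recount on random plan lists
  pr <- lapply(1:30, function(s) random_plan(s))
  tr <- lapply(1:30, function(s) random_plan(s + 100))
  acc2 <- size_accuracy(pr, tr)
  fem <- mean(vapply(1:30, function(i)
    unclass(pr[[i]])[["femur_size"]] == unclass(tr[[i]])[["femur_size"]], TRUE))
  expect_equal(unname(acc2["femoral"]), 100 * fem)
})

test_that("improvement is averaged across surgeons, not pooled", {
  imp <- improvement_summary(mpp_means = c(10, 10), app_means = c(8, 4))
  expect_equal(imp$per_surgeon, c(20, 60))
  expect_equal(imp$mean, 40)
  expect_equal(imp$sd, sd(c(20, 60)))
  expect_equal(imp$sd, 28.28, tolerance = 1e-3)
  same <- improvement_summary(c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$mean, 0); expect_equal(same$sd, 0)
  expect_message(z <- improvement_summary(c(0, 10), c(0, 5)), "zero MPP")
  expect_equal(z$per_surgeon, c(0, 50))
  # single surgeon: the summary is that surgeon's own improvement
  one <- improvement_summary(8, 2)
  expect_equal(one$mean, 75); expect_equal(one$sd, 0)
})

test_that("sample size: hand-computed value, scaling and monotonicity", {
  # canonical normal-approximation case: sigma = 1 both, delta = 0.5,
  # alpha = 0.05 two-sided, power 0.8 -> 63 per group
  r <- sample_size_two_means(0, 1, 0.5, 1, alpha = 0.05, power = 0.8)
  hand <- (qnorm(0.975) + qnorm(0.8))^2 * 2 / 0.25
  expect_equal(r$n_raw, hand, tolerance = 1e-12)
  expect_equal(r$n_per_group, 63)
  expect_equal(r$n_total, 126)
  # doubling the effect size quarters the raw requirement
  r2 <- sample_size_two_means(0, 1, 1, 1, alpha = 0.05, power = 0.8)
  expect_equal(r$n_raw / r2$n_raw, 4, tolerance = 1e-12)
  # larger power -> larger n
  r3 <- sample_size_two_means(0, 1, 0.5, 1, alpha = 0.05, power = 0.95)
  expect_gt(r3$n_raw, r$n_raw)
  expect_error(sample_size_two_means(1, 1, 1, 1), "infinite")
})
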