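# Statistical comparison machinery for planning methods: Friedman test
# (tie-corrected, with an exact small-sample mode), one-sided Wilcoxon
# signed-rank tests, Pearson correlation, implant size accuracy, improvement
# summaries and a two-sample normal-approximation sample-size calculation.

#' Friedman test across planning methods
#'
#' Rank-based test for differences between k related methods measured on n
#' subjects (rows = surgeons, columns = methods, entries = mean correction
#' counts). Within-row ties receive average ranks and the chi-square
#' statistic carries the standard tie correction. For small instances
#' (`(k!)^n` up to `exact_limit`) the p-value is computed from the exact
#' within-row permutation distribution of the statistic instead of the
#' chi-square approximation.
#'
#' @param m numeric matrix, >= 2 rows and >= 2 columns.
#' @param exact `"auto"` (default), `TRUE` or `FALSE`.
#' @param exact_limit maximum number of permutations for the exact mode
#'   under `"auto"` (default 1e5).
#' @return A list (class `htest`-like): `statistic`, `df`, `p.value`,
#'   `method`.
#' @export
friedman_test <- function(m, exact = "auto", exact_limit = 1e5) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns")
  stat <- friedman_statistic(m)
  n_perm <- factorial(k)^n
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && n_perm <= exact_limit)
  if (use_exact) {
    stats_all <- friedman_perm_stats(m)
    p <- mean(stats_all >= stat - 1e-12)
    method <- "Friedman rank sum test (exact permutation)"
  } else {
    p <- stats::pchisq(stat, df = k - 1L, lower.tail = FALSE)
    method <- "Friedman rank sum test (tie-corrected chi-square)"
  }
  structure(list(statistic = c(chisq = stat), df = k - 1L, p.value = p,
                 method = method), class = "kneeplan_test")
}

# per-row tie term sum(t^3 - t); invariant under within-row permutation
friedman_tie_term <- function(m) {
  sum(apply(m, 1L, function(row) {
    t <- table(row)
    sum(t^3 - t)
  }))
}

# tie-corrected chi-square statistic from column rank sums
friedman_stat_from_colsums <- function(colsum, n, k, tie_term) {
  corr <- 1 - tie_term / (n * k * (k^2 - 1))
  if (corr <= 1e-12) return(0)
  num <- 12 * sum((colsum - n * (k + 1) / 2)^2)
  (num / (n * k * (k + 1))) / corr
}

# tie-corrected Friedman chi-square statistic; 0 for fully tied data
friedman_statistic <- function(m) {
  n <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1L, rank))
  friedman_stat_from_colsums(colSums(R), n, k, friedman_tie_term(m))
}

# exact permutation distribution: the statistic under all (k!)^n within-row
# rearrangements of the observed values
friedman_perm_stats <- function(m) {
  n <- nrow(m); k <- ncol(m)
  perms <- all_permutations(k)
  nP <- nrow(perms)
  S <- matrix(0, 1L, k)
  for (i in seq_len(n)) {
    r <- rank(m[i, ])
    RR <- matrix(r[t(perms)], nP, k, byrow = TRUE)  # nP x k rank arrangements
    nS <- nrow(S)
    S <- S[rep(seq_len(nS), each = nP), , drop = FALSE] +
      RR[rep(seq_len(nP), times = nS), , drop = FALSE]
  }
  tie_term <- friedman_tie_term(m)
  apply(S, 1L, friedman_stat_from_colsums, n = n, k = k, tie_term = tie_term)
}

all_permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(pos) {
    t(apply(sub, 1L, function(p) append(p, k, after = pos - 1L)))
  }))
}

#' One-sided Wilcoxon signed-rank test
#'
#' Tests whether paired sample `a` is stochastically smaller than `b`
#' (alternative: the median of `a - b` is negative). Zero differences are
#' dropped (with a warning if all are zero, returning p = 1). With no ties
#' among the remaining absolute differences and up to 16 pairs the exact
#' signed-rank distribution is used; otherwise the normal approximation with
#' tie and continuity corrections.
#'
#' @param a,b equal-length paired samples; at least 5 nonzero differences.
#' @param exact `"auto"` (default), `TRUE` or `FALSE`.
#' @return The one-sided p-value.
#' @export
wilcoxon_one_sided <- function(a, b, exact = "auto") {
  if (length(a) != length(b)) stop("paired samples must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (!length(d)) {
    warning("all paired differences are zero; returning p = 1")
    return(1)
  }
  if (length(d) < 5L) stop("need at least 5 nonzero differences")
  has_ties <- anyDuplicated(abs(d)) > 0L
  use_exact <- isTRUE(exact) ||
    (identical(exact, "auto") && !has_ties && length(d) <= 16L)
  res <- suppressWarnings(stats::wilcox.test(d, mu = 0, alternative = "less",
                                             exact = use_exact,
                                             correct = TRUE))
  unname(res$p.value)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors of equal length >= 3; neither constant.
#' @return The product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (sd(x) < 1e-300 || sd(y) < 1e-300)
    stop("correlation undefined for constant input")
  stats::cor(x, y)
}

#' Implant size prediction accuracy
#'
#' @param pred_plans,true_plans equal-length lists of [implant_plan()]s.
#' @return Named vector: percent of cases with exact femoral / tibial size
#'   match.
#' @export
size_accuracy <- function(pred_plans, true_plans) {
  if (!length(pred_plans)) stop("empty plan list")
  if (length(pred_plans) != length(true_plans)) stop("plan lists differ in length")
  P <- plans_to_matrix(pred_plans); T_ <- plans_to_matrix(true_plans)
  c(femoral = 100 * mean(P[, "femur_size"] == T_[, "femur_size"]),
    tibial = 100 * mean(P[, "tibia_size"] == T_[, "tibia_size"]))
}

#' Overall improvement summary across surgeons
#'
#' The improvement of each surgeon is the percent reduction in their mean
#' correction count, `100 (MPP - APP) / MPP`; the overall figure is the mean
#' (and SD) of the per-surgeon improvements, not a pooled per-case ratio. A
#' surgeon whose MPP needs no corrections contributes 0 (with a message).
#'
#' @param mpp_means,app_means per-surgeon mean correction counts.
#' @return List: `per_surgeon` (percent), `mean`, `sd`.
#' @export
improvement_summary <- function(mpp_means, app_means) {
  if (!length(mpp_means) || length(mpp_means) != length(app_means))
    stop("need equal-length, non-empty mean vectors")
  imp <- ifelse(mpp_means > 0, 100 * (mpp_means - app_means) / mpp_means, 0)
  if (any(mpp_means <= 0))
    message(sum(mpp_means <= 0),
            " surgeon(s) with zero MPP corrections; improvement set to 0")
  list(per_surgeon = imp, mean = mean(imp),
       sd = if (length(imp) > 1L) sd(imp) else 0)
}

#' Two-sample normal-approximation sample size
#'
#' Total sample size for detecting a difference between two means with
#' unequal variances:
#' `n_per_group = (z_{1-alpha/2} + z_{power})^2 (sigma1^2 + sigma2^2) / (mu1 - mu2)^2`,
#' rounded up; the total is twice that.
#'
#' @param mu1,sigma1 mean and SD of group 1.
#' @param mu2,sigma2 mean and SD of group 2.
#' @param alpha two-sided significance level, in (0, 1).
#' @param power target power, in (0, 1).
#' @return List: `n_per_group` (rounded up), `n_total`, `n_raw` (unrounded
#'   per-group value).
#' @export
sample_size_two_means <- function(mu1, sigma1, mu2, sigma2, alpha = 0.01,
                                  power = 0.8) {
  if (mu1 == mu2) stop("effect size is zero; required sample size is infinite")
  if (sigma1 <= 0 || sigma2 <= 0) stop("SDs must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_raw <- z^2 * (sigma1^2 + sigma2^2) / (mu1 - mu2)^2
  list(n_per_group = ceiling(n_raw), n_total = 2 * ceiling(n_raw),
       n_raw = n_raw)
}

#' @export
print.kneeplan_test <- function(x, ...) {
  cat(x$method, "\n  chi-squared = ", signif(unname(x$statistic), 5),
      ", df = ", x$df, ", p = ", format.pval(x$p.value, digits = 4), "\n",
      sep = "")
  invisible(x)
}
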