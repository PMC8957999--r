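# Hyperparameter selection: exhaustive grid search scored by k-fold
# cross-validated mean squared error, with deterministic seeded folds and
# fixed tie-breaking (smaller C, then larger sigma).

#' Logarithmically spaced hyperparameter values
#'
#' @param from,to decade exponents; values are `10^seq(from, to)` restricted
#'   to the open interval (1e-6, 1e6).
#' @param by decade step (default 1).
#' @return Sorted positive values.
#' @export
log_grid <- function(from = -6, to = 6, by = 1) {
  v <- 10^seq(from, to, by = by)
  sort(v[v > 1e-6 - 1e-15 & v < 1e6 + 1e-9])
}

#' Default hyperparameter grids
#'
#' Reduced, desk-scale grids used by the planner pipeline: a handful of
#' log-spaced values per hyperparameter inside the canonical `(1e-6, 1e6)`
#' search range, with the RBF bandwidth scaled by `sqrt(p)` (the natural
#' length scale of a standardized p-dimensional feature space). Pass a larger
#' grid for a denser search.
#'
#' @param p feature dimension (for the bandwidth scale).
#' @return A data frame of hyperparameter combinations (columns `C`, `sigma`
#'   and `epsilon` or `delta`).
#' @export
svr_grid <- function(p) {
  expand.grid(C = c(1, 10, 100), sigma = sqrt(max(p, 1)) * c(1, 2),
              epsilon = 0.1)
}

#' @rdname svr_grid
#' @export
lad_svr_grid <- function(p) {
  expand.grid(C = c(1, 10, 100), sigma = sqrt(max(p, 1)) * c(1, 2), delta = 1)
}

#' Grid-search cross-validation for a regressor
#'
#' Evaluates every hyperparameter combination by k-fold cross-validated mean
#' squared error and returns the winner. Ties are broken towards smaller `C`,
#' then larger `sigma` (the smoother, more regularized model). Deterministic
#' given the seed.
#'
#' @param fitter a function `(X, y, ...hyperparameters...) -> model` whose
#'   models have a [predict()] method, e.g. [fit_svr()] or [fit_lad_svr()].
#' @param X,y training data.
#' @param grid data frame of hyperparameter combinations (one column per
#'   fitter argument); must be non-empty.
#' @param k_folds folds (default 10; requires `N >= k_folds`).
#' @param seed integer seed for the fold assignment.
#' @param folds optional explicit fold assignment (overrides `seed`).
#' @return A list: `best` (named list of winning hyperparameters), `cv_table`
#'   (the grid with a `cv_mse` column), `folds`.
#' @export
grid_search_cv <- function(fitter, X, y, grid, k_folds = 10L, seed = 1L,
                           folds = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (is.null(folds)) {
    if (n < k_folds) stop("need at least k_folds rows (", k_folds, ")")
    folds <- seeded_folds(n, k_folds, seed_stream(seed, "grid-cv"))
  }
  ord <- order(grid$C,
               if ("sigma" %in% names(grid)) -grid$sigma else seq_len(nrow(grid)))
  grid <- grid[ord, , drop = FALSE]
  mse <- vapply(seq_len(nrow(grid)), function(gi) {
    pars <- as.list(grid[gi, , drop = FALSE])
    err <- 0
    for (k in sort(unique(folds))) {
      tr <- folds != k
      model <- do.call(fitter, c(list(X[tr, , drop = FALSE], y[tr]), pars))
      err <- err + sum((y[!tr] - predict(model, X[!tr, , drop = FALSE]))^2)
    }
    err / n
  }, 0)
  best <- which(mse <= min(mse) + 1e-12)[1L]
  list(best = as.list(grid[best, , drop = FALSE]),
       cv_table = cbind(grid, cv_mse = mse), folds = folds)
}
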