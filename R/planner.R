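# The per-surgeon planner: for every planning DOF, all six combinations of
# {Lasso, group Lasso, Multi-Task Lasso} feature selection with {LAD-SVR,
# eps-SVR} regression compete against an MPP-copy baseline; the combination
# with the lowest cross-validated correction count wins and is refit on the
# full training set. The assembled per-DOF winners define the AI-based
# preoperative plan (APP).

#' The six selector/regressor combinations
#'
#' @return Data frame of the six method combinations in canonical order
#'   (selector-major: Lasso, group Lasso, Multi-Task Lasso; LAD-SVR before
#'   SVR). This order also breaks ties in the per-DOF contest.
#' @export
method_combos <- function() {
  data.frame(
    selector = rep(c("lasso", "group_lasso", "multitask"), each = 2L),
    regressor = rep(c("lad_svr", "svr"), times = 3L),
    name = paste(rep(c("lasso", "group_lasso", "multitask"), each = 2L),
                 rep(c("lad_svr", "svr"), times = 3L), sep = "+"),
    stringsAsFactors = FALSE
  )
}

#' Planner tuning configuration
#'
#' Desk-scale defaults for the per-surgeon pipeline: 10-fold CV throughout, a
#' 30-point penalty path over three decades for the selectors, and the
#' reduced hyperparameter grids of [svr_grid()] / [lad_svr_grid()].
#'
#' @param k_folds folds for selection, tuning and the combo contest.
#' @param n_lambda selector penalty-path length.
#' @param min_ratio penalty-path endpoint ratio.
#' @param svr_grid,lad_svr_grid functions of the (selected) feature dimension
#'   returning hyperparameter grids.
#' @param profile feature schema profile.
#' @return A named list of settings.
#' @export
planner_control <- function(k_folds = 10L, n_lambda = 30L, min_ratio = 1e-3,
                            svr_grid = kneeplan::svr_grid,
                            lad_svr_grid = kneeplan::lad_svr_grid,
                            profile = "paper149") {
  list(k_folds = k_folds, n_lambda = n_lambda, min_ratio = min_ratio,
       svr_grid = svr_grid, lad_svr_grid = lad_svr_grid, profile = profile)
}

# constant predictor fallback (used when a selector returns no features)
constant_model <- function(value) structure(list(value = value),
                                            class = "constant_model")
#' @export
predict.constant_model <- function(object, newdata, ...) {
  rep(object$value, nrow(as.matrix(newdata)))
}

fit_regressor <- function(regressor, Xs, ys, pars) {
  if (!ncol(Xs)) return(constant_model(0))
  if (regressor == "svr")
    fit_svr(Xs, ys, epsilon = pars$epsilon, C = pars$C, sigma = pars$sigma)
  else
    fit_lad_svr(Xs, ys, C = pars$C, sigma = pars$sigma, delta = pars$delta)
}

# snap a raw prediction for one DOF
snap_dof <- function(value, dof, catalog) {
  if (dof %in% size_dofs()) {
    b <- if (dof == "femur_size") "femur" else "tibia"
    min(max(round_half_away(value, 1), 0), n_sizes(catalog, b) - 1L)
  } else {
    round_half_away(value, 0.5)
  }
}

steps_for_dof <- function(pred, truth, dof) {
  step <- dof_steps()[[dof]]
  round(abs(pred - truth) / step)
}

#' Train the per-surgeon planner
#'
#' For each of the 14 DOFs: run the three feature selectors (penalty chosen
#' by 10-fold CV on the training set), tune each regressor's hyperparameters
#' by grid-search CV on the selected features, then score all six
#' selector/regressor combinations -- plus an MPP-copy baseline -- by the
#' cross-validated mean number of correction steps for that DOF on a shared
#' fold split. The winner (ties towards the baseline, then the canonical
#' combo order) is refit on the full training set. All six combos are also
#' refit and kept so that whole-plan method comparisons can be evaluated.
#'
#' @param cases one surgeon's training cases (a `tka_dataset`).
#' @param catalog the [implant_catalog()].
#' @param seed integer seed (folds and selector CV).
#' @param control a [planner_control()] list.
#' @return An object of class `planner_model`.
#' @export
train_surgeon_planner <- function(cases, catalog, seed = 1L,
                                  control = planner_control()) {
  surgeons <- dataset_surgeons(cases)
  if (length(surgeons) != 1L)
    stop("train_surgeon_planner expects a single surgeon's cases")
  n <- length(cases)
  if (n < control$k_folds)
    stop("need at least ", control$k_folds, " training cases")

  X <- feature_matrix(cases, catalog, profile = control$profile)
  Y <- plans_to_matrix(lapply(cases, `[[`, "scp"))
  M <- plans_to_matrix(lapply(cases, `[[`, "mpp"))
  groups <- feature_groups(colnames(X))
  nm <- dof_names()
  combos <- method_combos()

  # --- feature selection (per target for Lasso / group Lasso, shared for MTL)
  sel <- list()
  sel$lasso <- lapply(seq_along(nm), function(t)
    select_features("lasso", X, Y[, t], k_folds = control$k_folds,
                    n_lambda = control$n_lambda, min_ratio = control$min_ratio,
                    seed = seed_stream(seed, paste0("sel-lasso-", t))))
  sel$group_lasso <- lapply(seq_along(nm), function(t)
    select_features("group_lasso", X, Y[, t], groups = groups,
                    k_folds = control$k_folds, n_lambda = control$n_lambda,
                    min_ratio = control$min_ratio,
                    seed = seed_stream(seed, paste0("sel-group-", t))))
  mtl <- select_features("multitask", X, Y, k_folds = control$k_folds,
                         n_lambda = control$n_lambda,
                         min_ratio = control$min_ratio,
                         seed = seed_stream(seed, "sel-mtl"))
  sel$multitask <- rep(list(mtl), length(nm))

  folds <- seeded_folds(n, control$k_folds, seed_stream(seed, "combo-cv"))

  per_dof <- vector("list", length(nm))
  names(per_dof) <- nm
  for (t in seq_along(nm)) {
    dof <- nm[t]
    y <- Y[, t]
    y_center <- mean(y)
    y_scale <- sd(y)
    if (!is.finite(y_scale) || y_scale < 1e-12) y_scale <- 1
    ys <- (y - y_center) / y_scale

    scores <- c(mpp_copy = mean(steps_for_dof(M[, t], y, dof)))
    fitted <- list()
    for (ci in seq_len(nrow(combos))) {
      cname <- combos$name[ci]
      s <- sel[[combos$selector[ci]]][[t]]
      idx <- s$selected
      Xs <- apply_standardization(s$transform, X)[, idx, drop = FALSE]
      if (length(idx)) {
        grid <- if (combos$regressor[ci] == "svr") control$svr_grid(length(idx))
                else control$lad_svr_grid(length(idx))
        gs <- grid_search_cv(
          function(Xtr, ytr, ...) fit_regressor(combos$regressor[ci], Xtr, ytr,
                                                list(...)),
          Xs, ys, grid, folds = folds)
        pars <- gs$best
      } else {
        pars <- list()
      }
      # combo-level CV correction score on the shared folds
      steps <- numeric(0)
      for (k in sort(unique(folds))) {
        tr <- folds != k
        m <- if (length(idx))
          fit_regressor(combos$regressor[ci], Xs[tr, , drop = FALSE], ys[tr], pars)
        else constant_model(mean(ys[tr]))
        raw <- predict(m, Xs[!tr, , drop = FALSE]) * y_scale + y_center
        snapped <- vapply(raw, snap_dof, 0, dof = dof, catalog = catalog)
        steps <- c(steps, steps_for_dof(snapped, y[!tr], dof))
      }
      scores[cname] <- mean(steps)
      # refit on the full training set for deployment / method comparison
      full_model <- if (length(idx)) fit_regressor(combos$regressor[ci], Xs, ys, pars)
                    else constant_model(mean(ys))
      fitted[[cname]] <- list(selected = idx, pars = pars, model = full_model,
                              transform = s$transform, lambda = s$lambda,
                              feature_names = s$feature_names,
                              y_center = y_center, y_scale = y_scale)
    }
    # contest: baseline first, then canonical combo order
    winner <- names(scores)[which(scores <= min(scores) + 1e-12)[1L]]
    per_dof[[t]] <- list(dof = dof, winner = winner, cv_scores = scores,
                         models = fitted)
  }

  structure(list(surgeon = surgeons, per_dof = per_dof,
                 feature_names = colnames(X), profile = control$profile,
                 n_train = n, seed = seed,
                 fold_hash = schema_hash(paste(folds, collapse = ","))),
            class = "planner_model")
}

#' @export
print.planner_model <- function(x, ...) {
  w <- vapply(x$per_dof, `[[`, "", "winner")
  cat("Planner for surgeon ", x$surgeon, " (", x$n_train, " training cases)\n",
      sep = "")
  for (i in seq_along(w))
    cat(sprintf("  %-26s %s\n", names(x$per_dof)[i], w[i]))
  invisible(x)
}

#' Selected features per DOF (interpretability surface)
#'
#' @param planner a [train_surgeon_planner()] result.
#' @return Named list: for each DOF won by a learned model, the names of the
#'   features its selector retained.
#' @export
selected_feature_report <- function(planner) {
  out <- lapply(planner$per_dof, function(e) {
    if (e$winner == "mpp_copy") character(0)
    else e$models[[e$winner]]$feature_names
  })
  names(out) <- names(planner$per_dof)
  out
}

predict_dof_raw <- function(entry, combo, x) {
  m <- entry$models[[combo]]
  if (!length(m$selected)) return(m$y_center + predict(m$model, matrix(0, 1, 0)) * m$y_scale)
  xs <- (x[m$selected] - m$transform$x_center[m$selected]) /
    m$transform$x_scale[m$selected]
  xs[m$transform$constant[m$selected]] <- 0
  predict(m$model, matrix(xs, nrow = 1L)) * m$y_scale + m$y_center
}

#' Predict a preoperative plan for a new case
#'
#' Applies the planner's per-DOF winning models (the APP) -- or one fixed
#' method combination -- to a case and snaps the result to the planning
#' grids.
#'
#' @param planner a [train_surgeon_planner()] result.
#' @param case a case record with `anatomy` and `mpp`.
#' @param catalog the [implant_catalog()].
#' @param combo `"app"` (default: per-DOF winners) or one of
#'   `method_combos()$name` to force a single method for all DOFs.
#' @return A snapped [implant_plan()].
#' @export
predict_plan <- function(planner, case, catalog, combo = "app") {
  x <- assemble_features(case, catalog, profile = planner$profile)
  if (!identical(names(x), planner$feature_names))
    stop("feature schema mismatch between planner and case")
  v <- stats::setNames(numeric(14L), dof_names())
  for (dof in dof_names()) {
    e <- planner$per_dof[[dof]]
    use <- if (combo == "app") e$winner else combo
    v[dof] <- if (use == "mpp_copy") unclass(case$mpp)[dof]
              else predict_dof_raw(e, use, x)
  }
  snap_to_grid(implant_plan(v), catalog)
}

#' Evaluate a planner on held-out cases
#'
#' Counts, per case, the corrections separating each candidate plan from the
#' surgeon's corrected plan (SCP): the manufacturer default (MPP), the APP,
#' and each of the six fixed method combinations.
#'
#' @param planner a [train_surgeon_planner()] result.
#' @param test_cases held-out cases of the same surgeon.
#' @param catalog the [implant_catalog()].
#' @return An object of class `evaluation_report`: `cases` (per-case totals
#'   per method), `per_dof_app` (per-DOF step counts for the APP),
#'   `summary` (per-surgeon means/SDs, size accuracies).
#' @export
evaluate_planner <- function(planner, test_cases, catalog) {
  methods <- c("mpp", method_combos()$name, "app")
  totals <- matrix(0, length(test_cases), length(methods),
                   dimnames = list(vapply(test_cases, `[[`, "", "case_id"),
                                   methods))
  per_dof_app <- matrix(0L, length(test_cases), 14L,
                        dimnames = list(rownames(totals), dof_names()))
  size_hit <- matrix(FALSE, length(test_cases), 4L,
                     dimnames = list(NULL, c("app_fem", "app_tib",
                                             "mpp_fem", "mpp_tib")))
  for (i in seq_along(test_cases)) {
    cs <- test_cases[[i]]
    totals[i, "mpp"] <- count_corrections(cs$mpp, cs$scp, catalog)$total
    for (cm in method_combos()$name) {
      plan <- predict_plan(planner, cs, catalog, combo = cm)
      totals[i, cm] <- count_corrections(plan, cs$scp, catalog)$total
    }
    app <- predict_plan(planner, cs, catalog, combo = "app")
    cc <- count_corrections(app, cs$scp, catalog)
    totals[i, "app"] <- cc$total
    per_dof_app[i, ] <- cc$steps
    size_hit[i, ] <- c(app["femur_size"] == cs$scp["femur_size"],
                       app["tibia_size"] == cs$scp["tibia_size"],
                       cs$mpp["femur_size"] == cs$scp["femur_size"],
                       cs$mpp["tibia_size"] == cs$scp["tibia_size"])
  }
  structure(list(
    surgeon = planner$surgeon,
    cases = as.data.frame(totals),
    per_dof_app = per_dof_app,
    summary = list(
      n_test = length(test_cases),
      mean = colMeans(totals), sd = apply(totals, 2L, sd),
      per_dof_mean_app = colMeans(per_dof_app),
      size_accuracy = 100 * colMeans(size_hit))
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation for surgeon ", x$surgeon, " (", x$summary$n_test,
      " test cases)\n", sep = "")
  cat(sprintf("  MPP %.2f (%.2f) -> APP %.2f (%.2f) corrections\n",
              x$summary$mean["mpp"], x$summary$sd["mpp"],
              x$summary$mean["app"], x$summary$sd["app"]))
  sa <- x$summary$size_accuracy
  cat(sprintf("  size accuracy: femur %.1f%% (MPP %.1f%%), tibia %.1f%% (MPP %.1f%%)\n",
              sa["app_fem"], sa["mpp_fem"], sa["app_tib"], sa["mpp_tib"]))
  invisible(x)
}
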