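# Study-level orchestration: split every surgeon's cases 70/30, train one
# planner per surgeon, evaluate on the held-out cases, and aggregate the
# method comparison (correction counts per method, improvement percentages,
# size accuracies, Friedman / Wilcoxon tests).

#' Run the full multi-surgeon planning study
#'
#' @param cases a `tka_dataset` covering one or more surgeons.
#' @param catalog the [implant_catalog()].
#' @param seed integer master seed (split, folds, selector CV).
#' @param control a [planner_control()] list.
#' @return An object of class `study_report`: `planners`, `evaluations`,
#'   `method_matrix` (surgeons x methods mean corrections), `improvement`,
#'   `size_accuracy`, `friedman` (across the six learned combos),
#'   `wilcoxon_app_vs_mpp` (one-sided, if >= 5 informative surgeons),
#'   `split`.
#' @export
run_study <- function(cases, catalog = default_catalog(), seed = 1L,
                      control = planner_control()) {
  split <- split_dataset(cases, seed = seed)
  surgeons <- names(split$surgeons)
  planners <- list(); evaluations <- list()
  for (s in surgeons) {
    tr <- split_cases(cases, split, s, "train")
    te <- split_cases(cases, split, s, "test")
    planners[[s]] <- train_surgeon_planner(tr, catalog,
                                           seed = seed_stream(seed, paste0("train-", s)),
                                           control = control)
    evaluations[[s]] <- evaluate_planner(planners[[s]], te, catalog)
  }
  mm <- method_matrix(evaluations)
  imp <- improvement_summary(mm[, "mpp"], mm[, "app"])
  sa <- do.call(rbind, lapply(evaluations, function(e) e$summary$size_accuracy))
  fr <- if (length(surgeons) >= 2L)
    friedman_test(mm[, method_combos()$name, drop = FALSE]) else NULL
  wx <- if (length(surgeons) >= 5L)
    tryCatch(suppressWarnings(wilcoxon_one_sided(mm[, "app"], mm[, "mpp"])),
             error = function(e) NULL) else NULL
  structure(list(planners = planners, evaluations = evaluations,
                 method_matrix = mm, improvement = imp,
                 size_accuracy = colMeans(sa), friedman = fr,
                 wilcoxon_app_vs_mpp = wx, split = split, seed = seed),
            class = "study_report")
}

#' Per-surgeon method matrix
#'
#' @param evaluations list of [evaluate_planner()] reports.
#' @return Matrix: rows = surgeons, columns = MPP, the six method combos and
#'   the APP; entries = mean correction counts on the test cases.
#' @export
method_matrix <- function(evaluations) {
  mm <- do.call(rbind, lapply(evaluations, function(e) e$summary$mean))
  rownames(mm) <- vapply(evaluations, `[[`, "", "surgeon")
  mm
}

#' @export
print.study_report <- function(x, ...) {
  mm <- x$method_matrix
  cat("Study over", nrow(mm), "surgeons\n")
  cat(sprintf("  corrections: MPP %.2f (%.2f) -> APP %.2f (%.2f)\n",
              mean(mm[, "mpp"]), sd(mm[, "mpp"]),
              mean(mm[, "app"]), sd(mm[, "app"])))
  cat(sprintf("  improvement: %.2f%% (%.2f%%)\n",
              x$improvement$mean, x$improvement$sd))
  sa <- x$size_accuracy
  cat(sprintf("  size accuracy: femur APP %.1f%% vs MPP %.1f%%; tibia APP %.1f%% vs MPP %.1f%%\n",
              sa["app_fem"], sa["mpp_fem"], sa["app_tib"], sa["mpp_tib"]))
  if (!is.null(x$friedman))
    cat("  Friedman across combos: p =", format.pval(x$friedman$p.value, digits = 3), "\n")
  if (!is.null(x$wilcoxon_app_vs_mpp))
    cat("  Wilcoxon APP < MPP: p =",
        format.pval(x$wilcoxon_app_vs_mpp, digits = 3), "\n")
  invisible(x)
}

#' Write a study report to JSON (plus a CSV of the method matrix)
#'
#' @param report a [run_study()] result.
#' @param path JSON output path; the method matrix is written next to it as
#'   `<path>.methods.csv`.
#' @return The path, invisibly.
#' @export
report_to_json <- function(report, path) {
  obj <- list(
    schema = "kneeplan/report/v1",
    surgeons = rownames(report$method_matrix),
    method_means = as.data.frame(report$method_matrix),
    improvement_pct = list(per_surgeon = unname(report$improvement$per_surgeon),
                           mean = report$improvement$mean,
                           sd = report$improvement$sd),
    size_accuracy_pct = as.list(report$size_accuracy),
    friedman = if (!is.null(report$friedman))
      list(statistic = unname(report$friedman$statistic),
           p_value = report$friedman$p.value),
    wilcoxon_app_vs_mpp_p = report$wilcoxon_app_vs_mpp,
    selected_features = lapply(report$planners, selected_feature_report))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  utils::write.csv(data.frame(surgeon = rownames(report$method_matrix),
                              report$method_matrix, check.names = FALSE),
                   paste0(path, ".methods.csv"), row.names = FALSE)
  invisible(path)
}
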