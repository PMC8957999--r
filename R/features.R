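# Per-case feature vectors: landmark coordinates in the bone's own anatomical
# frame (26 x 3 = 78), the 57 implant-fit measurements, and the 14 default
# plan DOFs -- 149 features in the default profile. The "full" profile appends
# 15 fitted shape coefficients per bone (179 features).

#' Feature schema
#'
#' Ordered feature names for a profile: `"paper149"` (78 landmark coordinates
#' + 57 measurements + 14 default-plan DOFs = 149) or `"full"` (those plus 15
#' shape coefficients per bone = 179).
#'
#' @param profile `"paper149"` (default) or `"full"`.
#' @return Character vector of feature names.
#' @export
feature_schema <- function(profile = c("paper149", "full")) {
  profile <- match.arg(profile)
  lm <- landmark_schema()$name
  nm <- c(paste0(rep(lm, each = 3L), "_", c("ml", "ap", "pd")),
          measurement_schema()$name,
          paste0("mpp_", dof_names()))
  if (profile == "full")
    nm <- c(nm, paste0("femur_ssm_", 1:15), paste0("tibia_ssm_", 1:15))
  nm
}

# stable digest of a schema (frozen by tests; any schema change breaks them)
schema_hash <- function(names) {
  codes <- unlist(lapply(names, utf8ToInt))
  sprintf("%d-%d", length(names),
          sum(codes * (seq_along(codes) %% 97 + 1)) %% 1000000007)
}

#' Assemble the feature vector for one case
#'
#' Landmark coordinates are expressed in the frame of their own bone, so the
#' whole vector is invariant to rigid motion of the input anatomy. The
#' default-plan block is a pass-through of the case's MPP DOFs. The `"full"`
#' profile additionally fits 15 shape coefficients per bone, which requires
#' the case to carry its bone point sets or stored coefficients.
#'
#' @param case a case record (`anatomy`, `mpp`).
#' @param catalog the [implant_catalog()].
#' @param profile `"paper149"` (default) or `"full"`.
#' @param model a [build_synthetic_knee_model()] result; only needed for the
#'   `"full"` profile when coefficients must be fitted from points.
#' @return Named numeric vector following [feature_schema()].
#' @export
assemble_features <- function(case, catalog, profile = c("paper149", "full"),
                              model = NULL) {
  profile <- match.arg(profile)
  anat <- case$anatomy
  lmn <- landmark_schema()
  Lf <- to_frame(anat$landmarks[lmn$name[lmn$bone == "femur"], , drop = FALSE],
                 anat$frames$femoral)
  Lt <- to_frame(anat$landmarks[lmn$name[lmn$bone == "tibia"], , drop = FALSE],
                 anat$frames$tibial)
  coords <- as.vector(t(rbind(Lf, Lt)))  # per landmark: ml, ap, pd
  meas <- compute_measurements(anat, case$mpp, catalog)
  out <- c(coords, meas, unclass(case$mpp))
  if (profile == "full") {
    cf <- anat$coefficients
    if (is.null(cf)) {
      if (is.null(model) || is.null(anat$femur_points))
        stop("'full' profile needs stored coefficients or point sets + model")
      cf <- list(femur = fit_shape_coefficients(model$femur, anat$femur_points),
                 tibia = fit_shape_coefficients(model$tibia, anat$tibia_points))
    }
    pad <- function(x) c(x, numeric(15L))[1:15]
    out <- c(out, pad(cf$femur), pad(cf$tibia))
  }
  stats::setNames(out, feature_schema(profile))
}

#' Assemble the feature matrix for a dataset
#'
#' @param cases a `tka_dataset`.
#' @inheritParams assemble_features
#' @return Numeric matrix, one row per case (row names = case IDs), columns
#'   following [feature_schema()].
#' @export
feature_matrix <- function(cases, catalog, profile = c("paper149", "full"),
                           model = NULL) {
  profile <- match.arg(profile)
  X <- t(vapply(cases, assemble_features, numeric(length(feature_schema(profile))),
                catalog = catalog, profile = profile, model = model))
  rownames(X) <- vapply(cases, `[[`, "", "case_id")
  X
}

#' Write / read a feature matrix as CSV with a JSON sidecar
#'
#' The CSV has a header row of schema names and one row per case; the sidecar
#' (`<path>.meta.json`) records the profile, the schema hash and units.
#'
#' @param X a [feature_matrix()] result.
#' @param path CSV output path.
#' @param profile the schema profile the matrix was built with.
#' @return `write_feature_matrix()` the path, invisibly;
#'   `read_feature_matrix()` the matrix (checked against the sidecar hash).
#' @export
write_feature_matrix <- function(X, path, profile = "paper149") {
  stopifnot(identical(colnames(X), feature_schema(profile)))
  utils::write.csv(data.frame(case_id = rownames(X), X, check.names = FALSE),
                   path, row.names = FALSE)
  meta <- list(schema = "kneeplan/features/v1", profile = profile,
               hash = schema_hash(colnames(X)),
               units = c(rep("mm", 78L), measurement_schema()$unit,
                         ifelse(dof_schema()$unit == "size", "size",
                                dof_schema()$unit),
                         if (profile == "full") rep("score", 30L)))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".meta.json"))
  d <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(d[, -1L, drop = FALSE])
  rownames(X) <- d$case_id
  if (!identical(schema_hash(colnames(X)), meta$hash))
    stop("feature schema hash mismatch; file does not match this package version")
  X
}
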