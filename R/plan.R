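#' The 14 planning degrees of freedom
#'
#' Canonical, fixed ordering of the 14 implant-plan degrees of freedom (DOFs):
#' the seven femoral transformations first (size, coronal rotation, coronal
#' translation, axial rotation, axial translation, sagittal rotation, sagittal
#' translation), then the seven tibial analogues. All downstream indexing of
#' feature blocks, targets and correction vectors uses this order.
#'
#' @return A data frame with one row per DOF: `name`, `bone`, `unit`
#'   (`"size"`, `"deg"` or `"mm"`) and `step` (grid step: 1 size, 0.5 mm or
#'   0.5 degrees).
#' @export
dof_schema <- function() {
  data.frame(
    name = c("femur_size", "femur_varus_valgus", "femur_posterior_resection",
             "femur_int_ext_rotation", "femur_distal_resection",
             "femur_flexion_extension", "femur_ml_displacement",
             "tibia_size", "tibia_varus_valgus", "tibia_ap_displacement",
             "tibia_int_ext_rotation", "tibia_proximal_resection",
             "tibia_posterior_slope", "tibia_ml_displacement"),
    bone = rep(c("femur", "tibia"), each = 7L),
    unit = rep(c("size", "deg", "mm", "deg", "mm", "deg", "mm"), times = 2L),
    step = rep(c(1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5), times = 2L),
    stringsAsFactors = FALSE
  )
}

dof_names <- function() dof_schema()$name
dof_steps <- function() {
  s <- dof_schema()
  stats::setNames(s$step, s$name)
}
size_dofs <- function() c("femur_size", "tibia_size")

#' Create an implant plan
#'
#' An implant plan holds the 14 planning DOFs as a named numeric vector in the
#' canonical [dof_schema()] order. Sizes are ordinal indices (0-based);
#' rotations are degrees; translations/resections are millimetres.
#'
#' @param values a named numeric vector (or list) covering all 14 DOF names.
#'   Missing names raise an error; extra names raise an error.
#' @return An object of class `implant_plan` (a named numeric vector).
#' @examples
#' p <- implant_plan(c(femur_size = 3, tibia_size = 4,
#'                     femur_varus_valgus = 0, femur_posterior_resection = 9,
#'                     femur_int_ext_rotation = 0, femur_distal_resection = 9,
#'                     femur_flexion_extension = 3, femur_ml_displacement = 0,
#'                     tibia_varus_valgus = 0, tibia_ap_displacement = 0,
#'                     tibia_int_ext_rotation = 0, tibia_proximal_resection = 9,
#'                     tibia_posterior_slope = 3, tibia_ml_displacement = 0))
#' @export
implant_plan <- function(values) {
  values <- unlist(values)
  nm <- dof_names()
  if (!all(nm %in% names(values)))
    stop("missing DOFs: ", paste(setdiff(nm, names(values)), collapse = ", "))
  if (length(values) != 14L)
    stop("an implant plan has exactly 14 DOFs")
  v <- as.numeric(values[nm])
  names(v) <- nm
  structure(v, class = "implant_plan")
}

#' @export
print.implant_plan <- function(x, ...) {
  s <- dof_schema()
  cat("Implant plan (14 DOFs)\n")
  for (b in c("femur", "tibia")) {
    rows <- s[s$bone == b, ]
    cat(" ", b, ": ",
        paste0(sub(paste0(b, "_"), "", rows$name), "=",
               format(unclass(x)[rows$name], trim = TRUE),
               ifelse(rows$unit == "size", "", rows$unit), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# round half away from zero to a multiple of `step`
round_half_away <- function(x, step) {
  sign(x) * floor(abs(x) / step + 0.5) * step
}

#' Snap a plan to its planning grids
#'
#' Continuous DOFs (mm and degrees) are rounded to the nearest multiple of
#' 0.5, with exact midpoints rounded half away from zero; size DOFs are
#' rounded to the nearest integer and clamped into the catalog's size range.
#' Snapping is idempotent.
#'
#' @param plan an [implant_plan()]; all fields must be finite.
#' @param catalog an [implant_catalog()] supplying the valid size ranges.
#' @return The snapped `implant_plan`.
#' @export
snap_to_grid <- function(plan, catalog) {
  stopifnot(inherits(plan, "implant_plan"), inherits(catalog, "implant_catalog"))
  v <- unclass(plan)
  if (any(!is.finite(v))) stop("invalid plan: non-finite DOF value")
  steps <- dof_steps()
  out <- round_half_away(v, 0.5)
  for (b in c("femur", "tibia")) {
    key <- paste0(b, "_size")
    out[key] <- min(max(round_half_away(v[key], 1), 0), n_sizes(catalog, b) - 1L)
  }
  structure(out, class = "implant_plan")
}

is_snapped <- function(plan, catalog) {
  v <- unclass(plan)
  if (any(!is.finite(v))) return(FALSE)
  ok <- all(abs(v - round_half_away(v, 0.5)) < 1e-9)
  for (b in c("femur", "tibia")) {
    s <- v[paste0(b, "_size")]
    ok <- ok && abs(s - round(s)) < 1e-9 && s >= 0 && s <= n_sizes(catalog, b) - 1L
  }
  ok
}

#' Count discrete corrections between two plans
#'
#' A correction is one 0.5 mm change in a resection level or translation, one
#' 0.5 degree change in a rotation, or one implant size change. Both plans
#' must already be snapped to the grid of the same catalog; the count per DOF
#' is the number of grid steps separating the two values, and size changes
#' count their full ordinal distance (a two-size jump is two corrections).
#'
#' @param a,b snapped [implant_plan()]s on the same catalog.
#' @param catalog the shared [implant_catalog()].
#' @return An object of class `correction_vector`: a list with `steps` (named
#'   non-negative integer vector, one entry per DOF) and `total` (their sum).
#' @export
count_corrections <- function(a, b, catalog) {
  stopifnot(inherits(a, "implant_plan"), inherits(b, "implant_plan"))
  if (!is_snapped(a, catalog) || !is_snapped(b, catalog))
    stop("plans must be snapped to the grid before counting corrections")
  steps <- dof_steps()
  d <- abs(unclass(a) - unclass(b))
  k <- as.integer(round(d / steps))
  names(k) <- dof_names()
  structure(list(steps = k, total = sum(k)), class = "correction_vector")
}

#' @export
print.correction_vector <- function(x, ...) {
  cat("Corrections: total", x$total, "\n")
  nz <- x$steps[x$steps > 0]
  if (length(nz)) print(nz)
  invisible(x)
}

#' Serialize / deserialize an implant plan to JSON
#'
#' @param plan an `implant_plan`.
#' @param path optional file path; if `NULL`, a JSON string is returned.
#' @return `plan_to_json()`: a JSON string or (invisibly) the path;
#'   `plan_from_json()`: an `implant_plan`.
#' @export
plan_to_json <- function(plan, path = NULL) {
  stopifnot(inherits(plan, "implant_plan"))
  obj <- c(list(schema = "kneeplan/plan/v1"), as.list(unclass(plan)))
  if (is.null(path)) return(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname plan_to_json
#' @param json a JSON string or file path produced by [plan_to_json()].
#' @export
plan_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$schema, "kneeplan/plan/v1"))
    stop("unrecognized plan schema: ", obj$schema)
  implant_plan(unlist(obj[dof_names()]))
}

# 14-column matrix (canonical DOF order) from a list of plans, and back
plans_to_matrix <- function(plans) {
  m <- do.call(rbind, lapply(plans, unclass))
  colnames(m) <- dof_names()
  m
}

matrix_to_plans <- function(m) {
  lapply(seq_len(nrow(m)), function(i) implant_plan(m[i, ]))
}
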