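# Dataset (de)serialization: JSON-lines, one case record per line. Landmarks,
# derived dimensions, shape coefficients and both plans are always stored;
# full bone point sets are optional (they are only needed to refit shape
# coefficients, and make files much larger).

#' Write / read a dataset as JSON lines
#'
#' @param cases a `tka_dataset` (see [generate_dataset()]).
#' @param path output file path.
#' @param include_points store the full bone point sets as well (default
#'   `FALSE`; landmarks and stored shape coefficients are enough for the
#'   default feature profile).
#' @return `write_dataset()` the path, invisibly; `read_dataset()` a
#'   `tka_dataset`.
#' @export
write_dataset <- function(cases, path, include_points = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cs in cases) {
    rec <- list(
      schema = "kneeplan/case/v1",
      case_id = cs$case_id, surgeon = cs$surgeon,
      landmarks = unname(cs$anatomy$landmarks),
      landmark_names = rownames(cs$anatomy$landmarks),
      coefficients = cs$anatomy$coefficients,
      mpp = as.list(unclass(cs$mpp)), scp = as.list(unclass(cs$scp)))
    if (include_points) {
      rec$femur_points <- cs$anatomy$femur_points
      rec$tibia_points <- cs$anatomy$tibia_points
    }
    writeLines(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  lines <- readLines(path)
  cases <- lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    if (!identical(rec$schema, "kneeplan/case/v1"))
      stop("unrecognized case schema: ", rec$schema)
    lm <- if (is.list(rec$landmarks)) do.call(rbind, rec$landmarks)
          else as.matrix(rec$landmarks)
    rownames(lm) <- rec$landmark_names
    anat <- if (!is.null(rec$femur_points)) {
      new_anatomy(rec$femur_points, rec$tibia_points, lm, rec$coefficients)
    } else {
      anatomy_from_landmarks(lm, rec$coefficients)
    }
    list(case_id = rec$case_id, surgeon = rec$surgeon, anatomy = anat,
         mpp = implant_plan(unlist(rec$mpp)),
         scp = implant_plan(unlist(rec$scp)))
  })
  structure(cases, class = "tka_dataset")
}
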