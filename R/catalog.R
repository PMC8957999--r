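#' Implant size catalog
#'
#' An implant catalog lists, per component, the available sizes in increasing
#' order together with their anteroposterior (AP) and mediolateral (ML)
#' dimensions in millimetres. Sizes are handled everywhere as ordinal indices
#' `0..S-1`; the dimensions drive implant-fit measurements (notching,
#' overhang/underhang) and the default-plan sizing rules.
#'
#' @param femur,tibia data frames with numeric columns `ap` and `ml` (mm), one
#'   row per size, ordered from smallest to largest. Dimensions must be
#'   strictly increasing with size and each component needs at least 2 sizes.
#' @return An object of class `implant_catalog` with elements `femur` and
#'   `tibia` (each a data frame with columns `size`, `ap`, `ml`).
#' @seealso [default_catalog()]
#' @export
implant_catalog <- function(femur, tibia) {
  comp <- function(d, what) {
    if (!is.data.frame(d) || !all(c("ap", "ml") %in% names(d)))
      stop(what, " must be a data frame with columns 'ap' and 'ml'")
    if (nrow(d) < 2L) stop(what, " needs at least 2 sizes")
    if (any(!is.finite(d$ap)) || any(!is.finite(d$ml)))
      stop(what, " dimensions must be finite")
    if (any(diff(d$ap) <= 0) || any(diff(d$ml) <= 0))
      stop(what, " dimensions must be strictly increasing with size")
    data.frame(size = seq_len(nrow(d)) - 1L, ap = d$ap, ml = d$ml)
  }
  structure(list(femur = comp(femur, "femur"), tibia = comp(tibia, "tibia")),
            class = "implant_catalog")
}

#' Default synthetic implant catalog
#'
#' A parametric stand-in for a commercial implant system: 8 femoral sizes with
#' AP dimension 50--71 mm and 8 tibial sizes with ML dimension 58--86 mm, on
#' linear steps. Real implant geometries are proprietary; this synthetic
#' catalog preserves the structure the planning problem needs (ordinal sizes
#' with monotone dimensions).
#'
#' @return An `implant_catalog`.
#' @export
default_catalog <- function() {
  implant_catalog(
    femur = data.frame(ap = seq(50, 71, by = 3), ml = seq(58, 79, by = 3)),
    tibia = data.frame(ap = seq(40, 61, by = 3), ml = seq(58, 86, by = 4))
  )
}

n_sizes <- function(catalog, bone) nrow(catalog[[bone]])

#' @export
print.implant_catalog <- function(x, ...) {
  cat("Implant catalog:", nrow(x$femur), "femoral sizes (AP",
      min(x$femur$ap), "-", max(x$femur$ap), "mm),",
      nrow(x$tibia), "tibial sizes (ML",
      min(x$tibia$ml), "-", max(x$tibia$ml), "mm)\n")
  invisible(x)
}

#' Serialize / deserialize an implant catalog to JSON
#'
#' @param catalog an `implant_catalog`.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `catalog_to_json()` returns the path (invisibly) or a JSON string;
#'   `catalog_from_json()` returns an `implant_catalog`.
#' @export
catalog_to_json <- function(catalog, path = NULL) {
  stopifnot(inherits(catalog, "implant_catalog"))
  obj <- list(schema = "kneeplan/catalog/v1",
              femur = catalog$femur, tibia = catalog$tibia)
  if (is.null(path)) return(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname catalog_to_json
#' @param json a JSON string or file path produced by [catalog_to_json()].
#' @export
catalog_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  if (!identical(obj$schema, "kneeplan/catalog/v1"))
    stop("unrecognized catalog schema: ", obj$schema)
  implant_catalog(femur = obj$femur, tibia = obj$tibia)
}
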