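# Implant-fit measurements taken after virtual implantation: notching,
# overhang/underhang, bone dimensions and ratios, and signed distances from
# the planned resection planes to every landmark of the bone being cut.
# Exactly 57 named scalars, in a frozen schema order.

fem_landmark_names <- function() landmark_schema()$name[landmark_schema()$bone == "femur"]
tib_landmark_names <- function() landmark_schema()$name[landmark_schema()$bone == "tibia"]

#' The 57-measurement schema
#'
#' Names and units of the implant-fit measurement vector, in frozen order:
#' notching distance, femoral mediolateral overhang (medial/lateral), tibial
#' over- and underhang per compartment, bone widths/depths, dimension ratios,
#' implant-to-bone size margins, and signed distances from the distal and
#' posterior femoral resection planes and the proximal tibial resection plane
#' to each landmark of the resected bone.
#'
#' @return A data frame with columns `name` and `unit` (57 rows).
#' @export
measurement_schema <- function() {
  nm <- c(
    "notching_distance",
    "fem_overhang_medial", "fem_overhang_lateral",
    "tib_overhang_medial", "tib_overhang_lateral",
    "tib_underhang_medial", "tib_underhang_lateral",
    "fem_ml_width", "fem_ap_depth", "tib_ml_width", "tib_ap_depth",
    "fem_aspect_ratio", "tib_aspect_ratio",
    "femtib_ml_ratio", "femtib_ap_ratio",
    "fem_ml_margin", "tib_ap_margin",
    paste0("dist_cut_to_", fem_landmark_names()),
    paste0("post_cut_to_", fem_landmark_names()),
    paste0("prox_cut_to_", tib_landmark_names())
  )
  unit <- rep("mm", length(nm))
  unit[nm %in% c("fem_aspect_ratio", "tib_aspect_ratio",
                 "femtib_ml_ratio", "femtib_ap_ratio")] <- "ratio"
  data.frame(name = nm, unit = unit, stringsAsFactors = FALSE)
}

# overhang/underhang of an implant of total width `imp_w` centered at `offset`
# on a bone of total width `bone_w`; positive x = medial.
hang_measures <- function(imp_w, bone_w, offset) {
  ih <- imp_w / 2; bh <- bone_w / 2
  c(over_med = max(0, offset + ih - bh),
    over_lat = max(0, ih - offset - bh),
    under_med = max(0, bh - (offset + ih)),
    under_lat = max(0, bh - (ih - offset)))
}

#' Compute the 57 implant-fit measurements
#'
#' Notching distance is the anteroposterior margin of the femoral implant over
#' the bone (`implant AP - bone AP depth`); a negative value means the
#' anterior flange undercuts the anterior cortex (notching). Overhang and
#' underhang compare implant and bone widths per side, shifted by the planned
#' mediolateral displacement, and are mutually exclusive per side by
#' construction. Resection planes are placed in the bone's anatomical frame
#' from the planned resection levels; their signed distances to each landmark
#' (positive = on the kept, proximal/anterior side of the cut for the femur,
#' above the cut for the tibia) complete the vector.
#'
#' @param anatomy an `anatomy`.
#' @param plan a snapped [implant_plan()].
#' @param catalog the [implant_catalog()] the plan refers to.
#' @return Named numeric vector of length 57, in [measurement_schema()] order.
#' @export
compute_measurements <- function(anatomy, plan, catalog) {
  stopifnot(inherits(anatomy, "anatomy"), inherits(plan, "implant_plan"),
            inherits(catalog, "implant_catalog"))
  if (!is_snapped(plan, catalog)) stop("plan must be snapped to the grid")
  p <- unclass(plan)
  d <- anatomy$dims
  fi <- catalog$femur[p["femur_size"] + 1L, ]
  ti <- catalog$tibia[p["tibia_size"] + 1L, ]

  fh <- hang_measures(fi$ml, d["fem_condylar_width"], p["femur_ml_displacement"])
  th <- hang_measures(ti$ml, d["tib_ml_width"], p["tibia_ml_displacement"])

  Lf <- to_frame(anatomy$landmarks[fem_landmark_names(), , drop = FALSE],
                 anatomy$frames$femoral)
  Lt <- to_frame(anatomy$landmarks[tib_landmark_names(), , drop = FALSE],
                 anatomy$frames$tibial)
  rownames(Lf) <- fem_landmark_names(); rownames(Lt) <- tib_landmark_names()

  # resection planes in the bone frames
  dist_cut_pd <- mean(Lf[c("fem_med_distal", "fem_lat_distal"), "pd"]) +
    p["femur_distal_resection"]
  post_cut_ap <- mean(Lf[c("fem_med_posterior", "fem_lat_posterior"), "ap"]) +
    p["femur_posterior_resection"]
  prox_cut_pd <- mean(Lt[c("tib_med_plateau", "tib_lat_plateau"), "pd"]) -
    p["tibia_proximal_resection"]

  out <- c(
    notching_distance = unname(fi$ap - d["fem_ap_depth"]),
    fem_overhang_medial = unname(fh["over_med"]),
    fem_overhang_lateral = unname(fh["over_lat"]),
    tib_overhang_medial = unname(th["over_med"]),
    tib_overhang_lateral = unname(th["over_lat"]),
    tib_underhang_medial = unname(th["under_med"]),
    tib_underhang_lateral = unname(th["under_lat"]),
    fem_ml_width = unname(d["fem_ml_width"]),
    fem_ap_depth = unname(d["fem_ap_depth"]),
    tib_ml_width = unname(d["tib_ml_width"]),
    tib_ap_depth = unname(d["tib_ap_depth"]),
    fem_aspect_ratio = unname(d["fem_ap_depth"] / d["fem_ml_width"]),
    tib_aspect_ratio = unname(d["tib_ap_depth"] / d["tib_ml_width"]),
    femtib_ml_ratio = unname(d["fem_ml_width"] / d["tib_ml_width"]),
    femtib_ap_ratio = unname(d["fem_ap_depth"] / d["tib_ap_depth"]),
    fem_ml_margin = unname(fi$ml - d["fem_condylar_width"]),
    tib_ap_margin = unname(ti$ap - d["tib_ap_depth"]),
    stats::setNames(Lf[, "pd"] - dist_cut_pd,
                    paste0("dist_cut_to_", fem_landmark_names())),
    stats::setNames(Lf[, "ap"] - post_cut_ap,
                    paste0("post_cut_to_", fem_landmark_names())),
    stats::setNames(Lt[, "pd"] - prox_cut_pd,
                    paste0("prox_cut_to_", tib_landmark_names()))
  )
  stopifnot(identical(names(out), measurement_schema()$name))
  out
}
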