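# Manufacturer's preoperative plan (MPP): a deterministic, fixed-preference
# rule set mapping an anatomy to a default plan.

#' Default MPP rule configuration
#'
#' Fixed surgical preferences used by [generate_mpp()]: neutral (0 degree)
#' varus/valgus on both bones, 3 degrees of femoral flexion and tibial
#' posterior slope, 9 mm distal, posterior and proximal resections, and zero
#' displacements and axial rotations. All values are on the 0.5 grids.
#'
#' @return Named list of default DOF values (sizes excluded; they are rule
#'   based).
#' @export
mpp_rules <- function() {
  list(femur_varus_valgus = 0, femur_posterior_resection = 9,
       femur_int_ext_rotation = 0, femur_distal_resection = 9,
       femur_flexion_extension = 3, femur_ml_displacement = 0,
       tibia_varus_valgus = 0, tibia_ap_displacement = 0,
       tibia_int_ext_rotation = 0, tibia_proximal_resection = 9,
       tibia_posterior_slope = 3, tibia_ml_displacement = 0)
}

# smallest femoral size whose AP dimension covers the bone's AP depth
# (avoids notching by construction); boundary-clamped with a warning.
pick_femoral_size <- function(ap_depth, catalog) {
  ok <- which(catalog$femur$ap >= ap_depth)
  if (!length(ok)) {
    warning("bone AP depth ", round(ap_depth, 1),
            " mm exceeds the largest femoral implant; using the largest size")
    return(nrow(catalog$femur) - 1L)
  }
  ok[1L] - 1L
}

# largest tibial size whose ML dimension fits within the plateau width
# (avoids overhang by construction); boundary-clamped with a warning.
pick_tibial_size <- function(ml_width, catalog) {
  ok <- which(catalog$tibia$ml <= ml_width)
  if (!length(ok)) {
    warning("tibial ML width ", round(ml_width, 1),
            " mm is below the smallest tibial implant; using the smallest size")
    return(0L)
  }
  ok[length(ok)] - 1L
}

#' Generate the manufacturer's default preoperative plan
#'
#' A pure function of the anatomy, catalog and rule configuration: the femoral
#' size is the smallest size whose AP dimension covers the bone's AP depth
#' (no notching), the tibial size the largest whose ML dimension fits within
#' the plateau width (no overhang), and all alignment DOFs take the
#' configured defaults. The result is snapped to the planning grids.
#'
#' @param anatomy an `anatomy`.
#' @param catalog an [implant_catalog()].
#' @param rules default DOF values, see [mpp_rules()].
#' @return A snapped [implant_plan()].
#' @export
generate_mpp <- function(anatomy, catalog, rules = mpp_rules()) {
  stopifnot(inherits(anatomy, "anatomy"))
  vals <- unlist(rules)[setdiff(dof_names(), size_dofs())]
  vals["femur_size"] <- pick_femoral_size(anatomy$dims[["fem_ap_depth"]], catalog)
  vals["tibia_size"] <- pick_tibial_size(anatomy$dims[["tib_ml_width"]], catalog)
  snap_to_grid(implant_plan(vals), catalog)
}
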