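# Procedural femur and tibia template point clouds. Each template is a
# deterministic composite of ellipsoid patches, rings and a shaft, expressed in
# a canonical frame (+x medial, +y anterior, +z proximal, millimetres), with
# the 26 named landmark points appended as dedicated rows so that point
# correspondence (and landmark identity) is free by construction.

#' The 26-landmark schema
#'
#' Named landmark points used throughout the package: 14 femoral (hip center,
#' knee center, epicondyles, distal/posterior/anterior condyle points,
#' anterior cortex, trochlear groove, intercondylar notch, shaft reference)
#' and 12 tibial (knee center, tubercle, plateau edge points, spines, PCL
#' insertion, ankle center, malleoli).
#'
#' @return A data frame with columns `name` and `bone` (26 rows).
#' @export
landmark_schema <- function() {
  data.frame(
    name = c("hip_center", "fem_knee_center", "fem_med_epicondyle",
             "fem_lat_epicondyle", "fem_med_distal", "fem_lat_distal",
             "fem_med_posterior", "fem_lat_posterior", "fem_anterior_cortex",
             "fem_trochlear_groove", "fem_med_anterior", "fem_lat_anterior",
             "fem_notch_center", "fem_shaft_point",
             "tib_knee_center", "tib_tubercle", "tib_med_plateau",
             "tib_lat_plateau", "tib_ant_edge", "tib_post_edge",
             "tib_med_spine", "tib_lat_spine", "tib_pcl_insertion",
             "ankle_center", "med_malleolus", "lat_malleolus"),
    bone = rep(c("femur", "tibia"), times = c(14L, 12L)),
    stringsAsFactors = FALSE
  )
}

# Deterministic quasi-uniform points on a unit sphere (golden-spiral lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1L
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

ellipsoid_patch <- function(n, center, radii) {
  sweep(fibonacci_sphere(n) %*% diag(radii), 2, center, "+")
}

ring <- function(n, center, radii_xy, z) {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + radii_xy[1] * cos(th), center[2] + radii_xy[2] * sin(th),
        rep(z, n))
}

shaft_points <- function(z_from, z_to, n_rings, n_per_ring, radius, drift = 0) {
  zs <- seq(z_from, z_to, length.out = n_rings)
  do.call(rbind, lapply(zs, function(z)
    ring(n_per_ring, c(drift * (z - z_from) / (z_to - z_from), 0), c(radius, radius), z)))
}

femur_template_landmarks <- function() {
  rbind(
    hip_center           = c(5, 8, 400),
    fem_knee_center      = c(0, 0, 0),
    fem_med_epicondyle   = c(40, 0, 12),
    fem_lat_epicondyle   = c(-40, 0, 12),
    fem_med_distal       = c(22, 0, -5),
    fem_lat_distal       = c(-22, 0, -5),
    fem_med_posterior    = c(22, -30, 8),
    fem_lat_posterior    = c(-22, -30, 8),
    fem_anterior_cortex  = c(0, 28, 45),
    fem_trochlear_groove = c(0, 22, 10),
    fem_med_anterior     = c(20, 20, 15),
    fem_lat_anterior     = c(-20, 20, 15),
    fem_notch_center     = c(0, -10, 0),
    fem_shaft_point      = c(2, 4, 200)
  )
}

tibia_template_landmarks <- function() {
  rbind(
    tib_knee_center   = c(0, 0, 0),
    tib_tubercle      = c(5, 28, -25),
    tib_med_plateau   = c(37, 0, -1),
    tib_lat_plateau   = c(-37, 0, -1),
    tib_ant_edge      = c(0, 25, -1),
    tib_post_edge     = c(0, -22, -1),
    tib_med_spine     = c(8, -2, 5),
    tib_lat_spine     = c(-8, -2, 5),
    tib_pcl_insertion = c(0, -18, -5),
    ankle_center      = c(4, 6, -340),
    med_malleolus     = c(25, 3, -335),
    lat_malleolus     = c(-25, 3, -335)
  )
}

# Template point cloud + named landmark row indices.
bone_template <- function(bone = c("femur", "tibia")) {
  bone <- match.arg(bone)
  if (bone == "femur") {
    surf <- rbind(
      ellipsoid_patch(45, c(22, -8, 6), c(14, 19, 13)),   # medial condyle
      ellipsoid_patch(45, c(-22, -8, 6), c(14, 19, 13)),  # lateral condyle
      ellipsoid_patch(16, c(0, 16, 25), c(20, 9, 16)),    # trochlea / ant flange
      shaft_points(60, 380, 8L, 6L, 14, drift = 4)
    )
    lm <- femur_template_landmarks()
  } else {
    surf <- rbind(
      ring(18, c(0, 1, 0), c(36, 24), -1),                # plateau rim
      ring(12, c(0, 1, 0), c(20, 14), -1),                # plateau inner
      ring(12, c(0, 0, 0), c(24, 18), -25),               # metaphysis
      shaft_points(-50, -320, 8L, 6L, 12, drift = 3),
      ring(8, c(0, 4, 0), c(18, 14), -335)                # distal tibia
    )
    lm <- tibia_template_landmarks()
  }
  pts <- rbind(surf, lm)
  idx <- stats::setNames(nrow(surf) + seq_len(nrow(lm)), rownames(lm))
  list(points = unname(pts), landmark_index = idx)
}

# Smooth, mostly-linear random deformation of a template: anisotropic +
# global scaling, taper, bow and a coronal tilt, followed by a random rigid
# motion (which the Procrustes alignment later removes). `shared` lets the
# femur and tibia of one synthetic knee covary in size.
deform_template <- function(template, shared, own, rigid) {
  P <- template$points
  zr <- range(P[, 3])
  zn <- (P[, 3] - mean(zr)) / (diff(zr) / 2)  # normalized in [-1, 1]
  sx <- shared["sx"] * own["sx"]; sy <- shared["sy"] * own["sy"]
  sz <- shared["sz"] * own["sz"]; s <- shared["s"]
  Q <- cbind(P[, 1] * sx * (1 + own["taper_x"] * zn) + own["bow"] * (1 - zn^2) * 30 +
               own["tilt"] * zn * 15,
             P[, 2] * sy * (1 + own["taper_y"] * zn),
             P[, 3] * sz) * s
  # random rigid motion
  ang <- rigid[1:3]
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  sweep(Q %*% t(Rz %*% Ry %*% Rx), 2, rigid[4:6], "+")
}

draw_deform_params <- function() {
  shared <- c(s = 1 + 0.06 * rnorm(1), sx = 1 + 0.04 * rnorm(1),
              sy = 1 + 0.04 * rnorm(1), sz = 1 + 0.03 * rnorm(1))
  own <- function() c(sx = 1 + 0.025 * rnorm(1), sy = 1 + 0.025 * rnorm(1),
                      sz = 1 + 0.02 * rnorm(1), taper_x = 0.03 * rnorm(1),
                      taper_y = 0.03 * rnorm(1), bow = 0.02 * rnorm(1),
                      tilt = 0.04 * rnorm(1))
  list(shared = shared, femur = own(), tibia = own())
}

#' Build the synthetic knee shape model
#'
#' Trains one statistical shape model per bone on procedurally deformed
#' template point clouds (ellipsoid-composite femur and tibia templates with
#' the 26 landmarks as dedicated points). The deformations vary overall size,
#' mediolateral/anteroposterior proportions, taper, bow and coronal tilt,
#' with a shared size component so the two bones of one knee covary; random
#' rigid motions are applied and removed again by the Procrustes alignment
#' inside [build_shape_model()].
#'
#' @param n_training number of synthetic training knees (default 60).
#' @param n_modes variation modes to retain per bone (default 20).
#' @param seed integer seed; the model is a pure function of its arguments.
#' @return An object of class `knee_shape_model` with elements `femur` and
#'   `tibia` (each a `shape_model` carrying landmark indices), plus the
#'   generation settings.
#' @export
build_synthetic_knee_model <- function(n_training = 60L, n_modes = 20L, seed = 1L) {
  if (n_training < 2L) stop("need at least 2 training knees")
  tf <- bone_template("femur")
  tt <- bone_template("tibia")
  shapes <- with_seed(seed_stream(seed, "knee-model"), {
    lapply(seq_len(n_training), function(i) {
      par <- draw_deform_params()
      rig <- function() c(rnorm(3, 0, 0.08), rnorm(3, 0, 10))
      list(femur = deform_template(tf, par$shared, par$femur, rig()),
           tibia = deform_template(tt, par$shared, par$tibia, rig()))
    })
  })
  structure(list(
    femur = build_shape_model(lapply(shapes, `[[`, "femur"), n_modes,
                              landmark_index = tf$landmark_index),
    tibia = build_shape_model(lapply(shapes, `[[`, "tibia"), n_modes,
                              landmark_index = tt$landmark_index),
    n_training = n_training, seed = seed
  ), class = "knee_shape_model")
}

#' @export
print.knee_shape_model <- function(x, ...) {
  cat("Synthetic knee shape model (", x$n_training, " training knees)\n", sep = "")
  cat("  femur: "); print(x$femur)
  cat("  tibia: "); print(x$tibia)
  invisible(x)
}
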