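# Anatomy objects: per-case bone point sets (optional), the 26 named
# landmarks, anatomical frames and derived bone dimensions.

# Bone dimensions and the joint-line varus proxy, all computed from landmark
# coordinates expressed in the bone's own anatomical frame (rigid-invariant).
derive_dims <- function(landmarks, frames) {
  Lf <- to_frame(landmarks[landmark_schema()$bone == "femur", , drop = FALSE],
                 frames$femoral)
  rownames(Lf) <- landmark_schema()$name[landmark_schema()$bone == "femur"]
  Lt <- to_frame(landmarks[landmark_schema()$bone == "tibia", , drop = FALSE],
                 frames$tibial)
  rownames(Lt) <- landmark_schema()$name[landmark_schema()$bone == "tibia"]
  post_mid_ap <- mean(Lf[c("fem_med_posterior", "fem_lat_posterior"), "ap"])
  dz <- Lf["fem_med_distal", "pd"] - Lf["fem_lat_distal", "pd"]
  dx <- Lf["fem_med_distal", "ml"] - Lf["fem_lat_distal", "ml"]
  c(
    fem_ml_width = unname(Lf["fem_med_epicondyle", "ml"] -
                            Lf["fem_lat_epicondyle", "ml"]),
    fem_condylar_width = unname(Lf["fem_med_distal", "ml"] -
                                  Lf["fem_lat_distal", "ml"]),
    fem_ap_depth = unname(Lf["fem_anterior_cortex", "ap"] - post_mid_ap),
    tib_ml_width = unname(Lt["tib_med_plateau", "ml"] -
                            Lt["tib_lat_plateau", "ml"]),
    tib_ap_depth = unname(Lt["tib_ant_edge", "ap"] - Lt["tib_post_edge", "ap"]),
    joint_line_varus = unname(atan2(dz, dx) * 180 / pi)
  )
}

new_anatomy <- function(femur_points, tibia_points, landmarks, coefficients) {
  if (nrow(landmarks) != 26L)
    stop("expected 26 landmarks, got ", nrow(landmarks))
  miss <- setdiff(landmark_schema()$name, rownames(landmarks))
  if (length(miss)) stop("missing landmarks: ", paste(miss, collapse = ", "))
  landmarks <- landmarks[landmark_schema()$name, , drop = FALSE]
  if (any(!is.finite(landmarks))) stop("non-finite landmark coordinates")
  frames <- build_frames(landmarks)
  dims <- derive_dims(landmarks, frames)
  if (any(dims[c("fem_ml_width", "fem_ap_depth", "tib_ml_width",
                 "tib_ap_depth")] <= 0))
    stop("non-positive bone dimension; landmark geometry is inconsistent")
  structure(list(femur_points = femur_points, tibia_points = tibia_points,
                 landmarks = landmarks, coefficients = coefficients,
                 frames = frames, dims = dims),
            class = "anatomy")
}

# Build an anatomy from per-bone point sets sampled from / matching the knee
# model (landmarks are designated rows of the point sets).
anatomy_from_points <- function(femur_points, tibia_points, model,
                                coefficients = NULL) {
  lm <- rbind(femur_points[model$femur$landmark_index, , drop = FALSE],
              tibia_points[model$tibia$landmark_index, , drop = FALSE])
  rownames(lm) <- c(names(model$femur$landmark_index),
                    names(model$tibia$landmark_index))
  lm <- lm[landmark_schema()$name, , drop = FALSE]
  new_anatomy(femur_points, tibia_points, lm, coefficients)
}

#' Build an anatomy from landmark coordinates alone
#'
#' Used when reading datasets from disk without the full point sets; all
#' feature extraction except shape-coefficient fitting works from landmarks.
#'
#' @param landmarks 26 x 3 matrix with [landmark_schema()] row names.
#' @param coefficients optional list with per-bone shape coefficients.
#' @return An `anatomy` object (with `NULL` point sets).
#' @export
anatomy_from_landmarks <- function(landmarks, coefficients = NULL) {
  landmarks <- as.matrix(landmarks)[landmark_schema()$name, , drop = FALSE]
  new_anatomy(NULL, NULL, landmarks, coefficients)
}

#' @export
print.anatomy <- function(x, ...) {
  cat("Anatomy: fem ML", round(x$dims["fem_ml_width"], 1), "mm, fem AP",
      round(x$dims["fem_ap_depth"], 1), "mm, tib ML",
      round(x$dims["tib_ml_width"], 1), "mm",
      if (is.null(x$femur_points)) "(landmarks only)" else "", "\n")
  invisible(x)
}

#' Sample a synthetic anatomy from the knee shape model
#'
#' Mode coefficients are drawn independently from zero-mean normals with the
#' model's per-mode variances; the bone point sets are reconstructed from them
#' and the landmarks read off their designated rows. Deterministic given the
#' seed.
#'
#' @param model a [build_synthetic_knee_model()] result.
#' @param seed integer seed.
#' @return An `anatomy` object carrying the true shape coefficients.
#' @export
sample_anatomy <- function(model, seed) {
  stopifnot(inherits(model, "knee_shape_model"))
  with_seed(seed_stream(seed, "anatomy"), {
    cf <- rnorm(ncol(model$femur$modes), 0, sqrt(model$femur$variances))
    ct <- rnorm(ncol(model$tibia$modes), 0, sqrt(model$tibia$variances))
    anatomy_from_points(reconstruct_shape(model$femur, cf),
                        reconstruct_shape(model$tibia, ct),
                        model, coefficients = list(femur = cf, tibia = ct))
  })
}

#' Apply a rigid motion to an anatomy
#'
#' Mainly for testing rigid invariance of the feature pipeline: rotates and
#' translates both bones' points and landmarks by the same transform.
#'
#' @param anatomy an `anatomy`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector.
#' @return The transformed `anatomy`.
#' @export
transform_anatomy <- function(anatomy, rotation, translation) {
  tf <- function(P) if (is.null(P)) NULL else
    sweep(P %*% t(rotation), 2, translation, "+")
  lm <- tf(anatomy$landmarks)
  rownames(lm) <- rownames(anatomy$landmarks)
  new_anatomy(tf(anatomy$femur_points), tf(anatomy$tibia_points), lm,
              anatomy$coefficients)
}
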