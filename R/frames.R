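# Anatomical coordinate frames. The femoral frame has its origin at the
# femoral knee center, proximodistal axis toward the hip center (mechanical
# axis), mediolateral axis from the epicondyles orthogonalized against it, and
# anteroposterior axis completing a right-handed triad (+ml medial, +ap
# anterior, +pd proximal). The tibial frame is analogous (knee center toward
# ankle center, plateau edge points for the mediolateral direction).

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) stop("degenerate direction (zero-length vector)")
  v / n
}

make_frame <- function(origin, pd_point, ml_from, ml_to) {
  pd <- unit_vector(pd_point - origin)
  ml0 <- ml_to - ml_from
  ml <- ml0 - sum(ml0 * pd) * pd
  if (sqrt(sum(ml^2)) < 1e-6 * sqrt(sum(ml0^2)) || sqrt(sum(ml0^2)) < 1e-9)
    stop("degenerate frame: defining landmarks are collinear")
  ml <- unit_vector(ml)
  ap <- c(pd[2] * ml[3] - pd[3] * ml[2],
          pd[3] * ml[1] - pd[1] * ml[3],
          pd[1] * ml[2] - pd[2] * ml[1])  # ap = pd x ml, right-handed
  axes <- cbind(ml = ml, ap = ap, pd = pd)
  structure(list(origin = origin, axes = axes), class = "anatomical_frame")
}

#' Build femoral and tibial anatomical frames
#'
#' @param landmarks a 26 x 3 matrix with row names following
#'   [landmark_schema()], or an `anatomy` object.
#' @return A list with elements `femoral` and `tibial`, each an
#'   `anatomical_frame` (origin plus a 3 x 3 orthonormal, right-handed axis
#'   matrix with columns `ml`, `ap`, `pd`).
#' @export
build_frames <- function(landmarks) {
  if (inherits(landmarks, "anatomy")) landmarks <- landmarks$landmarks
  need <- c("fem_knee_center", "hip_center", "fem_lat_epicondyle",
            "fem_med_epicondyle", "tib_knee_center", "ankle_center",
            "tib_lat_plateau", "tib_med_plateau")
  miss <- setdiff(need, rownames(landmarks))
  if (length(miss)) stop("missing landmarks: ", paste(miss, collapse = ", "))
  if (any(!is.finite(landmarks[need, ]))) stop("non-finite landmark coordinates")
  list(
    femoral = make_frame(landmarks["fem_knee_center", ],
                         landmarks["hip_center", ],
                         landmarks["fem_lat_epicondyle", ],
                         landmarks["fem_med_epicondyle", ]),
    tibial = make_frame(landmarks["tib_knee_center", ],
                        # proximodistal axis points proximally, away from ankle
                        2 * landmarks["tib_knee_center", ] -
                          landmarks["ankle_center", ],
                        landmarks["tib_lat_plateau", ],
                        landmarks["tib_med_plateau", ])
  )
}

#' Express points in an anatomical frame
#'
#' @param points an `n x 3` matrix (or length-3 vector) of world coordinates.
#' @param frame an `anatomical_frame`.
#' @return Coordinates in the frame (columns ml, ap, pd).
#' @export
to_frame <- function(points, frame) {
  if (is.null(dim(points))) points <- matrix(points, 1L)
  out <- sweep(points, 2, frame$origin) %*% frame$axes
  colnames(out) <- c("ml", "ap", "pd")
  out
}
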