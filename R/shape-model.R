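# Statistical shape model: rigid generalized Procrustes alignment of
# corresponding point sets followed by a principal-component decomposition.
# Alignment is rigid (rotation + translation, no scale normalization) so that
# bone size -- the dominant predictor of implant size -- remains part of the
# modelled shape variation.

# Optimal rotation (Kabsch) aligning centered P onto centered Q: returns R
# such that Pc %*% R approximates Qc, with det(R) = +1.
kabsch_rotation <- function(Pc, Qc) {
  A <- crossprod(Pc, Qc)
  s <- svd(A)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

# Rigidly align points P (n x 3) onto target Q (n x 3).
rigid_align <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  R <- kabsch_rotation(Pc, Qc)
  sweep(Pc %*% R, 2, cq, "+")
}

# Rigid generalized Procrustes: returns the list of aligned point sets and the
# consensus mean shape.
procrustes_gpa <- function(point_sets, max_iter = 50L, tol = 1e-10) {
  aligned <- lapply(point_sets, function(P) sweep(P, 2, colMeans(P)))
  mean_shape <- aligned[[1L]]
  for (it in seq_len(max_iter)) {
    aligned <- lapply(aligned, function(P) rigid_align(P, mean_shape))
    new_mean <- Reduce(`+`, aligned) / length(aligned)
    new_mean <- sweep(new_mean, 2, colMeans(new_mean))
    delta <- sqrt(mean((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  list(aligned = aligned, mean = mean_shape)
}

#' Build a statistical shape model from corresponding point sets
#'
#' Point sets (one per training shape, with point-to-point correspondence) are
#' aligned by rigid generalized Procrustes analysis and the aligned
#' coordinates decomposed by principal components. The model describes any
#' bone as the mean shape plus a linear combination of orthonormal variation
#' modes; per-mode variances are non-increasing.
#'
#' @param point_sets list of at least two numeric `P x 3` matrices with equal
#'   row counts (corresponding points).
#' @param n_modes number of variation modes to retain (capped at the rank of
#'   the training set, `N - 1`).
#' @param landmark_index optional named integer vector mapping landmark names
#'   to point rows; carried through to sampled anatomies.
#' @return An object of class `shape_model`: `mean` (length-`3P` coordinate
#'   vector), `mean_points` (`P x 3`), `modes` (`3P x M`, orthonormal
#'   columns), `variances` (length `M`), `n_points`, `landmark_index`.
#' @export
build_shape_model <- function(point_sets, n_modes, landmark_index = NULL) {
  if (!is.list(point_sets) || length(point_sets) < 2L)
    stop("need at least 2 training shapes")
  P <- nrow(point_sets[[1L]])
  if (any(vapply(point_sets, nrow, 0L) != P))
    stop("all point sets must have the same number of points")
  g <- procrustes_gpa(point_sets)
  X <- do.call(rbind, lapply(g$aligned, as.vector))  # N x 3P
  mu <- colMeans(X)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  m <- min(n_modes, ncol(pc$rotation), length(point_sets) - 1L)
  structure(list(
    mean = mu,
    mean_points = matrix(mu, P, 3L),
    modes = pc$rotation[, seq_len(m), drop = FALSE],
    variances = pc$sdev[seq_len(m)]^2,
    n_points = P,
    landmark_index = landmark_index
  ), class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat("Shape model:", x$n_points, "points,", ncol(x$modes), "modes; top variances:",
      paste(signif(head(x$variances, 3), 3), collapse = ", "), "\n")
  invisible(x)
}

#' Reconstruct a shape from mode coefficients
#'
#' @param model a [build_shape_model()] result.
#' @param coefficients numeric vector of mode coefficients (length at most the
#'   number of modes); zero coefficients give the mean shape.
#' @return A `P x 3` point matrix.
#' @export
reconstruct_shape <- function(model, coefficients) {
  stopifnot(inherits(model, "shape_model"))
  k <- length(coefficients)
  if (k > ncol(model$modes)) stop("more coefficients than modes")
  v <- model$mean
  if (k > 0L) v <- v + as.vector(model$modes[, seq_len(k), drop = FALSE] %*% coefficients)
  matrix(v, model$n_points, 3L)
}

#' Fit shape-model coefficients to a point set
#'
#' Removes pose by rigid Procrustes alignment and projects the aligned
#' coordinates onto the leading variation modes, alternating alignment and
#' projection until the coefficients stabilize. For shapes lying in the model
#' span the recovered coefficients are exact up to numerical tolerance.
#'
#' @param model a [build_shape_model()] result.
#' @param points a `P x 3` matrix with the model's point count and
#'   correspondence.
#' @param n_coefficients number of leading modes to fit (default 15, capped at
#'   the number of modes).
#' @return Numeric coefficient vector of length `n_coefficients`.
#' @export
fit_shape_coefficients <- function(model, points, n_coefficients = 15L) {
  stopifnot(inherits(model, "shape_model"))
  if (is.null(points) || nrow(points) != model$n_points)
    stop("point count does not match the shape model (expected ",
         model$n_points, ")")
  k <- min(n_coefficients, ncol(model$modes))
  B <- model$modes[, seq_len(k), drop = FALSE]
  target <- model$mean_points
  coefs <- rep(0, k)
  for (it in seq_len(100L)) {
    aligned <- rigid_align(points, target)
    new_coefs <- as.vector(crossprod(B, as.vector(aligned) - model$mean))
    target <- matrix(model$mean + as.vector(B %*% new_coefs),
                     model$n_points, 3L)
    if (max(abs(new_coefs - coefs)) < 1e-12) {
      coefs <- new_coefs
      break
    }
    coefs <- new_coefs
  }
  coefs
}
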