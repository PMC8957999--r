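# Training-time standardization: columns to zero mean / unit SD (constant
# columns zeroed and flagged), targets centered. The transform is stored so it
# can be re-applied to held-out data and inverted for predictions.

#' Standardize a design matrix and targets
#'
#' @param X numeric matrix (N x d), N >= 2.
#' @param y numeric vector or matrix of targets.
#' @return A list: `X` (standardized), `y` (centered), `transform` (list with
#'   `x_center`, `x_scale`, `constant` flag per column, `y_center`).
#'   Constant columns are set to zero, forcing their coefficients to zero
#'   downstream.
#' @export
standardize <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows to standardize")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2L, sd)
  constant <- !is.finite(x_scale) | x_scale < 1e-12
  x_scale[constant] <- 1
  Xs <- sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  Xs[, constant] <- 0
  ym <- is.matrix(y)
  Y <- as.matrix(y)
  y_center <- colMeans(Y)
  Ys <- sweep(Y, 2L, y_center)
  transform <- list(x_center = x_center, x_scale = x_scale,
                    constant = constant, y_center = y_center)
  list(X = Xs, y = if (ym) Ys else as.vector(Ys), transform = transform)
}

#' Apply a stored standardization transform to new data
#'
#' @param transform the `transform` element of a [standardize()] result.
#' @param X new rows on the original scale.
#' @return The standardized matrix.
#' @export
apply_standardization <- function(transform, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2L, transform$x_center), 2L, transform$x_scale, "/")
  Xs[, transform$constant] <- 0
  Xs
}
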