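# Epsilon-insensitive support vector regression with a Gaussian RBF kernel.
# The dual QP is solved by libsvm's SMO (via e1071); the fitted model is
# stored as an explicit kernel expansion (support points, dual coefficients,
# bias) so predictions are a transparent sum alpha_i K(x_i, .) + b.

#' Gaussian RBF kernel matrix
#'
#' `K(x, z) = exp(-||x - z||^2 / (2 sigma^2))`; unit diagonal, symmetric
#' positive semi-definite.
#'
#' @param X1,X2 row-wise point matrices (same number of columns).
#' @param sigma bandwidth (> 0).
#' @return The `nrow(X1) x nrow(X2)` Gram matrix.
#' @export
rbf_kernel <- function(X1, X2, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-pmax(d2, 0) / (2 * sigma^2))
}

#' Fit epsilon-SVR with an RBF kernel
#'
#' Solves the epsilon-insensitive dual QP (box constraints `[-C, C]`, equality
#' constraint `sum(alpha) = 0`) with the Gaussian kernel. The quadratic
#' program is solved by libsvm's SMO decomposition; the returned model stores
#' the support points, dual coefficients and bias of the kernel expansion.
#'
#' @param X training inputs (N x p), N >= 2.
#' @param y training targets.
#' @param epsilon tube half-width (> 0).
#' @param C box constraint (> 0).
#' @param sigma RBF bandwidth (> 0).
#' @param tolerance SMO termination tolerance (default 1e-3; tighten for
#'   high-precision solutions).
#' @return An object of class `svr_model`: `support` (support points),
#'   `coefficients` (dual coefficients `alpha+ - alpha-` at the support
#'   points), `bias`, and the hyperparameters.
#' @export
fit_svr <- function(X, y, epsilon, C, sigma, tolerance = 1e-3) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 training points")
  if (epsilon <= 0 || C <= 0 || sigma <= 0)
    stop("hyperparameters must be positive")
  # fitted = FALSE: flat targets can yield zero support vectors (every point
  # inside the tube), which breaks libsvm's internal fitted-value pass
  fit <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = C, epsilon = epsilon,
                    scale = FALSE, tolerance = tolerance, fitted = FALSE)
  structure(list(support = X[fit$index, , drop = FALSE],
                 coefficients = as.vector(fit$coefs), bias = -fit$rho,
                 epsilon = epsilon, C = C, sigma = sigma, p = ncol(X)),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("eps-SVR: ", nrow(x$support), " support vectors (eps=", x$epsilon,
      ", C=", x$C, ", sigma=", signif(x$sigma, 3), ")\n", sep = "")
  invisible(x)
}

#' @export
predict.svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature dimension mismatch: expected ", object$p)
  if (!nrow(object$support)) return(rep(object$bias, nrow(newdata)))
  as.vector(rbf_kernel(newdata, object$support, object$sigma) %*%
              object$coefficients) + object$bias
}

# dual objective of the eps-SVR QP at dual coefficients beta = alpha+ - alpha-
# (evaluated with this package's kernel; used for solver/oracle comparisons):
# -0.5 beta'K beta - epsilon ||beta||_1 + y'beta  (to be maximized)
svr_dual_objective <- function(K, y, epsilon, beta) {
  -0.5 * sum(beta * (K %*% beta)) - epsilon * sum(abs(beta)) + sum(y * beta)
}
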