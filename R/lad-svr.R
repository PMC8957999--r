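# Robust kernel regression with a Huber loss (least-absolute-deviation SVR).
# The model is a kernel expansion f(x) = sum_i alpha_i K(x_i, x) + b fitted by
# minimizing
#
#   J(alpha, b) = 0.5 alpha' K alpha + C sum_i huber_delta(y_i - f(x_i))
#
# with huber_delta(r) = r^2/2 for |r| <= delta and delta|r| - delta^2/2
# beyond. Large residuals are penalized linearly, so isolated outliers barely
# move the fit. The objective is smooth and convex; it is minimized by a
# damped Newton method with backtracking line search, which converges in a
# handful of iterations at the per-surgeon sample sizes this package targets.

huber_loss <- function(r, delta) {
  a <- abs(r)
  ifelse(a <= delta, 0.5 * r^2, delta * a - 0.5 * delta^2)
}

huber_grad <- function(r, delta) pmax(pmin(r, delta), -delta)

lad_svr_objective <- function(K, y, C, delta, alpha, b) {
  0.5 * sum(alpha * (K %*% alpha)) +
    C * sum(huber_loss(y - as.vector(K %*% alpha) - b, delta))
}

#' Fit a Huber-loss (LAD) kernel SVR by Newton's method
#'
#' @param X training inputs (N x p), N >= 2.
#' @param y training targets.
#' @param C loss weight (> 0).
#' @param sigma RBF bandwidth (> 0).
#' @param delta Huber threshold (> 0); default 1, intended for standardized
#'   targets.
#' @param max_iter maximum Newton iterations (default 100).
#' @param tol gradient-norm convergence tolerance (default 1e-6).
#' @return An object of class `lad_svr_model`: `support` (the training
#'   points), `coefficients` (kernel expansion weights), `bias`,
#'   hyperparameters, and the iteration trace of objective values.
#' @export
fit_lad_svr <- function(X, y, C, sigma, delta = 1, max_iter = 100L,
                        tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 training points")
  if (C <= 0 || sigma <= 0) stop("hyperparameters must be positive")
  if (delta <= 0) stop("delta must be positive")
  K <- rbf_kernel(X, X, sigma)
  ridge <- 1e-8 * n
  alpha <- numeric(n)
  b <- median(y)
  obj <- lad_svr_objective(K, y, C, delta, alpha, b)
  trace <- obj
  for (it in seq_len(max_iter)) {
    f <- as.vector(K %*% alpha) + b
    r <- y - f
    psi <- huber_grad(r, delta)
    g_alpha <- as.vector(K %*% (alpha - C * psi))
    g_b <- -C * sum(psi)
    gnorm <- max(abs(c(g_alpha, g_b)))
    if (gnorm < tol) break
    w <- as.numeric(abs(r) <= delta)      # Huber second derivative
    # Newton system in (alpha, b); K factored out of the alpha block:
    #   [K (I + C W K)   C K w] [da]   [g_alpha]
    #   [C w'K           C 1'w] [db] = [g_b]
    # Solve the equivalent symmetric system with K absorbed where possible.
    H <- rbind(cbind(K + C * K %*% (w * K) + ridge * diag(n), C * (K %*% w)),
               c(C * as.vector(w %*% K), C * sum(w) + ridge))
    step <- tryCatch(solve(H, c(g_alpha, g_b)),
                     error = function(e) c(g_alpha, g_b) / (sum(abs(H)) / n))
    t_ls <- 1
    repeat {
      na <- alpha - t_ls * step[seq_len(n)]
      nb <- b - t_ls * step[n + 1L]
      new_obj <- lad_svr_objective(K, y, C, delta, na, nb)
      if (new_obj <= obj + 1e-12 || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    if (new_obj > obj) break             # no further descent possible
    alpha <- na; b <- nb; obj <- new_obj
    trace <- c(trace, obj)
    if (it == max_iter)
      stop("LAD-SVR Newton did not converge: gradient norm ",
           signif(gnorm, 3), " after ", max_iter, " iterations")
  }
  structure(list(support = X, coefficients = alpha, bias = b, C = C,
                 sigma = sigma, delta = delta, objective_trace = trace,
                 p = ncol(X)),
            class = "lad_svr_model")
}

#' @export
print.lad_svr_model <- function(x, ...) {
  cat("LAD-SVR (Huber/Newton): n=", nrow(x$support), ", C=", x$C,
      ", sigma=", signif(x$sigma, 3), ", delta=", x$delta,
      ", final objective ",
      signif(x$objective_trace[length(x$objective_trace)], 5), "\n",
      sep = "")
  invisible(x)
}

#' @export
predict.lad_svr_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("feature dimension mismatch: expected ", object$p)
  as.vector(rbf_kernel(newdata, object$support, object$sigma) %*%
              object$coefficients) + object$bias
}
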