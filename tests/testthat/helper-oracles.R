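# Independent oracles used for solver-equivalence checks.

obj_lasso_ <- function(X, y, th, lam)
  0.5 * sum((y - X %*% th)^2) + lam * sum(abs(th))

obj_group_ <- function(X, y, th, lam, grp) {
  pen <- sum(vapply(seq_len(grp$n_groups) - 1L, function(g)
    grp$weights[g + 1L] * sqrt(sum(th[grp$id == g]^2)), 0))
  0.5 * sum((y - X %*% th)^2) + lam * pen
}

obj_mtl_ <- function(X, Y, Th, lam)
  0.5 * sum((Y - X %*% Th)^2) + lam * sum(sqrt(rowSums(Th^2)))

# proximal-gradient (FISTA) group-lasso oracle
fista_group_lasso <- function(X, y, grp, lam, iters = 4000L) {
  d <- ncol(X)
  L <- max(eigen(crossprod(X), only.values = TRUE)$values)
  th <- numeric(d); zz <- th; tk <- 1
  for (i in seq_len(iters)) {
    grad <- as.vector(crossprod(X, X %*% zz - y))
    u <- zz - grad / L
    new <- numeric(d)
    for (g in seq_len(grp$n_groups) - 1L) {
      idx <- grp$id == g
      nrm <- sqrt(sum(u[idx]^2))
      thr <- lam * grp$weights[g + 1L] / L
      if (nrm > thr) new[idx] <- (1 - thr / nrm) * u[idx]
    }
    tnew <- (1 + sqrt(1 + 4 * tk^2)) / 2
    zz <- new + (tk - 1) / tnew * (new - th)
    th <- new; tk <- tnew
  }
  th
}

# eps-SVR dual objective (to be maximized) at beta = alpha+ - alpha-
svr_dual_obj_ <- function(K, y, eps, beta)
  -0.5 * sum(beta * (K %*% beta)) - eps * sum(abs(beta)) + sum(y * beta)

# dense QP oracle for the eps-SVR dual via kernlab::ipop
ipop_svr_dual <- function(K, y, eps, C) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(2 * n) * 1e-10
  cvec <- c(eps - y, eps + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1L)
  sol <- kernlab::ipop(cvec, H, A, 0, rep(0, 2 * n), rep(C, 2 * n), 0,
                       sigf = 9, maxiter = 200)
  z <- kernlab::primal(sol)
  z[1:n] - z[(n + 1):(2 * n)]
}

# full dual coefficient vector of a fitted svr_model, aligned with X rows
svr_full_beta <- function(model, X) {
  beta <- numeric(nrow(X))
  key <- apply(round(X, 10), 1L, paste, collapse = ",")
  skey <- apply(round(model$support, 10), 1L, paste, collapse = ",")
  beta[match(skey, key)] <- model$coefficients
  beta
}

# primal LAD-SVR objective at par = c(alpha, b)
lad_obj_ <- function(K, y, C, delta, par) {
  n <- nrow(K)
  a <- par[seq_len(n)]; b <- par[n + 1L]
  r <- y - as.vector(K %*% a) - b
  h <- ifelse(abs(r) <= delta, 0.5 * r^2, delta * abs(r) - 0.5 * delta^2)
  0.5 * sum(a * (K %*% a)) + C * sum(h)
}

# squared-loss kernel comparator with matched (C, sigma): exact solve of
# min 0.5 a'Ka + C/2 * ||y - Ka - b||^2
squared_loss_kernel_fit <- function(X, y, C, sigma) {
  n <- length(y)
  K <- rbf_kernel(X, X, sigma)
  A <- rbind(cbind(K + diag(n) / C, rep(1, n)), c(rep(1, n), 0))
  sol <- solve(A, c(y, 0))
  structure(list(support = X, coefficients = sol[seq_len(n)], bias = sol[n + 1L],
                 sigma = sigma, p = ncol(X)), class = "lad_svr_model")
}
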