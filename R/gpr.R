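# Gaussian-process regression with an isotropic exponential kernel and a
# constant mean. The posterior mean at a query x* is
#   c + k*' (K + sn^2 I)^{-1} (y - c),   k*_i = sf^2 exp(-||x* - x_i|| / l)
# with the constant c profiled out by generalised least squares. Kernel
# matrices are built from Euclidean distances (not squared), matching the
# "exponential" kernel of standard GP toolboxes.

# pairwise Euclidean distance between rows of A and rows of B
euclid_cross <- function(A, B) {
  a2 <- rowSums(A^2)
  b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

exp_kernel <- function(D, lengthscale, sigma_f) {
  sigma_f^2 * exp(-D / lengthscale)
}

# log marginal likelihood with c profiled by GLS; returns -Inf on failure.
# D: training distance matrix; jitter stabilises the Cholesky.
gpr_lml <- function(D, y, lengthscale, sigma_f, sigma_n, jitter = 1e-8) {
  n <- length(y)
  A <- exp_kernel(D, lengthscale, sigma_f)
  diag(A) <- diag(A) + sigma_n^2 + jitter
  L <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(L)) return(-Inf)
  ones <- rep(1, n)
  Ainv_y <- backsolve(L, forwardsolve(t(L), y))
  Ainv_1 <- backsolve(L, forwardsolve(t(L), ones))
  cc <- sum(ones * Ainv_y) / sum(ones * Ainv_1)
  r <- y - cc
  Ainv_r <- Ainv_y - cc * Ainv_1
  -0.5 * sum(r * Ainv_r) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

# maximise the log marginal likelihood over (lengthscale, sigma_f, sigma_n)
# on the log scale with multi-start L-BFGS-B. Starts are scaled from the
# median pairwise distance and sd(y) (the usual automatic initialisation).
gpr_optimize <- function(D, y, n_restarts = 2L, jitter = 1e-8) {
  d_med <- stats::median(D[upper.tri(D)])
  if (!is.finite(d_med) || d_med <= 0) d_med <- 1
  s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y <= 0) s_y <- 1
  negll <- function(par) {
    v <- -gpr_lml(D, y, exp(par[1]), exp(par[2]), exp(par[3]), jitter)
    if (!is.finite(v)) 1e10 else v
  }
  starts <- list(log(c(d_med, s_y, s_y / sqrt(2))))
  mults <- c(0.3, 3, 0.1)
  for (k in seq_len(max(0L, n_restarts - 1L))) {
    starts[[k + 1L]] <- starts[[1L]] + log(c(mults[(k - 1) %% 3 + 1], 1, 1))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, negll, method = "L-BFGS-B",
                   lower = log(c(d_med * 1e-3, s_y * 1e-3, s_y * 1e-4)),
                   upper = log(c(d_med * 1e3, s_y * 1e3, s_y * 1e2)),
                   control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("GP hyperparameter optimisation failed",
                          call. = FALSE)
  p <- exp(best$par)
  list(lengthscale = p[1], sigma_f = p[2], sigma_n = p[3],
       lml = -best$value)
}

# factorise the training system once; returns what prediction needs
gpr_factorize <- function(X, y, lengthscale, sigma_f, sigma_n,
                          jitter = 1e-8) {
  D <- euclid_cross(X, X)
  A <- exp_kernel(D, lengthscale, sigma_f)
  diag(A) <- diag(A) + sigma_n^2 + jitter
  L <- tryCatch(chol(A), error = function(e) {
    stop("kernel matrix is numerically singular; increase noise or jitter",
         call. = FALSE)
  })
  ones <- rep(1, length(y))
  Ainv_y <- backsolve(L, forwardsolve(t(L), y))
  Ainv_1 <- backsolve(L, forwardsolve(t(L), ones))
  cc <- sum(Ainv_y) / sum(Ainv_1)
  alpha <- Ainv_y - cc * Ainv_1  # = A^{-1} (y - c)
  list(alpha = alpha, constant = cc)
}

gpr_posterior_mean <- function(Xnew, X, alpha, constant, lengthscale,
                               sigma_f) {
  Ks <- exp_kernel(euclid_cross(Xnew, X), lengthscale, sigma_f)
  drop(constant + Ks %*% alpha)
}
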