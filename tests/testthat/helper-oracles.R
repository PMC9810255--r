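# Independent oracles: deliberately written as direct dense formulas, not
# shared with the package's implementation.

# GP posterior mean by brute-force dense linear algebra:
# m(x*) = c + k*' (K + sn^2 I)^{-1} (y - c),  k = sf^2 exp(-||xi - xj|| / l)
oracle_gp_mean <- function(Xtrain, y, Xnew, lengthscale, sigma_f, sigma_n,
                           constant, jitter = 0) {
  n <- nrow(Xtrain)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      K[i, j] <- sigma_f^2 *
        exp(-sqrt(sum((Xtrain[i, ] - Xtrain[j, ])^2)) / lengthscale)
    }
  }
  A <- K + diag(sigma_n^2 + jitter, n)
  w <- solve(A, y - constant)
  vapply(seq_len(nrow(Xnew)), function(q) {
    k <- vapply(seq_len(n), function(i) {
      sigma_f^2 * exp(-sqrt(sum((Xnew[q, ] - Xtrain[i, ])^2)) / lengthscale)
    }, 0)
    constant + sum(k * w)
  }, 0)
}

# OLS slope/intercept by the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- mean(y) - slope * mean(x)
  c(alpha = slope, beta = intercept)
}

# ANCOVA group F and partial eta^2 by explicit projection sums of squares
oracle_ancova <- function(bag, group, covariate) {
  g <- as.numeric(factor(group)) - 1
  X_full <- cbind(1, g, covariate)
  X_red <- cbind(1, covariate)
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% bag)
    sum((bag - X %*% beta)^2)
  }
  ss_error <- rss(X_full)
  ss_group <- rss(X_red) - ss_error
  df_error <- length(bag) - ncol(X_full)
  list(F = (ss_group / 1) / (ss_error / df_error),
       partial_eta_sq = ss_group / (ss_group + ss_error))
}

# tiny deterministic feature table for GP tests
make_feature_table <- function(X, ids = sprintf("id%02d", seq_len(nrow(X)))) {
  df <- data.frame(participant_id = ids, X, stringsAsFactors = FALSE)
  names(df) <- c("participant_id", sprintf("f%02d", seq_len(ncol(X))))
  df
}

# cohort of controls with purely affine noiseless features (age decodable)
make_affine_controls <- function(n, p = 4, seed = 1) {
  set.seed(seed)
  age <- runif(n, 20, 84)
  load <- seq(0.5, 1.5, length.out = p)
  X <- outer(age, load) + matrix(rep(seq_len(p), each = n), n, p)
  list(features = make_feature_table(X),
       ages = stats::setNames(age, sprintf("id%02d", seq_len(n))))
}
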