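#' Gaussian-process regression specification for brain-age models
#'
#' Describes the GP used by [brainage_fit()]: an isotropic exponential kernel
#' \eqn{k(x, x') = \sigma_f^2 \exp(-\lVert x - x'\rVert / \ell)} over
#' (optionally standardized) features, a constant mean, and observation noise
#' \eqn{\sigma_n}. By default all hyperparameters are set by maximising the
#' log marginal likelihood; supply `lengthscale`, `sigma_f`, `sigma_n` (and
#' optionally `constant`) to fix them instead.
#'
#' @param standardize Standardize each feature to zero mean / unit SD using
#'   training statistics (default `TRUE`).
#' @param lengthscale,sigma_f,sigma_n,constant Optional fixed hyperparameters;
#'   `NULL` (default) means optimise (`constant` is always profiled by
#'   generalised least squares unless fixed).
#' @param n_restarts Number of optimiser starts for automatic fitting.
#' @param jitter Diagonal jitter added to the kernel matrix for conditioning.
#' @return Object of class `"gpr_spec"`.
#' @export
gpr_spec <- function(standardize = TRUE, lengthscale = NULL, sigma_f = NULL,
                     sigma_n = NULL, constant = NULL, n_restarts = 2L,
                     jitter = 1e-8) {
  for (nm in c("lengthscale", "sigma_f")) {
    v <- get(nm)
    if (!is.null(v) && (!is.numeric(v) || v <= 0)) {
      stop(sprintf("'%s' must be > 0", nm), call. = FALSE)
    }
  }
  if (!is.null(sigma_n) && (!is.numeric(sigma_n) || sigma_n < 0)) {
    stop("'sigma_n' must be >= 0", call. = FALSE)
  }
  structure(list(standardize = isTRUE(standardize), lengthscale = lengthscale,
                 sigma_f = sigma_f, sigma_n = sigma_n, constant = constant,
                 n_restarts = as.integer(n_restarts), jitter = jitter),
            class = "gpr_spec")
}

#' Split healthy controls into training and hold-out sets
#'
#' Randomly partitions control participant ids at the given ratio. The
#' hold-out set is never used in training and later supplies the matched
#' controls for window comparisons.
#'
#' @param participants data.frame with columns `participant_id` and
#'   `diagnosis`; only controls may be passed.
#' @param ratio Training fraction in (0, 1); the training size is
#'   `round(ratio * N)`.
#' @param seed Integer seed making the split reproducible.
#' @return List with character vectors `training` and `holdout` (disjoint,
#'   exhaustive).
#' @examples
#' hc <- data.frame(participant_id = sprintf("C%02d", 1:10),
#'                  diagnosis = "control")
#' split_controls(hc, 0.7, seed = 1)
#' @export
split_controls <- function(participants, ratio = 0.7, seed = 1L) {
  if (!all(participants$diagnosis == "control")) {
    stop("only control records may be split", call. = FALSE)
  }
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1) {
    stop("'ratio' must be in (0, 1)", call. = FALSE)
  }
  ids <- participants$participant_id
  n <- length(ids)
  if (n < 2L) stop("need at least 2 controls to split", call. = FALSE)
  n_train <- round(ratio * n)
  train <- with_seed(seed, sample(ids, n_train))
  list(training = sort(train), holdout = sort(setdiff(ids, train)))
}

# coerce a feature table (participant_id + feature columns) into a numeric
# matrix with participant ids as rownames, feature columns ordered by `order`
feature_matrix <- function(features, order = NULL) {
  if (!"participant_id" %in% names(features)) {
    stop("feature table must have a 'participant_id' column", call. = FALSE)
  }
  ids <- features$participant_id
  X <- as.matrix(features[setdiff(names(features), "participant_id")])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  if (!is.null(order)) {
    missing <- setdiff(order, colnames(X))
    if (length(missing)) {
      stop(sprintf("feature table lacks column(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    X <- X[, order, drop = FALSE]
  }
  X
}

#' Fit a brain-age model on healthy-control features
#'
#' Trains a Gaussian-process regressor of chronological age on a feature
#' table (one modality), the core of the brain-age pipeline. Features are
#' standardized with training statistics; kernel hyperparameters maximise the
#' log marginal likelihood unless fixed in `spec`. The fitted object predicts
#' a raw brain age for any cohort sharing the feature set, and can carry a
#' linear age-bias correction (see [fit_bias()]).
#'
#' @param features Feature table: data.frame with `participant_id` then one
#'   numeric column per feature. Rows restricted to training subjects.
#' @param ages Named numeric vector of chronological ages (years), names
#'   matching `participant_id`, or unnamed in row order.
#' @param spec A [gpr_spec()].
#' @param modality Optional label stored on the model (e.g. `"volume"`).
#' @return Object of class `"brainage_model"` with, among others, fitted
#'   hyperparameters, training standardization statistics, and the stored
#'   training design needed for kernel prediction.
#' @seealso [predict.brainage_model()], [fit_bias()], [repeated_cv()]
#' @export
brainage_fit <- function(features, ages, spec = gpr_spec(),
                         modality = NULL) {
  X <- feature_matrix(features)
  y <- align_ages(ages, rownames(X))
  if (length(y) < 1L) stop("no training subjects", call. = FALSE)

  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (nrow(X) > 1L && any(!is.finite(scl) | scl == 0)) {
    bad <- colnames(X)[!is.finite(scl) | scl == 0]
    stop(sprintf("constant feature(s) cannot be standardized: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (spec$standardize && nrow(X) > 1L) {
    Xs <- scale(X, center = ctr, scale = scl)
  } else {
    Xs <- X
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }

  fixed <- !is.null(spec$lengthscale) && !is.null(spec$sigma_f) &&
    !is.null(spec$sigma_n)
  if (fixed) {
    hp <- list(lengthscale = spec$lengthscale, sigma_f = spec$sigma_f,
               sigma_n = spec$sigma_n, lml = NA_real_)
  } else {
    D <- euclid_cross(Xs, Xs)
    hp <- gpr_optimize(D, y, n_restarts = spec$n_restarts,
                       jitter = spec$jitter)
  }
  fac <- gpr_factorize_c(Xs, y, hp$lengthscale, hp$sigma_f, hp$sigma_n,
                         spec$constant, spec$jitter)

  structure(list(
    modality = modality,
    feature_names = colnames(X),
    center = stats::setNames(as.numeric(ctr), colnames(X)),
    scale = stats::setNames(as.numeric(scl), colnames(X)),
    standardize = spec$standardize,
    hyperparameters = list(lengthscale = hp$lengthscale,
                           sigma_f = hp$sigma_f, sigma_n = hp$sigma_n,
                           constant = fac$constant),
    log_marginal_likelihood = hp$lml,
    jitter = spec$jitter,
    X_train = Xs,
    y_train = y,
    alpha = fac$alpha,
    bias_correction = NULL,
    call = match.call()
  ), class = "brainage_model")
}

# factorisation honouring an optional fixed constant mean
gpr_factorize_c <- function(Xs, y, lengthscale, sigma_f, sigma_n,
                            constant = NULL, jitter = 1e-8) {
  if (is.null(constant)) {
    return(gpr_factorize(Xs, y, lengthscale, sigma_f, sigma_n, jitter))
  }
  D <- euclid_cross(Xs, Xs)
  A <- exp_kernel(D, lengthscale, sigma_f)
  diag(A) <- diag(A) + sigma_n^2 + jitter
  L <- chol(A)
  alpha <- backsolve(L, forwardsolve(t(L), y - constant))
  list(alpha = alpha, constant = constant)
}

align_ages <- function(ages, ids) {
  if (!is.null(names(ages))) {
    missing <- setdiff(ids, names(ages))
    if (length(missing)) {
      stop(sprintf("ages missing for: %s",
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    as.numeric(ages[ids])
  } else {
    if (length(ages) != length(ids)) {
      stop("unnamed 'ages' must match the number of rows", call. = FALSE)
    }
    as.numeric(ages)
  }
}

#' Predict raw (and optionally corrected) brain age
#'
#' Applies the stored standardization then the GP posterior mean. Feature
#' columns are reconciled by name, so column order in `newdata` is
#' irrelevant. If the model carries a bias correction and `ages` are given,
#' corrected brain ages and brain-age gaps are returned too.
#'
#' @param object A fitted [brainage_fit()] model.
#' @param newdata Feature table (data.frame with `participant_id` column).
#' @param ages Optional named chronological ages for correction.
#' @param ... Unused.
#' @return If `ages` is `NULL`, a named numeric vector of raw brain ages.
#'   Otherwise a data.frame with columns `participant_id`, `age`,
#'   `raw_brain_age`, `corrected_brain_age`, `bag` (the latter two require a
#'   fitted bias correction).
#' @export
predict.brainage_model <- function(object, newdata, ages = NULL, ...) {
  X <- feature_matrix(newdata, order = object$feature_names)
  Xs <- scale(X, center = object$center, scale = object$scale)
  hp <- object$hyperparameters
  raw <- gpr_posterior_mean(Xs, object$X_train, object$alpha, hp$constant,
                            hp$lengthscale, hp$sigma_f)
  names(raw) <- rownames(X)
  if (is.null(ages)) return(raw)
  age <- align_ages(ages, rownames(X))
  out <- data.frame(participant_id = rownames(X), age = age,
                    raw_brain_age = as.numeric(raw),
                    stringsAsFactors = FALSE)
  if (!is.null(object$bias_correction)) {
    out$corrected_brain_age <- apply_correction(out$raw_brain_age, out$age,
                                                object$bias_correction)
    out$bag <- compute_bag(out$corrected_brain_age, out$age)
  }
  out
}

#' @export
print.brainage_model <- function(x, ...) {
  hp <- x$hyperparameters
  cat("Brain-age GP regression",
      if (!is.null(x$modality)) sprintf("(%s)", x$modality), "\n")
  cat(sprintf("  n = %d subjects, %d features%s\n", length(x$y_train),
              length(x$feature_names),
              if (x$standardize) " (standardized)" else ""))
  cat(sprintf(
    "  exponential kernel: lengthscale %.3g, sigma_f %.3g, sigma_n %.3g, constant %.3g\n",
    hp$lengthscale, hp$sigma_f, hp$sigma_n, hp$constant))
  if (is.finite(x$log_marginal_likelihood)) {
    cat(sprintf("  log marginal likelihood: %.2f\n",
                x$log_marginal_likelihood))
  }
  if (!is.null(x$bias_correction)) {
    bc <- x$bias_correction
    cat(sprintf("  age-bias correction: alpha %.4f, beta %.2f (n = %d, %s)\n",
                bc$alpha, bc$beta, bc$fit_n, bc$fit_source))
  }
  invisible(x)
}

#' @export
coef.brainage_model <- function(object, ...) {
  hp <- object$hyperparameters
  out <- c(lengthscale = hp$lengthscale, sigma_f = hp$sigma_f,
           sigma_n = hp$sigma_n, constant = hp$constant)
  if (!is.null(object$bias_correction)) {
    out <- c(out, alpha = object$bias_correction$alpha,
             beta = object$bias_correction$beta)
  }
  out
}

#' @export
residuals.brainage_model <- function(object, ...) {
  pred <- gpr_posterior_mean(object$X_train, object$X_train, object$alpha,
                             object$hyperparameters$constant,
                             object$hyperparameters$lengthscale,
                             object$hyperparameters$sigma_f)
  stats::setNames(object$y_train - pred, rownames(object$X_train))
}

#' @export
summary.brainage_model <- function(object, ...) {
  res <- residuals(object)
  pred <- object$y_train - res
  m <- evaluate_predictions(stats::setNames(pred, names(res)),
                            stats::setNames(object$y_train, names(res)))
  out <- list(model = object, training_mae = m[["mae"]],
              training_r = m[["pearson_r"]])
  class(out) <- "summary.brainage_model"
  out
}

#' @export
print.summary.brainage_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training fit (in-sample): MAE %.2f years, r %.3f\n",
              x$training_mae, x$training_r))
  invisible(x)
}

#' Plot predicted against chronological age
#'
#' @param x A fitted `brainage_model`.
#' @param newdata,ages Optional evaluation set; defaults to the training set
#'   (in-sample fit).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.brainage_model <- function(x, newdata = NULL, ages = NULL, ...) {
  if (is.null(newdata)) {
    pred <- x$y_train - residuals(x)
    age <- x$y_train
  } else {
    pred <- predict(x, newdata)
    age <- align_ages(ages, names(pred))
  }
  graphics::plot(age, pred, xlab = "Chronological age (years)",
                 ylab = "Predicted brain age (years)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Prediction accuracy metrics
#'
#' Mean absolute error and Pearson correlation between predicted and
#' chronological ages.
#'
#' @param predictions,ages Named numeric vectors over the same ids.
#' @return Named numeric vector `c(mae, pearson_r)`.
#' @examples
#' evaluate_predictions(c(a = 2, b = 3, c = 4), c(a = 1, b = 2, c = 3))
#' @export
evaluate_predictions <- function(predictions, ages) {
  if (!is.null(names(predictions)) && !is.null(names(ages))) {
    if (!setequal(names(predictions), names(ages))) {
      stop("'predictions' and 'ages' must cover the same ids", call. = FALSE)
    }
    ages <- ages[names(predictions)]
  } else if (length(predictions) != length(ages)) {
    stop("'predictions' and 'ages' must have equal length", call. = FALSE)
  }
  mae <- mean(abs(predictions - ages))
  r <- NA_real_
  if (length(predictions) >= 3L) {
    if (stats::sd(predictions) == 0 || stats::sd(ages) == 0) {
      stop("Pearson r undefined: zero variance", call. = FALSE)
    }
    r <- stats::cor(predictions, ages)
  }
  c(mae = mae, pearson_r = r)
}

#' Repeated k-fold cross-validation of the brain-age model
#'
#' Repeats the whole k-fold procedure `n_repeats` times, reshuffling the
#' fold assignment each repeat. Per repeat, MAE and Pearson r are computed on
#' the pooled out-of-fold predictions; summaries are the mean, SD and normal
#' 95% confidence interval over repeats.
#'
#' @param features,ages,spec As in [brainage_fit()].
#' @param n_folds Folds per repeat (default 5).
#' @param n_repeats Number of repeats (>= 1).
#' @param seed Seed controlling all fold assignments.
#' @return Object of class `"cv_report"`: per-repeat `mae` and `pearson_r`
#'   vectors, the out-of-fold predictions of the first repeat, and a
#'   `summary` data.frame (mean, sd, ci_lo, ci_hi per metric).
#' @export
repeated_cv <- function(features, ages, spec = gpr_spec(), n_folds = 5L,
                        n_repeats = 10L, seed = 1L) {
  n_folds <- check_count(n_folds, "n_folds")
  n_repeats <- check_count(n_repeats, "n_repeats")
  if (n_folds < 2L) stop("'n_folds' must be >= 2", call. = FALSE)
  X <- feature_matrix(features)
  ids <- rownames(X)
  n <- length(ids)
  if (n < n_folds) stop("fewer subjects than folds", call. = FALSE)
  y <- align_ages(ages, ids)
  names(y) <- ids

  folds_per_repeat <- with_seed(seed, lapply(seq_len(n_repeats), function(i) {
    sample(rep_len(seq_len(n_folds), n))
  }))

  mae <- r <- numeric(n_repeats)
  first_oof <- NULL
  for (i in seq_len(n_repeats)) {
    fold <- folds_per_repeat[[i]]
    oof <- rep(NA_real_, n)
    for (k in seq_len(n_folds)) {
      tr <- fold != k
      fit <- brainage_fit(features[tr, , drop = FALSE], y[ids[tr]], spec)
      oof[!tr] <- predict(fit, features[!tr, , drop = FALSE])
    }
    m <- evaluate_predictions(stats::setNames(oof, ids), y)
    mae[i] <- m[["mae"]]; r[i] <- m[["pearson_r"]]
    if (i == 1L) first_oof <- stats::setNames(oof, ids)
  }
  summarise <- function(v) {
    se <- stats::sd(v) / sqrt(length(v))
    c(mean = mean(v), sd = stats::sd(v),
      ci_lo = mean(v) - 1.96 * se, ci_hi = mean(v) + 1.96 * se)
  }
  structure(list(
    n_folds = n_folds, n_repeats = n_repeats,
    mae = mae, pearson_r = r,
    oof_predictions = first_oof,
    summary = rbind(mae = summarise(mae), pearson_r = summarise(r))
  ), class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Repeated %d-fold CV, %d repeat(s)\n", x$n_folds, x$n_repeats))
  s <- x$summary
  cat(sprintf("  MAE: %.2f +/- %.2f (95%% CI %.2f-%.2f)\n",
              s["mae", "mean"], s["mae", "sd"], s["mae", "ci_lo"],
              s["mae", "ci_hi"]))
  cat(sprintf("  r:   %.3f +/- %.3f (95%% CI %.3f-%.3f)\n",
              s["pearson_r", "mean"], s["pearson_r", "sd"],
              s["pearson_r", "ci_lo"], s["pearson_r", "ci_hi"]))
  invisible(x)
}
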