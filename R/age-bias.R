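#' Fit the linear age-bias correction
#'
#' Brain-age regressors systematically over-predict young and under-predict
#' old subjects. The correction fits ordinary least squares of raw brain age
#' on chronological age, \eqn{\widehat{ba} = \alpha\,\Omega + \beta}, on a
#' healthy reference set (typically the training set's out-of-fold
#' predictions); the fitted slope/intercept are then frozen and applied to
#' every cohort via [apply_correction()].
#'
#' @param raw_brain_ages Named numeric vector of raw predicted brain ages.
#' @param ages Named numeric vector of chronological ages over the same ids
#'   (or unnamed, in the same order).
#' @param fit_source Label recording which predictions were used
#'   (`"training_oof"` or `"training_refit"`).
#' @return Object of class `"bias_correction"` with fields `alpha`, `beta`,
#'   `fit_n`, `fit_source`.
#' @examples
#' fit_bias(c(a = 20, b = 30, c = 40), c(a = 20, b = 30, c = 40))
#' @export
fit_bias <- function(raw_brain_ages, ages, fit_source = "training_oof") {
  if (!is.null(names(raw_brain_ages)) && !is.null(names(ages))) {
    if (!setequal(names(raw_brain_ages), names(ages))) {
      stop("id sets differ between raw brain ages and ages", call. = FALSE)
    }
    ages <- ages[names(raw_brain_ages)]
  }
  n <- length(raw_brain_ages)
  if (n < 2L) stop("need at least 2 subjects to fit the correction",
                   call. = FALSE)
  if (stats::var(ages) == 0) {
    stop("zero age variance: bias correction undefined", call. = FALSE)
  }
  fit <- stats::lm(raw ~ age,
                   data = data.frame(raw = as.numeric(raw_brain_ages),
                                     age = as.numeric(ages)))
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 beta = unname(stats::coef(fit)[1]),
                 fit_n = n, fit_source = fit_source),
            class = "bias_correction")
}

#' @export
print.bias_correction <- function(x, ...) {
  cat(sprintf("Age-bias correction: alpha = %.4f, beta = %.3f (n = %d, %s)\n",
              x$alpha, x$beta, x$fit_n, x$fit_source))
  invisible(x)
}

#' Apply the age-bias correction
#'
#' Corrected brain age = raw brain age + \[\eqn{\Omega} - (\eqn{\alpha
#' \Omega + \beta})\], where \eqn{\Omega} is chronological age. On the set
#' used to fit the correction, the OLS slope of corrected brain age on age is
#' exactly 1 with intercept 0, so the corrected gap is age-orthogonal.
#'
#' @param raw Raw brain age(s), years.
#' @param age Chronological age(s), years.
#' @param bc A [fit_bias()] object.
#' @return Corrected brain age(s), years.
#' @examples
#' bc <- structure(list(alpha = 0.5, beta = 25), class = "bias_correction")
#' apply_correction(60, 40, bc)  # 55
#' @export
apply_correction <- function(raw, age, bc) {
  if (!inherits(bc, "bias_correction")) {
    stop("'bc' must be a bias_correction", call. = FALSE)
  }
  raw + (age - (bc$alpha * age + bc$beta))
}

#' Brain-age gap
#'
#' BAG = corrected brain age - chronological age; positive values indicate
#' an older-appearing brain.
#'
#' @param corrected Corrected brain age(s), years.
#' @param age Chronological age(s), years.
#' @return BAG in years.
#' @examples
#' compute_bag(55, 40)  # 15
#' @export
compute_bag <- function(corrected, age) corrected - age

#' Attach a bias correction to a fitted brain-age model
#'
#' @param model A [brainage_fit()] model.
#' @param bc A [fit_bias()] object.
#' @return The model with `bias_correction` set.
#' @export
set_bias_correction <- function(model, bc) {
  if (!inherits(model, "brainage_model")) {
    stop("'model' must be a brainage_model", call. = FALSE)
  }
  if (!inherits(bc, "bias_correction")) {
    stop("'bc' must be a bias_correction", call. = FALSE)
  }
  model$bias_correction <- bc
  model
}

#' Per-subject brain-age-gap table
#'
#' Convenience wrapper producing one row per subject with raw, corrected and
#' gap values for a model that carries a bias correction.
#'
#' @param model Fitted `brainage_model` with a bias correction attached.
#' @param features Feature table for the cohort.
#' @param ages Named chronological ages.
#' @return data.frame: `participant_id`, `age`, `raw_brain_age`,
#'   `corrected_brain_age`, `bag`, `modality`.
#' @export
bag_table <- function(model, features, ages) {
  if (is.null(model$bias_correction)) {
    stop("model has no bias correction; fit one with fit_bias()",
         call. = FALSE)
  }
  out <- predict(model, features, ages = ages)
  out$modality <- if (is.null(model$modality)) NA_character_ else
    model$modality
  out
}
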