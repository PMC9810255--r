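#' Default duration-dependent brain-age deviation profiles
#'
#' Returns one function per modality mapping illness duration (years since
#' onset) to the planted brain-age deviation in years. The defaults encode
#' the qualitative trajectory ordering the package is designed to detect:
#' cortical thickness shows a large deviation from onset that plateaus early;
#' regional brain volume starts lower and grows roughly linearly so that it
#' overtakes thickness near 24 years of illness; fractional anisotropy (FA)
#' carries no deviation at any duration. All profiles are continuous.
#'
#' @return Named list of functions (`volume`, `thickness`, `fa`), each taking
#'   a numeric vector of durations and returning deviations in years.
#' @examples
#' p <- default_deviation_profiles()
#' p$thickness(0) > p$volume(0)   # early: thickness dominates
#' p$volume(30) > p$thickness(30) # late: volume dominates
#' p$fa(15)                       # FA is null throughout
#' @export
default_deviation_profiles <- function() {
  list(
    volume    = function(d) 3.5 + 0.12 * d + 0.5 * pmax(0, d - 22),
    thickness = function(d) 7 + 0.5 * (1 - exp(-d / 4)),
    fa        = function(d) 0 * d
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of [generate_cohort()]. Defaults mirror
#' a case-control structural-MRI study of schizophrenia: 330 controls aged
#' 20-84, 194 patients aged 20-70 with illness durations 0-38 years, and
#' three feature modalities with 57 volume, 70 thickness and 49 FA features.
#'
#' @param n_controls,n_patients Group sizes.
#' @param control_age_range,patient_age_range Age ranges in years.
#' @param duration_range Illness-duration range in years.
#' @param duration_mean,duration_sd Location/scale of the truncated-normal
#'   duration distribution (years).
#' @param n_features Named counts of features per modality.
#' @param aging_slopes Named per-modality feature-unit-per-year trend applied
#'   to signal-carrying features.
#' @param deviation_profiles Named list of functions of duration returning the
#'   planted patient deviation in brain-age years; see
#'   [default_deviation_profiles()].
#' @param noise_sd Named per-modality feature noise standard deviation.
#'   Defaults are set so that averaging the signal-carrying features yields a
#'   residual brain-age noise of roughly six years, in line with the
#'   hold-out errors structural brain-age models typically report.
#' @param loading_fraction Fraction of features per modality that carry the
#'   age signal; the rest are pure noise.
#' @param clinical_coupling Slope (BAG years per PANSS-total point) coupling
#'   symptom scores to the planted deviation; 0 (default) leaves clinical
#'   scores independent of brain age, an optional knob for power studies.
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @return Object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_controls = 330L,
                              n_patients = 194L,
                              control_age_range = c(20, 84),
                              patient_age_range = c(20, 70),
                              duration_range = c(0, 38),
                              duration_mean = 15.56,
                              duration_sd = 10.30,
                              n_features = c(volume = 57L, thickness = 70L,
                                             fa = 49L),
                              aging_slopes = c(volume = 1, thickness = 1,
                                               fa = 1),
                              deviation_profiles = default_deviation_profiles(),
                              noise_sd = c(volume = 35, thickness = 39,
                                           fa = 32),
                              loading_fraction = 0.6,
                              clinical_coupling = 0,
                              seed = 1L) {
  cfg <- list(
    n_controls = check_count(n_controls, "n_controls"),
    n_patients = check_count(n_patients, "n_patients"),
    control_age_range = check_range(control_age_range, "control_age_range"),
    patient_age_range = check_range(patient_age_range, "patient_age_range"),
    duration_range = check_range(duration_range, "duration_range"),
    duration_mean = duration_mean,
    duration_sd = duration_sd,
    n_features = n_features,
    aging_slopes = aging_slopes,
    deviation_profiles = deviation_profiles,
    noise_sd = noise_sd,
    loading_fraction = loading_fraction,
    clinical_coupling = clinical_coupling,
    seed = as.integer(seed)
  )
  mods <- names(cfg$n_features)
  if (is.null(mods) || !all(nzchar(mods))) {
    stop("'n_features' must be a named vector of modalities", call. = FALSE)
  }
  for (m in mods) {
    check_count(cfg$n_features[[m]], paste0("n_features[", m, "]"))
    if (is.null(cfg$noise_sd[[m]]) || cfg$noise_sd[[m]] < 0) {
      stop(sprintf("'noise_sd[%s]' must be >= 0", m), call. = FALSE)
    }
    if (is.null(cfg$aging_slopes[[m]])) {
      stop(sprintf("'aging_slopes[%s]' missing", m), call. = FALSE)
    }
    if (!is.function(cfg$deviation_profiles[[m]])) {
      stop(sprintf("'deviation_profiles[%s]' must be a function", m),
           call. = FALSE)
    }
  }
  if (!is.numeric(loading_fraction) || length(loading_fraction) != 1L ||
      is.na(loading_fraction) || loading_fraction <= 0 ||
      loading_fraction > 1) {
    stop("'loading_fraction' must be in (0, 1]", call. = FALSE)
  }
  if (duration_sd < 0) stop("'duration_sd' must be >= 0", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# truncated-normal sampler on [lo, hi] by inverse-CDF (exact, no rejection)
rtnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic case-control cohort with planted aging structure
#'
#' Simulates participant demographics and per-modality feature tables. Each
#' control's latent brain age equals their chronological age; each patient's
#' equals age plus the configured deviation profile evaluated at their
#' illness duration. A `loading_fraction` of each modality's features is
#' affine in latent brain age (per-feature loadings drawn once around the
#' modality's aging slope) plus i.i.d. Gaussian noise; the remaining features
#' are pure noise. Patient onset is constrained to adulthood
#' (duration <= age - 18).
#'
#' @param config A [simulation_config()].
#' @return List with elements:
#'   \describe{
#'     \item{participants}{data.frame, one row per participant: id, diagnosis
#'       (`"control"`/`"patient"`), age, sex, education, mmse, duration (NA
#'       for controls), PANSS total/pos/neg/gen and cpz (NA for controls;
#'       cpz NA for a fraction of patients emulating missing medication
#'       records).}
#'     \item{features}{named list of feature tables (data.frame with
#'       participant_id then feature columns), one per modality; attributes
#'       `modality`, `loadings`, `intercepts`, `carrier` record the planted
#'       generative coefficients.}
#'     \item{latent_brain_age}{named numeric vector of the planted latent
#'       brain age per participant (identical across modalities up to the
#'       modality-specific deviation; stored per modality in
#'       `attr(features[[m]], "latent")`).}
#'   }
#' @examples
#' cohort <- generate_cohort(simulation_config(n_controls = 30,
#'                                             n_patients = 20, seed = 7))
#' table(cohort$participants$diagnosis)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    stop("'config' must be a simulation_config", call. = FALSE)
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  n_hc <- cfg$n_controls
  n_sz <- cfg$n_patients
  n <- n_hc + n_sz
  ids <- sprintf("S%04d", seq_len(n))
  diagnosis <- c(rep("control", n_hc), rep("patient", n_sz))

  age_hc <- stats::runif(n_hc, cfg$control_age_range[1],
                         cfg$control_age_range[2])
  # patients: draw duration first, then age uniform over its feasible range
  # (onset at >= 18 years of age keeps duration <= age - 18)
  dur <- rtnorm(n_sz, cfg$duration_mean, cfg$duration_sd,
                cfg$duration_range[1], cfg$duration_range[2])
  age_lo <- pmax(cfg$patient_age_range[1], dur + 18)
  age_lo <- pmin(age_lo, cfg$patient_age_range[2])
  age_sz <- stats::runif(n_sz, age_lo, cfg$patient_age_range[2])
  age <- c(age_hc, age_sz)

  sex <- sample(c("male", "female"), n, replace = TRUE)
  education <- round(pmax(6, pmin(20, stats::rnorm(
    n, ifelse(diagnosis == "control", 15.85, 12.50),
    ifelse(diagnosis == "control", 3.85, 3.55)))))
  mmse <- round(pmax(0, pmin(30, stats::rnorm(
    n, ifelse(diagnosis == "control", 28.96, 26.81),
    ifelse(diagnosis == "control", 1.01, 3.39)))))

  duration <- c(rep(NA_real_, n_hc), dur)

  panss_pos <- panss_neg <- panss_gen <- panss_total <- cpz <-
    rep(NA_real_, n)
  pat <- diagnosis == "patient"
  panss_pos[pat] <- round(pmax(7, stats::rnorm(n_sz, 10.74, 3.37)))
  panss_neg[pat] <- round(pmax(7, stats::rnorm(n_sz, 10.04, 3.76)))
  panss_gen[pat] <- round(pmax(16, stats::rnorm(n_sz, 21.26, 5.18)))
  panss_total[pat] <- panss_pos[pat] + panss_neg[pat] + panss_gen[pat]
  cpz[pat] <- round(pmax(0, stats::rnorm(n_sz, 402.42, 324.27)), 1)
  # emulate incomplete medication records: ~1/6 of patients lack a dose
  missing_cpz <- stats::runif(n_sz) < 1 / 6
  cpz[pat][missing_cpz] <- NA_real_

  participants <- data.frame(
    participant_id = ids, diagnosis = diagnosis, age = age, sex = sex,
    education = education, mmse = mmse, duration = duration,
    panss_total = panss_total, panss_pos = panss_pos, panss_neg = panss_neg,
    panss_gen = panss_gen, cpz = cpz, stringsAsFactors = FALSE
  )

  features <- list()
  for (m in names(cfg$n_features)) {
    p <- cfg$n_features[[m]]
    dev <- rep(0, n)
    dev[pat] <- cfg$deviation_profiles[[m]](dur)
    if (cfg$clinical_coupling != 0) {
      dev[pat] <- dev[pat] +
        cfg$clinical_coupling * (panss_total[pat] - mean(panss_total[pat]))
    }
    latent <- age + dev

    n_carrier <- max(1L, round(cfg$loading_fraction * p))
    carrier <- c(rep(TRUE, n_carrier), rep(FALSE, p - n_carrier))
    # per-feature loadings scatter around the modality slope, alternating sign
    loadings <- ifelse(carrier,
                       cfg$aging_slopes[[m]] * stats::runif(p, 0.5, 1.5) *
                         rep_len(c(1, -1), p),
                       0)
    intercepts <- stats::rnorm(p, 0, 10)
    mat <- outer(latent, loadings) +
      matrix(intercepts, n, p, byrow = TRUE) +
      matrix(stats::rnorm(n * p, 0, cfg$noise_sd[[m]]), n, p)
    colnames(mat) <- sprintf("%s_f%03d", m, seq_len(p))
    tab <- data.frame(participant_id = ids, mat, stringsAsFactors = FALSE)
    attr(tab, "modality") <- m
    attr(tab, "loadings") <- stats::setNames(loadings, colnames(mat))
    attr(tab, "intercepts") <- stats::setNames(intercepts, colnames(mat))
    attr(tab, "carrier") <- stats::setNames(carrier, colnames(mat))
    attr(tab, "latent") <- stats::setNames(latent, ids)
    features[[m]] <- tab
  }

  list(participants = participants, features = features)
}

#' Write a cohort to CSV files
#'
#' Writes `participants.csv` and one `features_<modality>.csv` per modality
#' under `dir` (UTF-8, comma-separated, header row, `.` decimal separator;
#' missing clinical values are written as empty cells).
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, "participants.csv")
  utils::write.csv(cohort$participants, paths, row.names = FALSE, na = "")
  for (m in names(cohort$features)) {
    p <- file.path(dir, sprintf("features_%s.csv", m))
    utils::write.csv(cohort$features[[m]], p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
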