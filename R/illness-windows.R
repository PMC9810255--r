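#' Sliding-window specification over illness duration
#'
#' Defaults give overlapping 5-year windows stepped by 1 year (0-4, 1-5, ...,
#' 26-30) plus one merged tail window (31 up to `duration_max`) pooling the
#' sparse long-duration patients.
#'
#' @param width Window width in whole years (>= 1).
#' @param step Step between window starts in years (>= 1).
#' @param tail_merge_start First duration year of the merged tail window.
#' @param duration_max Largest observed duration (upper bound of the tail).
#' @return Object of class `"window_spec"`.
#' @export
window_spec <- function(width = 5L, step = 1L, tail_merge_start = 31L,
                        duration_max = 38L) {
  width <- check_count(width, "width")
  step <- check_count(step, "step")
  if (tail_merge_start < width) {
    stop("'tail_merge_start' must be >= 'width'", call. = FALSE)
  }
  structure(list(width = width, step = step,
                 tail_merge_start = as.integer(tail_merge_start),
                 duration_max = as.numeric(duration_max)),
            class = "window_spec")
}

#' Build illness-duration windows and assign patients
#'
#' Regular windows cover [s, s + width - 1] for s = 0, step, 2 step, ... as
#' long as the window ends before `tail_merge_start`; a final merged window
#' covers [tail_merge_start, duration_max]. Windows overlap by design, so a
#' patient can belong to several. Durations are compared on the whole-year
#' scale (a duration d belongs to [lo, hi] iff lo <= d < hi + 1), so "0-4"
#' holds onset up to just under 5 years.
#'
#' @param patients data.frame of patient records with `participant_id` and
#'   `duration` columns (duration in years, no missing values).
#' @param spec A [window_spec()].
#' @return List of windows; each has `label`, `duration_lo`, `duration_hi`,
#'   `merged`, `patient_ids`, `matched_control_ids` (empty until
#'   [match_controls()]), and `empty` flag.
#' @examples
#' pts <- data.frame(participant_id = c("P1", "P2"), duration = c(3, 33))
#' w <- build_windows(pts, window_spec())
#' length(w)  # 28
#' @export
build_windows <- function(patients, spec = window_spec()) {
  if (any(is.na(patients$duration))) {
    stop("all patients must have a duration", call. = FALSE)
  }
  starts <- seq(0L, by = spec$step,
                length.out = max(0L, (spec$tail_merge_start - spec$width) %/%
                                   spec$step + 1L))
  starts <- starts[starts + spec$width - 1L < spec$tail_merge_start]
  windows <- lapply(starts, function(s) {
    lo <- s; hi <- s + spec$width - 1L
    ids <- patients$participant_id[patients$duration >= lo &
                                     patients$duration < hi + 1]
    list(label = sprintf("%d-%d", lo, hi), duration_lo = lo,
         duration_hi = hi, merged = FALSE, patient_ids = ids,
         matched_control_ids = character(0), empty = length(ids) == 0L)
  })
  lo <- spec$tail_merge_start
  ids <- patients$participant_id[patients$duration >= lo]
  windows[[length(windows) + 1L]] <- list(
    label = sprintf("%d-%d", lo, as.integer(spec$duration_max)),
    duration_lo = lo, duration_hi = spec$duration_max, merged = TRUE,
    patient_ids = ids, matched_control_ids = character(0),
    empty = length(ids) == 0L)
  windows
}

#' Sample age- and sex-matched controls for one window
#'
#' Draws one hold-out control per patient: same sex, minimal absolute age
#' difference among candidates not yet used in this window, random
#' tie-breaking. Sampling is without replacement within a window and with
#' replacement across windows (each window draws from the full hold-out
#' pool). A pure-random mode ignores age and samples any same-sex control.
#'
#' @param window One element of [build_windows()] output.
#' @param holdout data.frame of hold-out control records (`participant_id`,
#'   `age`, `sex`).
#' @param seed Integer seed; matching is deterministic given the seed.
#' @param mode `"greedy"` (nearest age within sex, default) or `"random"`
#'   (random within sex).
#' @return The window with `matched_control_ids` filled and
#'   `mean_abs_age_diff` recorded.
#' @export
match_controls <- function(window, holdout, seed = 1L, mode = "greedy") {
  mode <- match.arg(mode, c("greedy", "random"))
  pts <- window$patient_ids
  if (length(pts) == 0L) {
    window$matched_control_ids <- character(0)
    window$mean_abs_age_diff <- NA_real_
    return(window)
  }
  pat <- attr(window, "patients")
  if (is.null(pat)) {
    stop("window lacks patient data; use match_controls_cohort()",
         call. = FALSE)
  }
  match_controls_impl(window, pat, holdout, seed, mode)
}

match_controls_impl <- function(window, patients, holdout, seed, mode) {
  pts <- patients[match(window$patient_ids, patients$participant_id), ,
                  drop = FALSE]
  need <- table(pts$sex)
  have <- table(factor(holdout$sex, levels = names(need)))
  deficit <- need - have
  if (any(deficit > 0)) {
    d <- deficit[deficit > 0]
    stop(sprintf("insufficient hold-out controls for window %s: need %s more",
                 window$label,
                 paste(sprintf("%d %s", d, names(d)), collapse = ", ")),
         call. = FALSE)
  }
  with_seed(seed, {
    # match hardest cases first: patients in random order keeps ties fair
    ord <- sample(seq_len(nrow(pts)))
    used <- character(0)
    matched <- character(nrow(pts))
    diffs <- numeric(nrow(pts))
    for (i in ord) {
      cand <- holdout[holdout$sex == pts$sex[i] &
                        !(holdout$participant_id %in% used), , drop = FALSE]
      if (mode == "greedy") {
        d <- abs(cand$age - pts$age[i])
        best <- which(d == min(d))
        pick <- if (length(best) > 1L) sample(best, 1L) else best
      } else {
        pick <- sample(nrow(cand), 1L)
      }
      matched[i] <- cand$participant_id[pick]
      diffs[i] <- abs(cand$age[pick] - pts$age[i])
      used <- c(used, matched[i])
    }
    window$matched_control_ids <- matched
    window$mean_abs_age_diff <- mean(diffs)
    window
  })
}

#' Match controls for every window of a cohort
#'
#' @param windows Output of [build_windows()].
#' @param patients Patient records (`participant_id`, `age`, `sex`).
#' @param holdout Hold-out control records.
#' @param seed Base seed; window i uses `seed + i` so draws are independent
#'   across windows yet reproducible.
#' @param mode See [match_controls()].
#' @return Windows with matched controls filled in.
#' @export
match_controls_cohort <- function(windows, patients, holdout, seed = 1L,
                                  mode = "greedy") {
  lapply(seq_along(windows), function(i) {
    w <- windows[[i]]
    if (w$empty) {
      w$matched_control_ids <- character(0)
      w$mean_abs_age_diff <- NA_real_
      return(w)
    }
    match_controls_impl(w, patients, holdout, seed + i, mode)
  })
}

#' Remove outliers by Tukey fences
#'
#' Computes Q1 and Q3 as the 25th/75th percentiles (linear interpolation
#' between order statistics, R quantile type 7) and keeps values inside
#' [Q1 - 1.5 IQR, Q3 + 1.5 IQR]. Applied once per group; with fewer than 4
#' values removal is skipped with a warning.
#'
#' @param values Numeric vector (e.g. one window's patient BAGs).
#' @return List: `kept`, `removed`, `fences` (lower, upper), `q1`, `q3`.
#' @examples
#' remove_outliers_tukey(c(1, 2, 3, 4, 100))$removed  # 100
#' @export
remove_outliers_tukey <- function(values) {
  if (length(values) < 4L) {
    warning("fewer than 4 values: outlier removal skipped")
    return(list(kept = values, removed = numeric(0),
                fences = c(-Inf, Inf), q1 = NA_real_, q3 = NA_real_))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(kept = values[keep], removed = values[!keep], fences = fences,
       q1 = q[1], q3 = q[2])
}
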