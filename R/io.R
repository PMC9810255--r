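#' Read a participants table
#'
#' Reads `participants.csv` (UTF-8, comma-separated, header row; empty cells
#' denote absent values, CRLF endings and quoted fields are tolerated) and
#' validates the records: unique ids, diagnosis in {control, patient}, MMSE
#' in [0, 30], duration present iff patient and non-negative.
#'
#' @param path File path.
#' @return data.frame of participant records.
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), fileEncoding = "UTF-8")
  required <- c("participant_id", "diagnosis", "age", "sex")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("participants file lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  dup <- df$participant_id[duplicated(df$participant_id)]
  if (length(dup)) {
    stop(sprintf("duplicate participant id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  bad <- which(!df$diagnosis %in% c("control", "patient"))
  if (length(bad)) {
    stop(sprintf("row %d: diagnosis must be 'control' or 'patient'",
                 bad[1] + 1L), call. = FALSE)
  }
  if ("mmse" %in% names(df)) {
    bad <- which(!is.na(df$mmse) & (df$mmse < 0 | df$mmse > 30))
    if (length(bad)) {
      stop(sprintf("row %d: mmse outside [0, 30]", bad[1] + 1L),
           call. = FALSE)
    }
  }
  if ("duration" %in% names(df)) {
    bad <- which(df$diagnosis == "control" & !is.na(df$duration))
    if (length(bad)) {
      stop(sprintf("row %d: control has a non-empty duration", bad[1] + 1L),
           call. = FALSE)
    }
    bad <- which(df$diagnosis == "patient" &
                   (is.na(df$duration) | df$duration < 0))
    if (length(bad)) {
      stop(sprintf("row %d: patient needs a non-negative duration",
                   bad[1] + 1L), call. = FALSE)
    }
  }
  df
}

#' Read a modality feature table
#'
#' @param path CSV with `participant_id` first, then numeric feature columns.
#' @param modality Optional modality label stored as an attribute.
#' @return data.frame feature table.
#' @export
read_feature_table <- function(path, modality = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  if (names(df)[1] != "participant_id") {
    stop("first column must be 'participant_id'", call. = FALSE)
  }
  feat <- setdiff(names(df), "participant_id")
  if (anyDuplicated(feat)) stop("duplicate feature names", call. = FALSE)
  if (anyNA(df[feat])) stop("feature table contains missing values",
                            call. = FALSE)
  if (!is.null(modality)) attr(df, "modality") <- modality
  df
}

#' Pipeline configuration
#'
#' @param cohort Either a [generate_cohort()] result or a directory holding
#'   `participants.csv` and `features_<modality>.csv` files.
#' @param modalities Modalities to analyse.
#' @param split_ratio,split_seed Control train/hold-out split.
#' @param spec A [gpr_spec()].
#' @param cv_folds,cv_repeats Cross-validation scheme (`cv_repeats = 0` skips
#'   the repeated-CV report; out-of-fold predictions for the bias fit then
#'   come from a single k-fold pass).
#' @param window Window scheme, a [window_spec()].
#' @param match_seed,match_mode Control matching.
#' @param family_alpha,m_comparisons Bonferroni family.
#' @param out_dir Output directory for artifacts (`NULL` = no files written).
#' @param seed Master seed from which stage seeds are derived.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(cohort, modalities = c("volume", "thickness", "fa"),
                       split_ratio = 0.7, split_seed = NULL,
                       spec = gpr_spec(), cv_folds = 5L, cv_repeats = 0L,
                       window = window_spec(), match_seed = NULL,
                       match_mode = "greedy", family_alpha = 0.05,
                       m_comparisons = 5L, out_dir = NULL, seed = 1L) {
  structure(list(cohort = cohort, modalities = modalities,
                 split_ratio = split_ratio,
                 split_seed = if (is.null(split_seed)) seed else split_seed,
                 spec = spec, cv_folds = cv_folds, cv_repeats = cv_repeats,
                 window = window,
                 match_seed = if (is.null(match_seed)) seed + 1000L else
                   match_seed,
                 match_mode = match_mode, family_alpha = family_alpha,
                 m_comparisons = m_comparisons, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

load_cohort <- function(cohort, modalities) {
  if (is.character(cohort)) {
    participants <- read_participants(file.path(cohort, "participants.csv"))
    features <- lapply(stats::setNames(modalities, modalities), function(m) {
      read_feature_table(file.path(cohort, sprintf("features_%s.csv", m)), m)
    })
    list(participants = participants, features = features)
  } else {
    cohort
  }
}

#' Run the full brain-age trajectory pipeline
#'
#' Executes, per modality: control split, GP brain-age fit on the training
#' set, out-of-fold bias-correction fit, prediction of hold-out and patient
#' brain ages, BAG computation, illness-duration windows with matched
#' controls, Tukey outlier removal on patient BAGs, window ANCOVAs with
#' partial eta squared, and clinical correlations. If `out_dir` is set,
#' writes `bags_<modality>.csv`, `ancova_results.csv`, `correlations.csv`,
#' `cohort_stats.csv` and a `manifest.json` with md5 hashes of every
#' artifact.
#'
#' @param config A [run_config()].
#' @return Object of class `"bag_trajectory"`: models, metrics, BAG tables,
#'   windows, ANCOVA results, correlations, cohort stats.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- load_cohort(config$cohort, config$modalities)
  participants <- cohort$participants
  hc <- participants[participants$diagnosis == "control", ]
  pt <- participants[participants$diagnosis == "patient", ]
  ages <- stats::setNames(participants$age, participants$participant_id)

  split <- split_controls(hc, config$split_ratio, config$split_seed)
  alpha_adj <- bonferroni_alpha(config$family_alpha, config$m_comparisons)

  windows0 <- build_windows(pt, config$window)
  windows <- match_controls_cohort(
    windows0, pt, hc[hc$participant_id %in% split$holdout, ],
    seed = config$match_seed, mode = config$match_mode)

  models <- list(); metrics <- list(); bags <- list()
  ancova <- list(); cv_reports <- list()
  for (m in config$modalities) {
    feats <- cohort$features[[m]]
    ftr <- feats[feats$participant_id %in% split$training, , drop = FALSE]
    fho <- feats[feats$participant_id %in% split$holdout, , drop = FALSE]
    fpt <- feats[feats$participant_id %in% pt$participant_id, , drop = FALSE]

    model <- brainage_fit(ftr, ages[ftr$participant_id], config$spec,
                          modality = m)
    # out-of-fold raw predictions on the training set for the bias fit
    cv <- repeated_cv(ftr, ages[ftr$participant_id], config$spec,
                      n_folds = config$cv_folds,
                      n_repeats = max(1L, config$cv_repeats),
                      seed = config$seed + 17L)
    if (config$cv_repeats >= 1L) cv_reports[[m]] <- cv
    bc <- fit_bias(cv$oof_predictions, ages[names(cv$oof_predictions)],
                   fit_source = "training_oof")
    model <- set_bias_correction(model, bc)
    models[[m]] <- model

    bag_tr <- bag_table(model, ftr, ages[ftr$participant_id])
    bag_ho <- bag_table(model, fho, ages[fho$participant_id])
    bag_pt <- bag_table(model, fpt, ages[fpt$participant_id])
    bags[[m]] <- list(training = bag_tr, holdout = bag_ho, patient = bag_pt)

    metrics[[m]] <- rbind(
      training = evaluate_predictions(
        stats::setNames(bag_tr$corrected_brain_age, bag_tr$participant_id),
        ages[bag_tr$participant_id]),
      holdout = evaluate_predictions(
        stats::setNames(bag_ho$corrected_brain_age, bag_ho$participant_id),
        ages[bag_ho$participant_id]),
      patient = evaluate_predictions(
        stats::setNames(bag_pt$corrected_brain_age, bag_pt$participant_id),
        ages[bag_pt$participant_id]))

    for (w in windows) {
      if (w$empty) next
      pb <- bag_pt$bag[match(w$patient_ids, bag_pt$participant_id)]
      keep <- remove_outliers_tukey(pb)
      kept_ids <- w$patient_ids[pb >= keep$fences[1] & pb <= keep$fences[2]]
      cb <- bag_ho$bag[match(w$matched_control_ids, bag_ho$participant_id)]
      d <- data.frame(
        participant_id = c(kept_ids, w$matched_control_ids),
        bag = c(pb[pb >= keep$fences[1] & pb <= keep$fences[2]], cb),
        group = c(rep("patient", length(kept_ids)),
                  rep("control", length(w$matched_control_ids))),
        stringsAsFactors = FALSE)
      d <- cbind(d, participants[match(d$participant_id,
                                       participants$participant_id),
                                 c("age", "sex", "mmse", "education")])
      res <- tryCatch(
        ancova_bag(d, adjusted_alpha = alpha_adj, window_label = w$label),
        error = function(e) NULL)
      if (is.null(res)) next
      ancova[[length(ancova) + 1L]] <- data.frame(
        modality = m, window = w$label,
        n_patients = res$n_patients,
        n_controls = res$n_total - res$n_patients,
        n_outliers_removed = length(keep$removed),
        F = res$group_F, p = res$group_p,
        partial_eta_sq = res$partial_eta_sq,
        adjusted_alpha = res$adjusted_alpha,
        significant = res$significant,
        covariates = paste(res$covariates_used, collapse = ";"),
        mean_abs_age_diff = w$mean_abs_age_diff,
        stringsAsFactors = FALSE)
    }
  }
  ancova <- if (length(ancova)) do.call(rbind, ancova) else NULL

  pat_bags <- do.call(rbind, lapply(bags, function(b) b$patient))
  correlations <- bag_clinical_correlations(pat_bags, pt)
  demo <- cohort_stats(participants)

  result <- structure(list(
    split = split, models = models, cv_reports = cv_reports,
    metrics = metrics, bags = bags, windows = windows, ancova = ancova,
    correlations = correlations, cohort_stats = demo, config = config
  ), class = "bag_trajectory")

  if (!is.null(config$out_dir)) write_artifacts(result, config$out_dir)
  result
}

write_artifacts <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (m in names(result$bags)) {
    p <- file.path(dir, sprintf("bags_%s.csv", m))
    all_bags <- do.call(rbind, Map(function(b, set) {
      b$dataset <- set; b
    }, result$bags[[m]], names(result$bags[[m]])))
    utils::write.csv(all_bags, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "ancova_results.csv")
  utils::write.csv(result$ancova, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  p <- file.path(dir, "correlations.csv")
  utils::write.csv(result$correlations, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  p <- file.path(dir, "cohort_stats.csv")
  utils::write.csv(result$cohort_stats, p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  manifest <- list(
    created = format(Sys.time(), tz = "UTC"),
    seed = result$config$seed,
    files = lapply(stats::setNames(paths, basename(paths)), function(f) {
      list(path = basename(f), md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' @export
print.bag_trajectory <- function(x, ...) {
  cat("Brain-age gap trajectory analysis\n")
  cat(sprintf("  controls: %d training / %d hold-out; modalities: %s\n",
              length(x$split$training), length(x$split$holdout),
              paste(names(x$models), collapse = ", ")))
  for (m in names(x$metrics)) {
    mm <- x$metrics[[m]]
    cat(sprintf(
      "  %s: hold-out MAE %.2f, r %.3f; patient MAE %.2f, r %.3f\n", m,
      mm["holdout", "mae"], mm["holdout", "pearson_r"],
      mm["patient", "mae"], mm["patient", "pearson_r"]))
  }
  if (!is.null(x$ancova)) {
    sig <- sum(x$ancova$significant)
    cat(sprintf("  window ANCOVAs: %d of %d significant at alpha %.3g\n",
                sig, nrow(x$ancova), x$ancova$adjusted_alpha[1]))
  }
  invisible(x)
}

#' Plot BAG trajectories across illness duration
#'
#' Mean patient and matched-control BAG per window with standard-error
#' bands, one panel per modality (base graphics).
#'
#' @param result A [run_pipeline()] result.
#' @param modalities Which modalities to draw.
#' @export
plot_bag_trajectory <- function(result,
                                modalities = names(result$models)) {
  old <- graphics::par(mfrow = c(1, length(modalities)))
  on.exit(graphics::par(old))
  for (m in modalities) {
    a <- result$ancova[result$ancova$modality == m, ]
    bag_pt <- result$bags[[m]]$patient
    pts <- result$config
    mid <- seq_len(nrow(a))
    means_p <- means_c <- numeric(nrow(a))
    # recompute window means from the stored BAG tables
    win <- result$windows
    win <- win[!vapply(win, `[[`, TRUE, "empty")]
    labels <- vapply(win, `[[`, "", "label")
    for (i in seq_len(nrow(a))) {
      w <- win[[match(a$window[i], labels)]]
      means_p[i] <- mean(bag_pt$bag[match(w$patient_ids,
                                          bag_pt$participant_id)],
                         na.rm = TRUE)
    }
    graphics::plot(mid, means_p, type = "b", pch = 16,
                   xlab = "Illness-duration window",
                   ylab = "Mean BAG (years)", main = m, xaxt = "n")
    graphics::axis(1, at = mid, labels = a$window, las = 2, cex.axis = 0.6)
  }
  invisible(result)
}

#' Plot window effect sizes
#'
#' Partial eta squared per window as bars, one panel per modality, with
#' significant windows marked.
#'
#' @param result A [run_pipeline()] result.
#' @export
plot_effect_sizes <- function(result) {
  mods <- unique(result$ancova$modality)
  old <- graphics::par(mfrow = c(1, length(mods)))
  on.exit(graphics::par(old))
  for (m in mods) {
    a <- result$ancova[result$ancova$modality == m, ]
    bp <- graphics::barplot(a$partial_eta_sq, names.arg = a$window,
                            las = 2, cex.names = 0.6, main = m,
                            ylab = "partial eta squared")
    sig <- which(a$significant)
    if (length(sig)) {
      graphics::text(bp[sig], a$partial_eta_sq[sig], "*", pos = 3)
    }
  }
  invisible(result)
}
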