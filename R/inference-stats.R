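#' ANCOVA comparison of brain-age gaps for one window
#'
#' Fits the linear model `bag ~ group + age + sex + mmse + education` and
#' tests the diagnosis effect by its partial sum of squares (equivalent to a
#' Type-III test for a two-level factor): F = (SS_group / 1) / (SS_error /
#' df_error) where SS_group is the drop in residual SS when the group term is
#' added to the covariate-only model. Partial eta squared is
#' SS_group / (SS_group + SS_error). Covariates that are constant in the
#' sample (e.g. a single-sex window) are dropped with a record in
#' `covariates_used`.
#'
#' @param data data.frame with columns `bag`, `group` (two levels, e.g.
#'   `"patient"`/`"control"`), and the covariates `age`, `sex`, `mmse`,
#'   `education`.
#' @param covariates Character vector of covariate column names.
#' @param adjusted_alpha Significance threshold after multiplicity
#'   correction (default [bonferroni_alpha()] of 0.05 over 5 comparisons).
#' @param window_label Optional label carried into the result.
#' @return Object of class `"ancova_result"`: `F`, `p`, `partial_eta_sq`,
#'   `ss_group`, `ss_error`, `df_error`, group sizes, `significant`,
#'   `covariates_used`, `adjusted_alpha`, `window_label`.
#' @examples
#' d <- data.frame(bag = c(1, 2, 3, 4, 9, 8, 11, 10),
#'                 group = rep(c("control", "patient"), each = 4),
#'                 age = c(30, 40, 50, 60, 35, 45, 55, 65))
#' ancova_bag(d, covariates = "age")
#' @export
ancova_bag <- function(data, covariates = c("age", "sex", "mmse", "education"),
                       adjusted_alpha = bonferroni_alpha(0.05, 5),
                       window_label = NA_character_) {
  stopifnot(all(c("bag", "group") %in% names(data)))
  data$group <- factor(data$group)
  if (nlevels(data$group) != 2L) {
    stop("'group' must have exactly 2 levels present", call. = FALSE)
  }
  used <- character(0)
  for (cv in covariates) {
    if (!cv %in% names(data)) {
      stop(sprintf("covariate '%s' missing from data", cv), call. = FALSE)
    }
    v <- data[[cv]]
    if ((is.numeric(v) && stats::var(v) > 0) ||
        (!is.numeric(v) && length(unique(v)) > 1L)) {
      used <- c(used, cv)
    } else {
      warning(sprintf("covariate '%s' is constant; dropped", cv))
    }
  }
  rhs <- paste(c("group", used), collapse = " + ")
  full <- stats::lm(stats::reformulate(c("group", used), "bag"), data = data)
  if (any(is.na(stats::coef(full)))) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  reduced <- stats::lm(stats::reformulate(if (length(used)) used else "1",
                                          "bag"), data = data)
  ss_error <- sum(stats::residuals(full)^2)
  ss_group <- sum(stats::residuals(reduced)^2) - ss_error
  df_error <- stats::df.residual(full)
  if (df_error < 1L) {
    stop("too few subjects for the covariate set (no error df left)",
         call. = FALSE)
  }
  Fstat <- (ss_group / 1) / (ss_error / df_error)
  p <- stats::pf(Fstat, 1, df_error, lower.tail = FALSE)
  pat_level <- if ("patient" %in% levels(data$group)) "patient" else
    levels(data$group)[2]
  structure(list(
    window_label = window_label,
    n_patients = sum(data$group == pat_level),
    n_total = nrow(data),
    group_F = Fstat, group_p = p,
    partial_eta_sq = ss_group / (ss_group + ss_error),
    ss_group = ss_group, ss_error = ss_error, df_error = df_error,
    adjusted_alpha = adjusted_alpha,
    significant = p < adjusted_alpha,
    covariates_used = used,
    model = full
  ), class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf(
    "ANCOVA%s: F(1, %d) = %.3f, p = %.4g, partial eta^2 = %.3f%s\n",
    if (!is.na(x$window_label)) sprintf(" [window %s]", x$window_label)
    else "",
    x$df_error, x$group_F, x$group_p, x$partial_eta_sq,
    if (x$significant) sprintf(" (significant at %.3g)", x$adjusted_alpha)
    else ""))
  cat(sprintf("  covariates: %s\n",
              if (length(x$covariates_used))
                paste(x$covariates_used, collapse = ", ") else "none"))
  invisible(x)
}

#' Independent two-sample t statistic from summary statistics
#'
#' Computes the pooled-variance or Welch t statistic from group means, SDs
#' and sizes — the form needed to reproduce published demographic tables
#' where only summaries are printed.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param variant `"pooled"` (equal variances, df = n1 + n2 - 2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return List: `t` (signed, mean1 - mean2 in the numerator), `df`, `p`
#'   (two-sided).
#' @examples
#' two_sample_t(43.25, 11.93, 194, 43.49, 15.47, 330, "welch")
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("SDs must be >= 0", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  if (se == 0) stop("undefined statistic: zero standard error", call. = FALSE)
  t <- (mean1 - mean2) / se
  list(t = t, df = df, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Pearson chi-square for a 2x2 contingency table
#'
#' Closed form without continuity correction:
#' chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)).
#'
#' @param a,b,c,d Cell counts (row 1: a, b; row 2: c, d).
#' @return List: `chi2`, `df` (= 1), `p`.
#' @examples
#' chi_square_2x2(85, 109, 129, 201)  # sex by diagnosis
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- as.numeric(c(a, b, c, d))
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be >= 0 with positive total", call. = FALSE)
  }
  a <- counts[1]; b <- counts[2]; c <- counts[3]; d <- counts[4]
  n <- sum(counts)
  denom <- (a + b) * (c + d) * (a + c) * (b + d)
  if (denom == 0) stop("undefined: zero marginal total", call. = FALSE)
  chi2 <- n * (a * d - b * c)^2 / denom
  list(chi2 = chi2, df = 1L,
       p = stats::pchisq(chi2, 1L, lower.tail = FALSE))
}

#' Correlations of brain-age gaps with clinical characteristics
#'
#' Pearson correlations (with two-sided p values) between each modality's
#' patient BAGs and symptom / medication variables, using pairwise deletion
#' of missing clinical values. Dose (CPZ) correlations automatically restrict
#' to patients with a recorded dose.
#'
#' @param bags data.frame with `participant_id`, `bag`, `modality` (patient
#'   rows, possibly several modalities stacked).
#' @param clinical data.frame with `participant_id` and clinical columns.
#' @param variables Clinical columns to correlate (default the PANSS scores
#'   and CPZ dose).
#' @return data.frame: one row per (modality, variable) with `n`, `r`, `p`;
#'   `r`/`p` are NA when a cell has fewer than 3 complete pairs or zero
#'   variance.
#' @export
bag_clinical_correlations <- function(bags, clinical,
                                      variables = c("panss_total",
                                                    "panss_pos", "panss_neg",
                                                    "panss_gen", "cpz")) {
  out <- list()
  for (m in unique(bags$modality)) {
    b <- bags[bags$modality == m, ]
    cl <- clinical[match(b$participant_id, clinical$participant_id), ,
                   drop = FALSE]
    for (v in variables) {
      x <- b$bag; y <- cl[[v]]
      ok <- !is.na(x) & !is.na(y)
      n <- sum(ok)
      if (n < 3L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          modality = m, variable = v, n = n, r = NA_real_, p = NA_real_)
      } else {
        ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
        out[[length(out) + 1L]] <- data.frame(
          modality = m, variable = v, n = n,
          r = unname(ct$estimate), p = ct$p.value)
      }
    }
  }
  do.call(rbind, out)
}

#' Case-control demographic comparison table
#'
#' Reproduces the standard "Table 1": chi-square for sex, and independent
#' t tests (both pooled and Welch variants) for continuous variables,
#' computed from the raw participant records.
#'
#' @param participants data.frame with `diagnosis`, `sex` and the continuous
#'   columns in `variables`.
#' @param variables Continuous variables to compare.
#' @return data.frame of test statistics and p values, one row per test.
#' @export
cohort_stats <- function(participants,
                         variables = c("age", "education", "mmse")) {
  pt <- participants[participants$diagnosis == "patient", ]
  hc <- participants[participants$diagnosis == "control", ]
  tab <- table(participants$diagnosis, participants$sex)
  cs <- chi_square_2x2(tab["patient", "male"], tab["patient", "female"],
                       tab["control", "male"], tab["control", "female"])
  rows <- list(data.frame(variable = "sex", test = "chi_square",
                          statistic = cs$chi2, df = cs$df, p = cs$p))
  for (v in variables) {
    for (variant in c("pooled", "welch")) {
      tt <- two_sample_t(mean(pt[[v]], na.rm = TRUE),
                         stats::sd(pt[[v]], na.rm = TRUE),
                         sum(!is.na(pt[[v]])),
                         mean(hc[[v]], na.rm = TRUE),
                         stats::sd(hc[[v]], na.rm = TRUE),
                         sum(!is.na(hc[[v]])), variant)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, test = paste0("t_", variant), statistic = tt$t,
        df = tt$df, p = tt$p)
    }
  }
  do.call(rbind, rows)
}
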