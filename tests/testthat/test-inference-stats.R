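test_that("ANCOVA matches the explicit sums-of-squares oracle", {
  bag <- c(1.2, 2.5, 0.8, 1.9, 6.1, 7.4, 5.5, 8.0)
  group <- rep(c("control", "patient"), each = 4)
  age <- c(30, 42, 55, 61, 33, 47, 52, 66)
  d <- data.frame(bag = bag, group = group, age = age)
  res <- ancova_bag(d, covariates = "age")
  want <- oracle_ancova(bag, group, age)
  expect_equal(res$group_F, want$F, tolerance = 1e-8)
  expect_equal(res$partial_eta_sq, want$partial_eta_sq, tolerance = 1e-8)
  # stored SS recompose the reported effect size exactly
  expect_equal(res$partial_eta_sq,
               res$ss_group / (res$ss_group + res$ss_error))
  # two-level factor: F equals the squared t of the group coefficient
  tt <- summary(res$model)$coefficients["grouppatient", "t value"]
  expect_equal(res$group_F, tt^2, tolerance = 1e-8)
})

test_that("ANCOVA agrees with a type-III analysis from car", {
  skip_if_not_installed("car")
  set.seed(2)
  n <- 40
  d <- data.frame(bag = rnorm(n, 0, 5) + rep(c(0, 4), each = n / 2),
                  group = rep(c("control", "patient"), each = n / 2),
                  age = runif(n, 20, 80),
                  sex = sample(c("male", "female"), n, TRUE),
                  mmse = round(runif(n, 24, 30)),
                  education = round(runif(n, 8, 20)))
  res <- ancova_bag(d)
  fit <- lm(bag ~ group + age + sex + mmse + education, data = d)
  a3 <- car::Anova(fit, type = "III")
  expect_equal(res$group_F, a3["group", "F value"], tolerance = 1e-8)
  expect_equal(res$ss_group, a3["group", "Sum Sq"], tolerance = 1e-8)
})

test_that("identical groups give a null ANCOVA result", {
  set.seed(3)
  reps <- 50
  ps <- numeric(reps)
  for (i in 1:reps) {
    n <- 200
    d <- data.frame(bag = rnorm(n, 0, 5),
                    group = rep(c("control", "patient"), each = n / 2),
                    age = runif(n, 20, 80),
                    sex = sample(c("male", "female"), n, TRUE),
                    mmse = round(runif(n, 24, 30)),
                    education = round(runif(n, 8, 20)))
    r <- ancova_bag(d)
    ps[i] <- r$group_p
  }
  # p values approximately uniform: small-p fraction near alpha
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(mean(ps), 0.35)
  # and eta^2 small under the null
  expect_lt(median(vapply(1:5, function(i) {
    set.seed(400 + i)
    n <- 200
    d <- data.frame(bag = rnorm(n, 0, 5),
                    group = rep(c("control", "patient"), each = n / 2),
                    age = runif(n, 20, 80))
    ancova_bag(d, covariates = "age")$partial_eta_sq
  }, 0)), 0.05)
})

test_that("a planted 10-year deviation is detected with high power", {
  set.seed(4)
  hits <- 0L
  for (i in 1:100) {
    n <- 30
    d <- data.frame(
      bag = c(rnorm(n, 0, 8), rnorm(n, 10, 8)),
      group = rep(c("control", "patient"), each = n),
      age = runif(2 * n, 20, 70),
      sex = sample(c("male", "female"), 2 * n, TRUE),
      mmse = round(runif(2 * n, 24, 30)),
      education = round(runif(2 * n, 8, 20)))
    r <- ancova_bag(d, adjusted_alpha = 0.01)
    hits <- hits + r$significant
  }
  expect_gte(hits, 90L)
})

test_that("constant covariates are dropped with a record", {
  d <- data.frame(bag = c(1, 2, 3, 7, 8, 9, 2, 8),
                  group = rep(c("control", "patient"), 4),
                  age = c(30, 40, 50, 60, 35, 45, 55, 65),
                  sex = rep("male", 8))
  expect_warning(r <- ancova_bag(d, covariates = c("age", "sex")),
                 "constant")
  expect_equal(r$covariates_used, "age")
})

test_that("group F and eta^2 are invariant to sex recoding", {
  set.seed(5)
  n <- 30
  d <- data.frame(bag = rnorm(n), group = rep(c("control", "patient"),
                                              length.out = n),
                  age = runif(n, 20, 80),
                  sex = sample(c("male", "female"), n, TRUE))
  r1 <- ancova_bag(d, covariates = c("age", "sex"))
  d2 <- d
  d2$sex <- ifelse(d$sex == "male", 1, 0)     # numeric 0/1 recoding
  r2 <- ancova_bag(d2, covariates = c("age", "sex"))
  expect_equal(r1$group_F, r2$group_F, tolerance = 1e-10)
  expect_equal(r1$partial_eta_sq, r2$partial_eta_sq, tolerance = 1e-10)
})

test_that("Bonferroni adjustment is family_alpha / m", {
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 4), 0.025)
  expect_error(bonferroni_alpha(1.2, 5), "family_alpha")
  expect_error(bonferroni_alpha(0.05, 0), "'m'")
})

test_that("summary-statistic t tests reproduce published demographic rows", {
  # age: balanced groups, Welch variant
  age <- two_sample_t(43.25, 11.93, 194, 43.49, 15.47, 330, "welch")
  expect_equal(round(abs(age$t), 2), 0.20)
  expect_gt(age$p, 0.8)
  # education: pooled variant
  edu <- two_sample_t(12.50, 3.55, 194, 15.85, 3.85, 330, "pooled")
  expect_equal(round(abs(edu$t), 2), 9.90)
  expect_lt(edu$p, 0.001)
  expect_equal(edu$df, 522)
  # equal means give t = 0 under both variants
  expect_equal(two_sample_t(5, 1, 10, 5, 2, 12, "pooled")$t, 0)
  expect_equal(two_sample_t(5, 1, 10, 5, 2, 12, "welch")$t, 0)
  expect_error(two_sample_t(5, 0, 10, 5, 0, 12, "pooled"), "zero standard")
})

test_that("2x2 chi-square matches the closed form and stats::chisq.test", {
  expect_equal(chi_square_2x2(10, 10, 10, 10)$chi2, 0)
  # diagnosis-by-sex counts with the consistent female count of 201
  sex <- chi_square_2x2(85, 109, 129, 201)
  expect_equal(round(sex$chi2, 2), 1.13)
  expect_gt(sex$p, 0.25)
  # extreme association: chi2 equals n
  expect_equal(chi_square_2x2(20, 0, 0, 20)$chi2, 40)
  # cross-check against the standard implementation, no continuity correction
  m <- matrix(c(13, 9, 4, 17), 2, byrow = TRUE)
  ours <- chi_square_2x2(13, 9, 4, 17)
  ref <- suppressWarnings(chisq.test(m, correct = FALSE))
  expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_error(chi_square_2x2(0, 0, 1, 1), "marginal")
})

test_that("clinical correlations use pairwise-complete patient data", {
  set.seed(6)
  n <- 50
  bag <- rnorm(n, 2, 5)
  bags <- data.frame(participant_id = sprintf("P%03d", 1:n), bag = bag,
                     modality = "volume")
  clinical <- data.frame(participant_id = sprintf("P%03d", 1:n),
                         panss_total = bag,              # identical to BAG
                         panss_pos = rnorm(n, 10, 3),
                         panss_neg = rnorm(n, 10, 3),
                         panss_gen = rnorm(n, 21, 5),
                         cpz = c(rnorm(n - 12, 400, 300), rep(NA, 12)))
  res <- bag_clinical_correlations(bags, clinical)
  r_tot <- res[res$variable == "panss_total", ]
  expect_equal(r_tot$r, 1, tolerance = 1e-12)
  # missing doses shrink the CPZ cell's n
  expect_equal(res[res$variable == "cpz", "n"], n - 12)
  # degenerate cell flagged undefined
  clinical$panss_pos <- 7
  res2 <- bag_clinical_correlations(bags, clinical)
  expect_true(is.na(res2[res2$variable == "panss_pos", "r"]))
})

test_that("independent clinical variables rarely show large correlations", {
  set.seed(7)
  n <- 150
  big <- 0L
  for (i in 1:200) {
    r <- cor(rnorm(n), rnorm(n))
    big <- big + (abs(r) >= 0.2)
  }
  # sampling-null reference for |r|: matches the package's pairwise r
  bags <- data.frame(participant_id = sprintf("P%03d", 1:n),
                     bag = rnorm(n), modality = "fa")
  clinical <- data.frame(participant_id = sprintf("P%03d", 1:n),
                         panss_total = rnorm(n, 42, 10))
  res <- bag_clinical_correlations(bags, clinical,
                                   variables = "panss_total")
  expect_lt(abs(res$r), 0.25)
  expect_lte(big / 200, 0.05)
})

test_that("cohort_stats assembles the demographic test table", {
  ch <- generate_cohort(simulation_config(n_controls = 60, n_patients = 40,
                                          n_features = c(volume = 4,
                                                         thickness = 4,
                                                         fa = 4),
                                          seed = 8))
  tab <- cohort_stats(ch$participants)
  expect_true(all(c("sex", "age", "education", "mmse") %in% tab$variable))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  expect_true(all(is.finite(tab$statistic)))
  # education is planted lower in patients: both t variants strongly negative
  edu <- tab[tab$variable == "education", ]
  expect_true(all(edu$statistic < 0))
})
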