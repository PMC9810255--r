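---
title: "Brain-age gap trajectories: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-age gap trajectories: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bagtraj)
```

## The model

`bagtraj` estimates how far a patient's brain structure deviates from normal
aging, and how that deviation evolves over the course of illness. The
analysis has four statistical layers.

### 1. Brain-age regression

For each modality (regional brain volume, cortical thickness, fractional
anisotropy) a Gaussian-process regression of chronological age on the feature
vector is fitted to the *training* controls. The kernel is isotropic
exponential over standardized features,

$$k(x, x') = \sigma_f^2 \exp\!\big(-\lVert x - x'\rVert / \ell\big),$$

with constant mean $c$ and observation noise $\sigma_n$. Predictions use the
posterior-mean closed form $c + k_*^\top (K + \sigma_n^2 I)^{-1} (y - c)$.
The exponential (rather than squared-exponential) kernel is the common choice
for brain-age work: it is less smooth and more tolerant of the ragged
feature–age relationships seen in regional morphometry.

Hyperparameters $(\ell, \sigma_f, \sigma_n)$ maximise the log marginal
likelihood via multi-start L-BFGS-B on the log scale; the constant $c$ is
profiled out by generalised least squares at every evaluation, which keeps
the search three-dimensional and cannot decrease the likelihood. Starts are
scaled from the median pairwise feature distance and `sd(y)` (with
$\sigma_n = \mathrm{sd}(y)/\sqrt 2$), the usual automatic initialisation. A
diagonal jitter of $10^{-8}$ guards the Cholesky factorisation; it is
invisible at reported precision. With $\sigma_n = 0$ and duplicated training
rows the system is singular by construction — the fit then stops with advice
to add noise or jitter rather than silently regularising.

Model quality is summarised by repeated k-fold cross-validation
(`repeated_cv()`): each repeat reshuffles a uniformly random partition into
`n_folds` near-equal folds (five by default, unstratified), computes MAE and
Pearson r on the pooled out-of-fold predictions, and the repeat distribution
is summarised as mean ± SD with a normal 95% CI
($\bar x \pm 1.96\,s/\sqrt{R}$). Hold-out and patient predictions come from
the model refitted on the full training set; refitting (rather than
ensembling the fold models) was chosen for simplicity and because the two
differ negligibly at these sample sizes.

### 2. Age-bias correction

Regression-to-the-mean makes raw brain ages too old for young subjects and
too young for old ones. The standard linear correction is applied: fit
$\widehat{ba} = \alpha\,\Omega + \beta$ by OLS on a healthy reference set,
then report $\mathrm{corrected} = raw + [\Omega - (\alpha\Omega + \beta)]$
and $\mathrm{BAG} = \mathrm{corrected} - \Omega$. Two algebraic identities
follow on the fitting set and are asserted in the tests: the regression of
corrected brain age on age has slope 1 and intercept 0, and the mean BAG is
exactly zero (OLS residuals sum to zero).

The correction is fitted on the training set's **out-of-fold** predictions —
in-sample predictions would understate the bias because the GP partially
interpolates its training targets — and then frozen and applied unchanged to
training, hold-out and patient data. It is never refitted on patients: that
would absorb exactly the disease signal the analysis is after. One
correction is kept per modality model.

### 3. Illness-duration windows and matching

Patients are grouped by a sliding window over duration of illness: width 5
years, step 1 year, so windows overlap and a patient contributes to up to
five of them. A duration $d$ belongs to window "$s$–$(s{+}4)$" iff
$s \le d < s + 5$. Regular windows stop at 26–30 and durations from 31
onward form one merged tail window — long-duration patients are too sparse
for stable 5-year bins, and stopping the regular grid at 26–30 keeps the
tail disjoint from it (the boundary windows 27–31 … 30–34 would otherwise
straddle the merge point). Both the merge start and the grid are
configurable via `window_spec()`.

Each window's patients receive age- and sex-matched controls drawn from the
hold-out split only (never from training data). Matching is greedy: patients
in random order each take the same-sex unused control with the smallest
absolute age difference, ties broken at random. Greedy nearest-age honours
both the "matched" and the "selected randomly" aspects of typical matched
sampling; a pure random-within-sex mode (`mode = "random"`) is available for
sensitivity checks. Sampling is without replacement within a window and with
replacement across windows, and each window uses its own derived seed, so
matched sets are reproducible yet independent across windows.

### 4. Outliers, ANCOVA and effect sizes

Before each comparison, Tukey fences are applied once to the window's
patient BAGs: values outside $[Q_1 - 1.5\,\mathrm{IQR},\,
Q_3 + 1.5\,\mathrm{IQR}]$ are removed. Quartiles use linear interpolation
between order statistics (R's default type-7 convention; the fences for
`c(1, 2, 3, 4, 100)` are $(-1, 7)$). Removal is applied to patients only,
matching the convention of screening each clinical group; a flagless design
keeps matched-control BAGs untouched.

The group comparison is an ANCOVA: `bag ~ group + age + sex + mmse +
education`. The diagnosis effect is tested by its partial sum of squares —
for a two-level factor this equals the Type-III test, and the F statistic
equals the squared t of the group coefficient (asserted to $10^{-8}$ in the
tests, along with agreement with `car::Anova(type = "III")`). The effect
size is partial $\eta^2 = SS_\mathrm{group}/(SS_\mathrm{group} +
SS_\mathrm{error})$. Sex may enter as strings or any 0/1 coding — F and
$\eta^2$ are invariant under affine recoding, which the tests verify.
Covariates that are constant within a window (e.g. a single-sex window) are
dropped with a warning recorded in `covariates_used`; windows whose error
degrees of freedom would be exhausted raise an error and are skipped by the
pipeline.

Significance is declared at a Bonferroni-adjusted threshold,
`family_alpha / m` with defaults 0.05/5 = 0.01. The grouping of the ~28
overlapping windows into families of five is a convention of the study
design this package follows; `m` is configurable because other designs may
correct differently. P-values use the F distribution with $(1, n - p)$
degrees of freedom; no small-sample corrections are applied.

Demographic tables are reproduced from group summaries with closed-form
statistics: a 2×2 Pearson chi-square without continuity correction and
independent t tests in both pooled and Welch variants — published tables are
not always consistent about the variant, so `cohort_stats()` reports both.
Clinical correlations (PANSS scores, chlorpromazine-equivalent dose) are
plain Pearson correlations with pairwise deletion; dose correlations
automatically restrict to patients with a recorded dose.

## The synthetic cohort generator

Real feature tables from clinical samples are rarely shareable, so
`generate_cohort()` simulates cohorts with the statistical structure the
pipeline assumes:

* **Demographics.** 330 controls aged uniformly 20–84 and 194 patients aged
  20–70, with illness duration drawn from a normal distribution with mean
  15.56 and SD 10.30 years truncated to [0, 38] — the shape of a typical
  chronic-schizophrenia sample. Onset is constrained to adulthood
  (duration ≤ age − 18), enforced by sampling age uniformly over the
  feasible range given the duration. Education, MMSE, PANSS and dose are
  drawn around typical group summaries; PANSS and dose are independent of
  brain age by default (a `clinical_coupling` knob exists for power
  studies). Sex has no effect on features.
* **Latent brain age.** Controls: latent = age. Patients: latent = age +
  profile(duration), per modality.
* **Features.** 57 volume, 70 thickness and 49 FA features. A
  `loading_fraction` (default 0.6) of each modality's features is affine in
  latent brain age with per-feature loadings scattered around the modality's
  aging slope (alternating sign, so "larger" and "smaller with age" features
  both occur); the rest are pure noise. All noise is i.i.d. Gaussian given
  the latent — feature–feature covariance beyond the shared latent is *not*
  modelled, a deliberate simplification (real morphometry has anatomical
  correlation structure the generator does not emulate).
* **Noise scale.** Feature noise SDs (35/39/32 feature units) were set so
  that the information-ideal aggregate of the carrier features has a
  residual brain-age noise of roughly six years,
  $\sigma/( \mathrm{slope}\sqrt{k})\approx 6$ — matching the hold-out error
  range brain-age models report in practice. The fitted GP lands close to
  this bound (hold-out MAE ≈ 4–5 years, r ≈ 0.94–0.96 at the default sizes).

### Deviation profiles

The planted patient deviations (in brain-age years) encode the trajectory
ordering the pipeline is designed to detect:

```{r}
p <- default_deviation_profiles()
curve(p$thickness(x), 0, 38, ylim = c(0, 14), xlab = "duration (years)",
      ylab = "planted deviation (years)")
curve(p$volume(x), add = TRUE, lty = 2)
abline(h = 0, col = "grey")  # fa
```

* thickness: $7 + 0.5(1 - e^{-d/4})$ — a large deviation from onset that
  plateaus within the first decade;
* volume: $3.5 + 0.12\,d + 0.5\max(0, d - 22)$ — a moderate early offset
  whose growth steepens after ~22 years of illness, overtaking thickness
  near 24 years and dominating thereafter;
* FA: identically zero — a planted null.

The late volume slope is sized so that at the merged-tail durations the
deviation reaches ~12–16 years, which at the simulated BAG noise corresponds
to large effect sizes (partial $\eta^2$ in the 0.4–0.5 range) — the scale at
which a "most vigorous late deviation" is actually detectable at n ≈ 30–40
per window. All profiles are continuous in duration and fully configurable.

## What passing tests do and do not show

The test suite and `scripts/acceptance.R` verify, on synthetic cohorts at
the default sizes (330 + 194; reduced feature counts in the fast unit
tests):

* exact reproduction of published demographic worked examples from their
  group summaries (Welch t 0.20 for age, pooled t 9.90 for education,
  chi-square 1.13 for sex, Bonferroni 0.01, 230/100 split);
* GP posterior means equal to an independently coded dense-linear-algebra
  oracle to $10^{-8}$ on instances up to 50 points;
* the bias-correction identities, the ANCOVA sums-of-squares oracle and the
  Tukey-fence arithmetic exactly;
* parameter recovery: hold-out r > 0.8 for the default generator; a planted
  null (FA-like) keeps the significant-window rate ≤ 3% at α = 0.01 over
  200 BAG-level replicates; and the thickness-early/volume-late crossover is
  recovered (early-window mean $\eta^2$ higher for thickness, late-window
  mean higher for volume) in ≥ 80% of five seeded full-pipeline replicates.

Because the generator's features are conditionally independent given a
one-dimensional latent, these results demonstrate the *pipeline's*
correctness and sensitivity, not the behaviour of real imaging data:
anatomical covariance, site and scanner effects, non-Gaussian feature noise
and age-dependent heteroscedasticity are all absent. On real data, expect
lower hold-out r, wider BAG spreads, and effect sizes that depend on those
nuisance structures.

## Numerical choices and degenerate inputs

* Quantile convention: type 7 (linear interpolation); recorded here because
  Tukey-fence membership can change under other conventions for n < ~10.
* Constant features abort the fit (standardization would divide by zero);
  constant covariates are dropped per window, not globally.
* `split_controls()` sizes the training set as `round(ratio * N)`; a 230/100
  split of 330 controls corresponds to ratio 230/330 (an exact 7:3 split of
  330 is 231/99).
* Fewer than four values skip outlier removal with a warning; windows with
  no patients are retained, flagged and excluded downstream.
* All randomness (cohort, split, folds, matching, tie-breaks) is seeded, and
  seeds are restored after each call, so library use never perturbs the
  caller's RNG state.

## Problem sizes

The shipped tests run the full pipeline at the default cohort size with
reduced cross-validation repeats (out-of-fold predictions for the bias fit
come from a single 5-fold pass) and five replicates for the crossover check;
the unit tests use 4–8 features per modality. These sizes were chosen so the
complete suite documents the method at the study's sample sizes while
remaining quick to run; `repeated_cv()` scales to the traditional thousand
repeats unchanged if a user wants publication-grade CI widths.

## Known limitations

* One modality per model; no multimodal fusion.
* No alternative regressors beyond the GP (the fit/predict surface is small
  enough to swap in another model, but none is shipped).
* No uncertainty intervals on individual brain ages (the GP posterior
  variance is computed nowhere; only the posterior mean is used).
* Cross-sectional only: the window trajectories emulate, but are not,
  longitudinal change.
* Matching is greedy nearest-age within sex — adequate for balanced
  hold-out pools, but no caliper or optimal matching is implemented.
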