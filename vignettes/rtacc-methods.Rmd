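---
title: "RTACC: methods, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RTACC: methods, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtacc)
```

## The digital biomarker

Computerized cognitive training produces a continuous behavioral stream:
every 3-minute game task yields a mean reaction time (RT, seconds) and an
accuracy (proportion of correct trials). Single-dimension summaries of this
stream (mean RT alone, mean accuracy alone) are sensitive to strategy
shifts, practice effects and ceiling effects. RTACC instead summarizes the
*coupling* of the two dimensions for participant $p$:

$$\mathrm{RTACC}_p = \mathrm{corr}\big(\mathrm{RT}_i,\ \mathrm{Accuracy}_i\big),$$

the product-moment correlation across that participant's tasks $i$. Under
the usual speed–accuracy trade-off, faster responding costs accuracy and
the correlation is positive (or near zero). A *negative* RTACC means the
participant tended to be fast and accurate on the same tasks — efficient,
automatized processing — and is the regime hypothesized to predict benefit
from a multi-domain intervention (MI) in older adults with mild cognitive
impairment.

Pairs are pooled across all games and sessions into one correlation per
participant: the metric indexes tasks, not games, and the leave-one-game-out
analysis exists precisely to check that no single game drives it. Pearson
correlation is the default reading of "correlation coefficient" for a
mean/proportion pairing; a Spearman option (`method = "spearman"`) is
exposed for rank-based robustness checks. An RTACC is reported as undefined
(`defined = FALSE`) below `min_pairs = 10` pooled pairs or when either
series is degenerate; such participants are dropped (and counted) when the
analysis table is built.

## Preprocessing

Before any metric is computed the task stream is checked for missing RT or
accuracy values and screened by a robust outlier rule: value $v$ is flagged
when $|v - \mathrm{median}| > k \cdot 1.4826 \cdot \mathrm{MAD}$ with
$k = 3$, where MAD is the raw median absolute deviation and 1.4826 the
normal-consistency constant. Design choices a one-sentence rule leaves
open, decided here:

* **Granularity** — flags are computed per participant and per series (RT
  and accuracy separately), so between-person speed differences are not
  mistaken for outliers. A pooled mode exists behind `pooled = TRUE`.
* **Degenerate scale** — when the MAD is 0 (near-constant series) nothing
  is flagged and a warning is emitted; flagging all deviants under a zero
  scale would delete valid data.
* **Short series** — participants with fewer than 3 records are skipped
  from flagging and noted in the report.
* **Invalid rows** (accuracy outside [0, 1], non-positive RT, unparseable
  numbers) are quarantined to `rejected_rows.csv` with line numbers rather
  than aborting the run.

## The synthetic cohort generator

The trial data the pipeline was designed around are not public, so the
package ships a generator that emulates their structure; every stage of the
pipeline is exercised and validated against *planted* ground truth.

**Participants.** Covariates are drawn independently from the published
baseline summaries: age $\sim N(73.02, 5.53^2)$ truncated to the 60–85
eligibility window; education $\sim N(10.73, 4.54^2)$ truncated at 0;
female with probability 0.6385 (coded 1); APOE $\varepsilon4$ carriage
0.3154; baseline RBANS $\sim N(90.10, 15.26^2)$, untruncated. Each
participant also receives a latent coupling $\rho_p \sim N(-0.2, 0.25^2)$
truncated to $(-1, 1)$. The distribution of observed RTACC values is not
reported for the real cohort, so the coupling mean and SD are calibration
choices: the mean is negative (most participants improved and negative
RTACC predicts improvement) and the SD is wide enough that the planted
outcome effect is detectable at $n = 130$ without being trivial.

**Training streams.** Each week schedules $3 + \mathrm{Binomial}(2, 0.53)$
sessions of four 3-minute tasks (games cycle through the 18-game
catalogue), making the expected total $24 \times 4 \times 4.06 = 389.8$
RT–accuracy pairs — the reported ≈390. Each task draws a bivariate
standard-normal latent with correlation $\rho_p$; one component maps to RT
through a log-normal transform ($\mathrm{RT} = 1.8\,e^{0.15 z}$ seconds,
floored at 0.2 s), the other to accuracy through a clamped linear link
($0.78 + 0.10 z$ into $[0, 1]$). RT units are seconds (the scale of
single-trial responses in game tasks); the source data never state units.

Two generator decisions deserve emphasis:

* **Bounded dynamic range.** The latent variation is truncated at
  $\pm 1.8$ SD (`latent_trunc`). Short standardized game tasks cannot
  produce arbitrarily extreme 3-minute means — response windows and task
  design bound performance — and the real training streams contained *no*
  MAD-rule outliers. With unbounded Gaussian tails that condition is
  mathematically unreachable ($P(|z| > 3) \times 390 \approx 1$ flag per
  participant), whereas the truncated generator yields zero flags with a
  wide margin against the sampling variability of the per-stream MAD, while
  biasing the realized coupling by less than 0.01 across
  $\rho_p \in [-0.6, 0.3]$.
* **Difficulty is metadata by default.** The adaptive staircase
  (increment after accuracy ≥ 0.85, decrement below 0.65, levels 1–10) is
  simulated and recorded, but the default per-level performance gradients
  are zero. Because the staircase feeds on past accuracy, a per-level RT or
  accuracy shift would add variance uncorrelated with the current task's
  latent and attenuate the realized RT–accuracy correlation below the
  planted $\rho_p$; with zero gradients the planted coupling is exact,
  which is what parameter-recovery validation requires. Non-zero gradients
  (`rt_params$per_level`, `acc_params$per_level`) are available for
  sensitivity studies.

**Outcomes.** The RBANS change score is a planted linear model:
$\Delta = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex} +
\beta_3\,\mathrm{edu} + \beta_4\,\mathrm{APOE} +
\beta_5\,\mathrm{RBANS}_0 + \beta_6\,\rho_p + \varepsilon$, with
$\beta_6 = -11.90$ (the reported adjusted RTACC effect) and the remaining
coefficients small, plausible values chosen once
($-0.10, 1.0, 0.20, -2.0, -0.10$); $\beta_0 = 20.038$ and
$\sigma_\varepsilon = 7.94$ solve the two moment conditions that the mean
and SD of the generated change score equal the published 8.26 and 8.74.
This calibration also reproduces the reported responder split (about
106–108 of 130 with an increased score). Each biomarker change is
$a_m + b_m \rho_p + \varepsilon_m$ with the published path coefficients as
slopes (BDNF $-3.132$, pTau181 $2.832$, NfL $3.879$, GFAP $-31.69$) and
residual SDs back-solved from the published path standard errors at
$n = 130$; biomarker-to-outcome effects default to 0, mirroring the
non-significant reported paths, and are configurable for power studies.
Week-24 RBANS is baseline plus change, so regressing week-24 on baseline
reproduces the planted change-score model with the baseline coefficient
shifted to $1 + \beta_5$.

The generator is an all-complete cohort (no dropout), reflecting the
complete-case analysis set. What passing recovery tests on it shows is that
the *pipeline* is correct and well-calibrated — unbiased estimation,
nominal coverage and type-I error under the planted model. It does not
show that real training streams satisfy the planted model: real data have
learning curves, session-level autocorrelation, game-specific difficulty
profiles and possibly time-varying coupling, none of which the default
generator produces.

## Inferential models

**Adjusted linear model.** `fit_linear_rbans()` estimates
$\mathrm{RBANS}_{24} = \beta_0 + \beta_1\,\mathrm{age} + \beta_2\,\mathrm{sex}
+ \beta_3\,\mathrm{edu} + \beta_4\,\mathrm{APOE}\varepsilon4 +
\beta_5\,\mathrm{RBANS}_{0} + \beta_6\,\mathrm{RTACC}$ by least squares
with classical standard errors. Week-24 RBANS with baseline as covariate is
the printed equation; it is interpretable as a change-score model because
baseline is held fixed. Rank-deficient designs abort with the collinear
term named. Window semantics for the sensitivity analysis are inclusive
(`week <= W`), so windows nest.

**Robust sensitivity fit.** `fit_robust_rbans()` uses Huber M-estimation
via IRLS (tuning 1.345, MAD residual scale re-estimated each iteration,
tolerance $10^{-8}$, max 50 iterations), delegated to `MASS::rlm`. The
tuning constant gives 95% Gaussian efficiency; as it grows the fit tends to
OLS, and when every Huber weight is 1 the two coincide exactly.
Non-convergence is reported, not thrown.

**Path model.** `fit_path_model()` estimates a recursive observed-variable
system by equation-wise least squares (equivalent to full-information ML
for recursive systems with uncorrelated errors): each biomarker change on
RTACC, and the outcome on RTACC plus all biomarker changes. By default
every equation adjusts for the clinical covariates and the outcome equation
for baseline RBANS — chosen because the reported path-model direct effect
($-11.98$) is nearly identical to the covariate-adjusted regression
coefficient ($-11.90$), which implies the path model was adjusted;
`adjust_covariates = FALSE` switches to the raw change score. Indirect
effects are, definitionally, the product of the two path estimates.
`prune_path_model()` performs backward elimination: repeatedly drop the
single largest-p marker path at or above $\alpha = 0.05$, refit, stop when
all remaining marker paths are significant or none remain; the direct path
is never dropped and the full removal trace is kept for audit. No latent
variables and no global fit indices are computed. Note a statistical
property of this per-path rule: under completely null marker paths the
minimum of 8 roughly-uniform p-values falls below 0.05 in about a third of
datasets, so single spurious paths survive pruning at that rate — the
trace, not the final model alone, is the honest summary.

**Responder models.** Good responders have an increased RBANS score after
24 weeks, poor responders a decreased one; exact zeros get a `tie` label
and are excluded from fits (the source definition covers only
increase/decrease). Three in-sample logistic models — clinical covariates
only; RTACC only; both — are scored by the rank-based (Mann–Whitney) AUC,
with ties counted one half, identical to trapezoidal ROC integration. The
95% CI is a stratified percentile bootstrap (2000 resamples, seeded); the
CI method behind the published intervals is unstated, and a DeLong-style
interval can be obtained from `pROC` on the same scores. AUCs are apparent
(in-sample) performance, matching the source procedure; no cross-validation
is applied, and no multiplicity correction is applied anywhere (the window
and game-exclusion p-values are descriptive).

## Numerical and validation choices

* Correlations with fewer than 3 complete pairs or zero variance return
  `NA` and propagate as `defined = FALSE` rather than exceptions.
* Seeds: `cohort_config$seed` seeds the whole generation; the pipeline
  seed propagates to the bootstrap. Identical config + seed reproduces
  every artifact byte-for-byte; each artifact embeds a hash of the full
  configuration.
* Validation problem sizes (the package's own choices, stated here so the
  test suite is interpretable): metric-vs-oracle equivalence on 500 random
  participant/window/exclusion selections; planted-coupling recovery with
  200 replicate ~390-pair streams per $\rho_p \in \{-0.6, -0.3, 0, 0.3\}$
  (mean error < 0.05); $\beta_6$ recovery and 95% CI coverage over 1000
  calibrated cohorts of $n = 130$; type-I error over 1000 null cohorts;
  Huber-vs-OLS comparison over 200 contaminated cohorts; AUC equivalence on
  200 random score sets and null-AUC calibration over 200 cohorts; MAD-rule
  agreement with a brute-force oracle on 1000 random vectors.

## Known limitations

* The generator's task-level latent is exchangeable within participant: no
  learning curves, no autocorrelation, no game-difficulty structure, no
  dropout. Conclusions about pipeline correctness transfer to real data;
  conclusions about effect sizes do not.
* Regressing the outcome on an *estimated* RTACC (≈390 pairs) attenuates
  the planted effect by roughly the reliability ratio
  $\mathrm{var}(\rho_p)/(\mathrm{var}(\rho_p) + \mathrm{var}(\hat r - \rho_p))$,
  about 3–8% here; recovery claims are therefore stated against the planted
  coupling, with the stream-to-estimate fidelity validated separately.
* In-sample AUCs are optimistic; the k-fold option is deliberately off by
  default to mirror the source procedure.
* Huber regression protects against outcome outliers, not leverage points;
  with 10% gross symmetric outcome contamination both estimators remain
  unbiased and the robust fit's advantage is a roughly halved error
  magnitude, not a guarantee of winning every dataset.
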