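# rtacc

Digital-biomarker analysis of computerized cognitive training streams.

Older adults with mild cognitive impairment who receive a multi-domain
intervention (MI — cognitive training, exercise, nutrition, risk-factor
management, motivation) improve on average, but responses vary widely, and
baseline clinical information predicts that variation poorly. Game-based
cognitive training continuously logs in-game behavior, and this package is
built around one integrative summary of that stream: **RTACC**, the
per-participant correlation between each 3-minute task's mean reaction
time and its accuracy,

```
RTACC_p = corr(RT_i, Accuracy_i)    over participant p's tasks i
```

Under the usual speed–accuracy trade-off this correlation is positive; a
*negative* RTACC identifies participants who were fast **and** accurate on
the same tasks — efficient, automatized processing — and is the regime
associated with greater cognitive improvement (RBANS change) after 24
weeks of MI.

The package provides, for anyone analyzing adaptive cognitive-training
logs (or validating methods for them):

* **Synthetic cohort generator** (`cohort_config()`, `generate_cohort()`)
  — a calibrated emulation of a 130-participant, 24-week training trial:
  18-game catalogue in five cognitive domains, 3–5 sessions/week of four
  3-minute tasks (≈390 RT–accuracy pairs per participant), adaptive
  difficulty staircase, a planted per-participant RT–accuracy coupling,
  and outcome/biomarker changes from planted linear effects.
* **Ingest & preprocessing** (`read_training_log()`, `read_participants()`,
  `check_missing()`, `mad_flags()`, `apply_outlier_filter()`) — schema
  validation with row quarantine, missingness accounting, and the
  per-participant MAD outlier rule (k = 3, consistency constant 1.4826).
* **Metrics** (`compute_rtacc()`, `rtacc_windows()`,
  `rtacc_leave_one_game_out()`, `label_responders()`) — full-period,
  time-windowed (weeks 1, 2, 3, 6, 12, 24) and leave-one-game-out RTACC,
  plus good/poor responder labels from the sign of the RBANS change.
* **Inference** (`fit_linear_rbans()`, `fit_robust_rbans()`,
  `fit_path_model()` / `prune_path_model()`, `fit_responder_models()`,
  `roc_auc()`) — the covariate-adjusted linear model
  `RBANS_24 ~ age + sex + education + APOEe4 + RBANS_0 + RTACC`, a Huber
  robust (IRLS) sensitivity fit, a recursive path model through blood
  biomarker changes (BDNF, pTau181, NfL, GFAP) with p-value pruning, and
  three responder-classification logistic models scored by rank-based AUC
  with stratified bootstrap CIs.
* **Pipeline** (`run_config()`, `run_pipeline()`) — one seeded,
  hash-stamped, byte-reproducible run from simulation (or CSV ingest) to a
  markdown report; `inst/cli/rtacc_pipeline.R` is a thin command-line
  wrapper.

## Worked example

```r
library(rtacc)

cfg    <- cohort_config(n_participants = 130, seed = 42)  # calibrated defaults
cohort <- generate_cohort(cfg, dir = NULL)

vals <- rtacc_windows(cohort$training_log, windows = c(2, 24))
tab  <- build_analysis_table(cohort$participants, vals, window = 24)

fit_linear_rbans(tab)
#> <model_fit: ols, n = 130>
#>              term estimate std_error statistic   p_value
#> 1     (Intercept)  50.2449  10.67715     4.706 6.686e-06
#> 2             age  -0.4888   0.13592    -3.596 4.661e-04
#> 3             sex  -1.8636   1.59889    -1.166 2.460e-01
#> 4 education_years   0.2420   0.16246     1.489 1.389e-01
#> 5         apoe_e4  -3.1778   1.68146    -1.890 6.112e-02
#> 6  rbans_baseline   0.9003   0.05107    17.629 1.841e-35
#> 7           rtacc -11.1105   2.98346    -3.724 2.972e-04
```

The `rtacc` row is the estimate of interest: each unit decrease in RTACC
(a stronger fast-and-accurate coupling) predicts an ~11-point larger
24-week RBANS gain after adjustment, here recovering the planted effect of
−11.90 within sampling error. Because baseline RBANS is a covariate, the
fit is equivalent to modelling the change score.

```r
mods <- fit_responder_models(tab, bootstrap_reps = 2000, seed = 42)
for (m in mods) print(m)
#> <responder_model 1: AUC 0.694 (95% CI 0.565-0.808), 109 good / 21 poor>
#> <responder_model 2: AUC 0.649 (95% CI 0.519-0.772), 109 good / 21 poor>
#> <responder_model 3: AUC 0.764 (95% CI 0.660-0.864), 109 good / 21 poor>
```

Model 1 uses clinical information only, model 2 RTACC only, model 3 both;
combining the digital biomarker with clinical covariates gives the best
in-sample discrimination of good responders (increased RBANS at week 24).
A full run — windowed and leave-one-game-out sensitivity fits, the
biomarker path model with pruning, figures and a markdown report — is one
call:

```r
res <- run_pipeline(run_config(cohort = cfg, seed = 42), out_dir = "runs/demo")
```

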