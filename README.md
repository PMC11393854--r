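# cmmcdyn

Longitudinal analysis of circulating multiple myeloma cell (CMMC) counts.

CMMCs are clonal plasma cells detected in peripheral blood
(CD138+/CD38+/DAPI+/CD19−/CD45−), enumerated as an absolute count per 4 mL.
Serial enumeration is a minimally invasive alternative to repeated
bone-marrow sampling for monitoring smouldering (SMM) and newly diagnosed
multiple myeloma (MM). `cmmcdyn` is for biostatisticians and translational
researchers who need the complete analysis chain around such data:

* **Cohort I/O** — validated CSV schemas for patients, serial enumerations
  with co-measured biochemistry, and bone-marrow MRD records.
* **coMMstant index** — the on-treatment trajectory classifier: index 1
  for patients with CMMCs ≥ 1 at every in-window enumeration, 0 when any
  in-window count is zero, indeterminate below two enumerations. Both
  published variants of the rule (`all_positive`, `first_two`) are
  available.
* **Baseline stratification** — median split of earliest-enumeration
  counts (ties go high) and flow-cytometry–equivalent percentages via
  calibration pairs.
* **Dynamics statistics** — pairwise-complete Pearson/Spearman matrices,
  Kruskal–Wallis, probability-mass two-sided Fisher exact, and a
  random-intercept Gaussian mixed model on log(count + 1) reporting
  multiplicative effects exp(β) per biomarker unit.
* **MRD concordance** — milestone pairing of marrow MRD with blood
  enumerations, hemodilution exclusion accounting, detectability
  concordance, and the coMMstant × MRD cross-tab.
* **Survival** — Kaplan–Meier, log-rank and two-group Cox (Efron ties)
  contrasts between trajectory classes.
* **Single-cell CNA clonality** — arm-level calls against a diagnostic
  bulk profile: clonal / subclonal / rare categories, emerging-alteration
  detection, bulk overlap (Jaccard), main ploidy.
* **Synthetic cohorts** — a seeded generator producing zero-inflated
  negative-binomial counts (log-mean linear in β2-microglobulin with a
  5.5× default effect per mg/L), proportional-hazards survival (default
  class hazard ratios 4.554 for PFS, 7.805 for OS), coupled MRD
  detectability and multi-subclone single-cell experiments — all carrying
  ground-truth labels.

The model at the core: for patient *i*, timepoint *j*,

```
count_ij ~ ZINB(mu_ij, size)
log mu_ij = alpha + log(5.5) * (beta2m_ij - 3.5) + delta * phase_ij + u_i
u_i ~ N(0, sigma_u^2)
```

with structural zeros only in the clearing class, zero-truncation in the
persistent class (so "consistently detectable" holds by construction), and
exponential proportional-hazards survival between the two classes. The
estimation side inverts this: a REML mixed model on log(count + 1)
recovers exp(β̂) per predictor, and Cox partial likelihood recovers the
class hazard ratios.

## Worked example

```r
library(cmmcdyn)

# bundled 7-patient SMM monitoring series: stratify at the baseline median
coh <- example_smm_cohort()
stratify_by_baseline_median(baseline_counts(coh))
#> $median
#> [1] 327
#> $high
#> [1] "AIRC19_051" "AIRC19_054" "AIRC19_055" "AIRC19_075"
#> $low
#> [1] "AIRC19_001" "AIRC19_013" "AIRC19_021"
```

Four of seven patients sit at or above the median count of 327 (the
patient exactly at the median is in the high group by convention); higher
baseline counts flag the patients more likely to progress.

```r
# simulate an MM monitoring cohort and run the trajectory analysis
gen <- generate_cohort(generator_config(n_patients = 200, seed = 1))
cls <- classify_cohort_commstant(gen$cohort)
table(cls$index)
#>             0             1 indeterminate
#>           109            63            28

survival_by_commstant(gen$cohort, cls, "pfs")$cox
#> HR = 5.969 (95% CI 3.500-10.180), log-rank p = 1.273e-13
#>   n = 109/63, events = 20/44

concordance(pair_measurements(gen$cohort))
#> MRD-CMMC concordance: 216/284 pairs (76%), 60 excluded for hemodilution
```

Patients with persistently detectable CMMCs (index 1) progress markedly
faster; blood and marrow detectability agree in roughly three quarters of
evaluable milestone pairs, with hemodiluted-undetectable marrow samples
excluded rather than counted as negative.

```r
# longitudinal count-biomarker model on the at-risk observations
tp <- merge(gen$cohort$timepoints, gen$truth$observations,
            by = c("patient_id", "time_months"))
fit_longitudinal_model(tp[!tp$structural_zero, ],
                       predictors = c("beta2m", "phase_index"))
#>             log_coef fold_change
#> beta2m        1.5409      4.6686
#> phase_index  -1.2029      0.3003
```

Each mg/L of β2-microglobulin multiplies the expected CMMC count by
≈ 4.7 here (generative truth 5.5; the gap is the documented log(count+1)
attenuation at low counts), while each treatment phase step reduces it by
≈ 70%.

A one-call orchestration of all stages, with CSV/JSON outputs and an
exclusion-accounting log, is available via `run_pipeline()` (see
`inst/scripts/cmmc_pipeline.R` for the shell wrapper).

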