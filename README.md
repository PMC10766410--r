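# reprometab

Analysis of frequent-sampling gonadotropin time series from paired
diet-intervention (crossover) studies, with a calibrated synthetic cohort
generator. The package targets the study design used to probe
*reprometabolic syndrome* — the relative hypogonadotropic hypogonadism of
obesity — in which each woman is sampled in the early follicular phase
before and at the end of a eucaloric high-fat diet: LH/FSH drawn every
10 min for 6 h, with a 75 ng/kg GnRH bolus at 240 min splitting the session
into an endogenous (0–240 min) and a stimulated (240–360 min) window.

It provides, as testable building blocks:

* **Simulation** — pulsatile LH secretion as a renewal pulse train
  (truncated-normal interpulse intervals, mean 83 min) with
  instantaneous-rise / exponential-decay pulses (amplitude 2.4 ± 1.1 IU/L,
  elimination half-life 45 min) on a basal level, a GnRH-stimulated
  response raising the time-averaged level of the stimulated window, a
  within-subject multiplicative diet effect, lognormal assay noise
  (CV 3.4% for LH), and lognormal between-subject heterogeneity shared
  across visits; plus a three-timepoint metabolite generator with
  class-specific trends (depleting, transient, increasing, null) and
  optional hormone-coupled metabolites.
* **Pulse detection** — the modified Santen–Bardin sweep: a pulse is an
  excursion whose peak exceeds the running nadir by ≥ 20%
  (`single_point`), with a stricter two-consecutive-samples variant
  (`two_point`); peak-to-peak interpulse intervals and amplitude summaries.
  The sweep's semantics are pinned by an exhaustive reference
  implementation in the test suite.
* **Response metrics** — trapezoidal AUC per window, time-normalized AUC
  (AUC/window length, in IU/L) as the GnRH-response measure, mean
  endogenous level, and percent change `100·(pre − post)/pre`.
* **Paired inference** — log-scale paired t tests gated by Shapiro–Wilk on
  the paired log-differences (α = 0.05), falling back to exact Wilcoxon
  signed-rank; geometric means; a Table-style cohort report.
* **Metabolomics stage** — per-metabolite repeated-measures ANOVA on log
  abundances with Greenhouse–Geisser correction, Benjamini–Hochberg FDR,
  deterministic top-feature ranking, and pooled Spearman
  hormone–metabolite correlation.

## Worked example

```r
library(reprometab)

cfg <- cohort_config(n_subjects = 18, seed = 2026L)  # pre-diet LH calibration
coh <- simulate_cohort(cfg)                          # 18 x {pre,post} x {LH,FSH}

lh  <- Filter(function(s) s$hormone == "LH", coh)
cs  <- lapply(lh, detect_pulses)                     # single-point, 20%, 0-240 min
vs  <- summarize_cohort(coh)
rep <- build_report(vs, pulsatility_by_subject(cs))
writeLines(format_report(rep))
```

```
Metric                                   Pre      Post  Change%         Test       P
Mean LH (IU/L)                          3.93      3.28     16.5 paired_t_log  <0.001
LH response to GnRH (IU/L)              9.13      6.26     31.4 paired_t_log  <0.001
Mean FSH (IU/L)                         6.94      6.57      5.3 paired_t_log  <0.001
FSH response to GnRH (IU/L)             8.48      7.87      7.3 paired_t_log  <0.001
LH pulse amplitude (IU/L)               2.04      1.69     17.3 paired_t_log    0.04
LH interpulse interval (min)           84.77     89.89     -6.0 paired_t_log    0.59
```

Pre/Post are geometric means. This simulated 18-subject cohort recovers
the configured design: endogenous LH suppressed by roughly 12% and the
GnRH-stimulated response by roughly 29% (here 16.5% and 31.4% — one
cohort's sampling noise around those targets), FSH changes smaller, and no
significant change in pulse timing. The per-visit pulsatility summary
(`summarize_pulsatility(cs)`) reports, for this seed, a pre-diet amplitude
of 2.22 ± 0.92 IU/L (mean ± SD) and an interpulse interval of
88.6 ± 6.6 min (mean ± SEM), against generator settings of 2.4 IU/L and
83 min.

`run_pipeline(cfg, "out/")` executes every stage (simulate → detect →
summarize → report → metabolomics) and writes the stage CSVs plus a
`manifest.json` with the configuration snapshot, seed and file digests;
re-running with the same configuration reproduces the outputs
byte-for-byte. An external long-format series CSV can replace the
simulation via `series_csv =`.

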