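---
title: "Methods: simulation and analysis of gonadotropin pulsatility in a paired diet intervention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and analysis of gonadotropin pulsatility in a paired diet intervention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprometab)
```

## The study design this package models

`reprometab` analyses paired crossover studies of gonadotropin secretion in
which each subject is sampled twice — before and at the end of a dietary
exposure — with a frequent-sampling protocol: blood drawn every 10 minutes
for 6 hours, the first 4 hours unperturbed (the *endogenous* window), a
GnRH bolus at 240 minutes, and 2 further hours of sampling (the
*stimulated* window). LH and FSH are measured in IU/L. The scientific
questions are whether the exposure suppresses (i) mean endogenous
gonadotropin output, (ii) pituitary responsiveness to GnRH, and (iii) LH
pulsatility (pulse amplitude and frequency), and how the plasma metabolome
moves over the exposure.

Because subject-level raw series from such studies are rarely
redistributable, the package pairs every analysis stage with a calibrated
synthetic-cohort generator, so the full pipeline is testable end to end and
its estimators can be validated by parameter recovery.

## The secretion simulator

One subject-visit series is generated as

\[
y(t_k) = \Big[ b\,m + \sum_{j:\,\tau_j \le t_k} A_j\, m\, m_a\,
  e^{-\lambda (t_k - \tau_j)} + s(t_k) \Big]\; u\; \varepsilon_k ,
\]

with

* **Pulse train**: onsets \(\tau_j\) from a renewal process whose
  inter-onset intervals are truncated-normal (mean `mean_ipi`, SD `ipi_sd`,
  floored at one sampling interval so pulses remain resolvable; any
  coincident pulses simply superpose). The train starts ten half-lives plus
  two mean intervals before time zero so the sampled window sees a
  stationary superposition of tails.
* **Pulse shape**: instantaneous rise, single-exponential decay with
  elimination rate \(\lambda = \ln 2 / t_{1/2}\). The half-life default of
  45 min is within published LH kinetics; no secretion-event shape beyond
  this is modelled because the detector only consumes nadir-to-peak
  excursions at a 10-minute grid.
* **Amplitudes** \(A_j\): truncated-normal, positive. A configured mean of
  0 switches pulses off entirely (used by the flat-series contracts).
* **Diet effect**: at the post visit the whole endogenous level (basal and
  pulses) is multiplied by \(m =\) `diet_effect_mean`, and amplitudes by an
  extra factor \(m_a =\) `diet_effect_amplitude`. The post/pre ratio of
  endogenous means therefore converges to `diet_effect_mean` as noise
  vanishes. A consequence of this multiplicative composition: with the
  default \(m_a = 1\) the simulated post-diet amplitude shrinks with the
  level; a user wanting level suppression with preserved amplitude sets
  `diet_effect_amplitude = 1/diet_effect_mean`.
* **GnRH response** \(s(t)\): a gamma-like rise-and-decay shape
  \((u/30)\,e^{1-u/30}\) (peak 30 min after the bolus), scaled so the
  expected time-averaged total level over 240–360 min equals
  `gnrh_response_mean` (times `diet_effect_gnrh` post). Only the
  time-averaged response (a normalized AUC) feeds the analysis, so the
  shape detail is deliberately simple.
* **Noise**: multiplicative lognormal with unit mean and CV `assay_cv`
  (assays report CVs, not additive SDs), applied last. Between-subject
  heterogeneity \(u\) is a single lognormal level multiplier (CV
  `between_subject_cv`) shared across visits and hormones, which induces
  the within-subject correlation that paired testing exploits.

### Calibration

Defaults are calibrated to the pre-diet early-follicular LH reference
values: interpulse interval 83 min, amplitude 2.4 ± 1.1 IU/L, mean LH
4.3 IU/L, GnRH-stimulated level 10.1 IU/L, intra-assay CV 3.4%. The basal
level is not reported by such studies; it is derived from the stationary
mean of the pulse superposition,

\[ \mathbb{E}[y] = b + \mathbb{E}[A]\,\frac{t_{1/2}/\ln 2}{\mathrm{IPI}}
   \approx b + 2.44 \times \frac{64.9}{83} \approx b + 1.9 , \]

so \(b = 2.4\) IU/L yields a mean of ≈ 4.3 IU/L. The diet multipliers
default to the reference pre/post ratios 3.8/4.3 (mean LH) and 7.2/10.1
(GnRH response). Choices the data do not pin down, made once and stated
here: `ipi_sd = 15` min (the published ±11 is a cohort SEM, not a
within-subject interval SD; 15 min is a realistic follicular-phase
dispersion), `between_subject_cv = 0.25` (paired designs report no ICC;
0.25 gives geometric-scale SDs of the magnitude such cohorts show), and
the 45-min half-life. FSH is simulated pulse-free (no FSH pulses are
detectable at this sampling rate) with its own level calibration
(7.8 → 7.4 endogenous, 9.5 → 8.8 stimulated, CV 5%).

Reproducibility: one master seed; per-subject effects and per-series
streams are derived substreams indexed by subject/hormone/visit counters,
so enlarging a cohort never reshuffles earlier subjects, and equal
`(config, seed)` gives bit-identical output.

## Pulse detection

The detector implements the nadir-to-peak excursion criterion
("modified Santen–Bardin"): a pulse is an excursion whose peak exceeds the
preceding nadir by at least 20% (`threshold = 0.2`). Published
descriptions under-specify the scan mechanics, so the package commits to
an explicit sweep whose semantics are pinned by an exhaustive reference
implementation in the test suite:

* a running nadir records the earliest minimum since the last confirmed
  pulse;
* a sample *qualifies* when its relative rise over the running nadir is at
  least the threshold ("at least 20%" means the boundary qualifies);
* `single_point` confirms a pulse at the first qualifying sample;
  `two_point` requires two consecutive qualifying samples against the same
  nadir (the stricter published variant);
* the peak is the earliest maximum from the first qualifying sample until
  the first strict decline; ties take the earliest sample;
* after a pulse the nadir search restarts at the sample following the
  peak, so pulses cannot overlap;
* a running nadir of exactly 0 IU/L cannot form a ratio; such samples are
  skipped with a warning.

Detection is confined to the endogenous window (0–240 min): the
GnRH-stimulated rise would otherwise always be called a pulse. No
smoothing or pre-filtering is applied; robustness to assay noise comes
from the threshold and the two-point variant. The interpulse interval is
measured peak-to-peak, because peaks are the only observable landmarks on
a 10-minute grid; it is undefined (and excluded from summaries, with a
count) for series with fewer than two pulses. Single-point results are the
headline outputs.

Cohort summaries are computed subject-level first: the cohort mean
amplitude carries an SD, the mean interpulse interval an SEM, matching the
field's reporting convention.

A note on estimator bias visible in parameter recovery: pulses whose
amplitude falls below 20% of the local nadir are undetectable by
construction (about 5% of pulses under the default calibration), which
inflates the estimated interpulse interval by a few minutes relative to
the generating renewal mean. This is a property of the detection criterion
itself, shared with its use on real data.

## Response metrics

Per subject-visit: the arithmetic mean of the endogenous samples, and the
composite-trapezoid AUC of each window. "Response to GnRH" is reported as
the time-normalized AUC (AUC divided by the 120-min window), which puts
stimulated responses on the IU/L scale of mean levels and makes a
stimulated level of ~10 IU/L commensurate with a mean LH of ~4 IU/L; the
raw IU·min/L AUC is also emitted. The 240-min sample belongs to both
windows (the bolus is administered at that instant), and no baseline
subtraction is applied to the stimulated window. Percent change is
\(100\,( \mathrm{pre} - \mathrm{post})/\mathrm{pre}\), rounded only at
reporting: the reference pairs give 29% (10.1 → 7.2), 12% (4.3 → 3.8) and
5% (7.8 → 7.4); the analogous 9.5 → 8.8 computation gives 7.4%, not the
8% sometimes quoted — a rounding discrepancy internal to the source
material, documented here and not treated as a target.

## Paired inference

The testing scheme mirrors standard practice in these studies: values are
log-transformed and compared by a paired t test when the log-differences
are compatible with normality; otherwise a Wilcoxon signed-rank test is
used. "Could not be normalized" needs an explicit, testable rule: the
package uses Shapiro–Wilk on the paired log-differences at α = 0.05.
Wilcoxon runs on the raw differences, drops zero differences (the simple
convention, stated in output), and uses the exact distribution for n ≤ 25
without ties. Degenerate inputs are resolved rather than left to error:
identical pre/post vectors give percent change 0 and p = 1 with a warning;
an exact fold change (zero-variance log-differences) reports p at the
smallest positive double; with only two pairs normality cannot be assessed
and the log-scale t path is taken. Centers are reported as geometric means
(with arithmetic means alongside); log-scale analysis makes p-values
invariant to common rescaling, so whether the t test consumes raw or
time-normalized AUC is inert for inference. No multiple-testing correction
is applied across the report's handful of endocrine metrics, matching the
per-metric reporting convention; the metabolomics stage, where thousands
of features are possible, does correct.

## Metabolomics stage

Three timepoints (pre, on-diet, end-of-diet) per subject per metabolite.
Abundances are log-transformed before testing (intensities are
multiplicative). Per metabolite a balanced one-way within-subject ANOVA is
computed from the closed-form sum-of-squares decomposition; a
Greenhouse–Geisser correction to the degrees of freedom is applied
whenever the timepoint covariance is estimable — with three timepoints
sphericity violations are mild, but the correction is the conservative
default of standard metabolomics tooling. (The closed form is used for
speed across thousands of metabolite fits; the test suite verifies it
against `aov(y ~ time + Error(subject/time))`, and with two timepoints it
reduces to the squared paired t statistic.) Benjamini–Hochberg q-values
are computed across metabolites, and each metabolite receives a direction
class from the ordering of its timepoint means (increasing / decreasing /
transient / flat). Feature ranking for downstream clustering orders by p,
then |F|, then name — a deterministic tie-break.

Hormone–metabolite association uses Spearman correlation. The default
pools all (subject, timepoint) pairs per metabolite — the
trajectory-association framing — with exact small-sample p-values where
ties allow; a per-subject mode (average of within-subject rank
correlations over 3 points) is exposed for sensitivity analysis. Whether
such analyses should aggregate to pathway level first is a genuinely open
choice; the package implements the metabolite level and leaves aggregation
to the caller.

The metabolite generator mirrors the patterns the trend stage must
recover: geometric trend ratios per class (defaults: depletion to 0.55 of
baseline, transient doubling, monotone doubling, and nulls), lognormal
baselines, a subject-by-metabolite random level (CV 0.30) and residual CV
0.20, plus optional metabolites coupled monotonically to a supplied
hormone trajectory for validating the correlation stage. In the pipeline
driver the on-diet hormone value is proxied by the pre/post midpoint,
since the frequent-sampling design measures hormones at only two visits.

## Problem sizes used by the validation suite

Chosen as the package's own validation design: parameter recovery uses 200
simulated pre-diet subjects (cohort-mean tolerances: ±10 min interpulse
interval, ±0.5 IU/L amplitude, ±0.4 IU/L mean level); null calibration of
the paired test uses 1000 cohorts of 18 subjects with the rejection rate
checked against the 99% binomial band around 0.05; effect recovery
averages percent changes over 200 cohorts; FDR control uses 500 all-null
matrices of 40 metabolites × 18 subjects; detector-oracle equivalence
enumerates every series up to length 6 over a four-level alphabet spanning
the 10/20/50% thresholds and samples 600 longer series at fixed seed.

## What passing tests do and do not show

The generator emulates the statistical structure the analysis assumes —
stationary pulsatility, multiplicative noise, a shared subject level,
class-wise metabolite trends. It does not emulate circadian or sleep
structure, assay drift, missed draws or irregular grids, estradiol/SHBG
dynamics, secretion-burst shapes, or correlated metabolite blocks beyond
the explicit hormone coupling. Parameter recovery on simulated cohorts
validates the estimators under the stated model; it cannot certify
behaviour on real series that violate it (e.g. strongly non-stationary
baselines). The detector's semantics are fixed by the oracle; variants of
the "modified" criterion that merge adjacent pulses or pre-smooth would
give different counts on noisy data.
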