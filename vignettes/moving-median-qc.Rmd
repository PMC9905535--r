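---
title: "Patient-based statistical quality control of quantitative CMR with moving-median charts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-based statistical quality control of quantitative CMR with moving-median charts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrqc)
```

## The monitoring problem

Quantitative cardiovascular magnetic resonance (CMR) reports left-ventricular
(LV) function parameters — ejection fraction (EF, %), end-diastolic volume
(EDV, ml), stroke volume (SV, ml), LV mass (LVM, g), and the derived
end-systolic volume ESV = EDV − SV — whose values feed directly into clinical
decisions. The measurement chain (scanner hardware and software, acquisition
protocol, post-processing tools, human readers) changes over the years, and
any such change can introduce a *bias*: a persistent shift in the reported
level, switched on at a discrete point in time and convolved with the large
patient-to-patient variation. Classical phantom- or volunteer-based quality
control snapshots the chain at isolated dates; it does not watch the routine
stream. `cmrqc` implements the complementary, patient-based approach known in
laboratory medicine as *Average of Normals*: monitor a robust location
statistic of consecutive patient results and alarm when it leaves a fixed
tolerance interval.

## The chart

For a cleaned, date-ordered stream of one parameter's values
$x_1, x_2, \dots$, the monitored statistic is the trailing moving median

$$\mathrm{MM}_i = \mathrm{median}(x_{i-w+1}, \dots, x_i), \qquad i \ge w,$$

with a sample-count window $w$. The default windows are 250 and 750 samples,
roughly one month and one quarter of scanning at a high-volume center
(about 197 examinations per month); windows are counted in examinations, not
calendar days, so the smoothing is uniform in information rather than in
time. The median (rather than a mean) keeps single extreme values — which
survive any plausible inclusion filter — from moving the statistic. Even
windows use the midpoint of the two central order statistics.

An *alert* is a defined MM entry strictly outside the per-parameter tolerance
interval $[L, U]$; a value exactly on a limit is in control (the strictness
is configurable, `strict = FALSE` alarms on the limits too). The limits are
*fixed inputs*, in clinical use derived from intra-observer variability
studies; they are never estimated from the monitored data, otherwise a slow
drift would recalibrate its own alarm away. Contiguous alerts form runs;
a run never mixes directions, so a jump from above $U$ to below $L$ between
adjacent entries opens a new run. Alert load is aggregated per calendar year
as the percentage of defined MM entries that alert (each examination past
warm-up contributes exactly one MM entry, so this equals the percentage of
examinations whose chart entry is out of limits), and period summaries are
arithmetic means of the constituent yearly percentages. Calendar attribution
uses the window's most recent examination date.

## Inclusion filters

Exam records arrive as a flat CSV export. Per parameter, a data point is
included iff

* the value is present (missing values are never imputed),
* the exam date is a real calendar date (an existing day, month and year —
  strict round-trip parsing, so a February 30th is flagged, not normalised),
* the value is strictly greater than zero, and
* the value is strictly smaller than 1.5 × the 99th percentile of the
  *uncleaned* column (all non-missing values before any exclusion; date
  validity is an independent filter and does not change the cap).

Each excluded entry carries exactly one reason (`missing`, `invalid_date`,
`nonpositive`, `above_p99_cap`, assigned in that order), and the cleaning
report's counts always add back to the input count. The percentile estimator
defaults to linear interpolation between order statistics
(`stats::quantile` type 7) with nearest-rank (type 1) as an alternative;
the choice moves the cap only at the margin. Filtering is per parameter —
an exam with an implausible LVM still contributes its SV — with an
intersection mode (`included_for_all()`) for cohort-style summaries.
Derived quantities (ESV, Mosteller BSA $\sqrt{hw/3600}$, BMI) are computed
from raw columns *before* cleaning and then pass through the same filter;
a negative derived ESV is flagged at derivation but removed only by the
nonpositive rule, keeping exclusion logic in one place.

## The synthetic phantom

Because a real exam stream is hospital data, validation runs on a synthetic
phantom with the statistical structure the chart assumes. The generator
draws i.i.d. from a two-component normal mixture mimicking the sex split of
a large clinical cohort's LV SV: females $N(75.5, 18.1^2)$ ml with weight
8553/20337, males $N(93.9, 25.5^2)$ ml with weight 11784/20337, 20,000
samples. These parameters are a documented modeling choice anchored in
published sex-stratified summary statistics — the generator emulates the
*marginal* distribution and the sample size, nothing more. A distortion is a
constant step: `inject_step()` adds a fixed offset (default experiment:
+5 ml from sample 10,001 onward) and returns the matching 0/1 confounder
indicator. Synthetic exam dates advance at 197 per calendar month purely so
the calendar-based reporting works.

What the phantom deliberately does *not* emulate: case-mix drift, seasonal
referral patterns, reader rotations as generative processes, autocorrelation
from scheduling, or heavy non-Gaussian tails. Passing tests on the phantom
therefore demonstrate the *mechanics* (filters, chart, alerting, attribution,
run-length behavior) under the stated mixture, not performance on any real
stream.

## Drift attribution

Detected drifts are confronted with candidate confounders (staff rotation,
scanner relocation, software updates) in two ways.

**Granger causality.** `granger_test(cause, effect)` compares the
restricted autoregression of the effect on its own lags $1..L$ against the
unrestricted model adding the cause's lags, by the F-test on the added
coefficients. The lag $L$ is chosen by AIC *on the restricted model only*
(candidates 1..5 on a common sample). Selecting the lag on the unrestricted
model — i.e. picking the order under which the cause looks most predictive —
inflates the empirical type-I error to roughly twice the nominal level in
our simulations (about 10% at $\alpha = 0.05$ with 200-sample series), while
restricted-model selection holds ~5–6%; that measurement settled the design.
The test runs on the *raw* per-exam series, not the MM series: MM values are
overwhelmingly autocorrelated by construction (adjacent windows share
$w - 1$ samples) and would fabricate significance. A deterministic step
violates the test's stationarity assumptions; the package computes the test
anyway — this mirrors its intended screening use — but warns on monotone
inputs instead of silently differencing (`difference = TRUE` is available).
The two directions are always two independent calls; no symmetry is assumed.

**Step recovery.** `estimate_step()` quantifies a drift visible in an MM
chart. The pre-change level is the median of MM entries whose windows end at
least one window before onset, the post-change level the median of entries
whose windows start at or after onset; entries straddling the onset mix both
regimes and are excluded from both levels. The magnitude is the level
difference. When the onset is unknown it is searched in two stages: a global
split maximizing the between-segment median difference scaled by the split's
precision $|d| / \sqrt{1/n_{\text{pre}} + 1/n_{\text{post}}}$ (unscaled, the
argmax drifts to the series edges, where a handful of entries can produce an
extreme segment median), then a local refinement using the MM jump
$J(s) = \mathrm{MM}_{s+w-1} - \mathrm{MM}_{s-1}$, taking the midpoint of the
maximal plateau of $|J|$. For a noiseless step the saturated-median plateau
is symmetric about the true onset, so the refinement recovers it exactly;
in noise the onset uncertainty is of the order of the window.

On the default phantom (20,000 samples, +5 ml at 10,001, window 750) the
recovered magnitude is unbiased with a sampling standard deviation of about
0.45–0.5 ml: each level is a median over roughly 10,000 underlying samples
of a mixture with standard deviation ≈ 24.4 ml, so the asymptotic sd of one
level is $1/(2 f(m) \sqrt{n}) \approx 0.31$ ml and the difference roughly
$\sqrt{2}$ times that. A ±0.5 ml check on a single replication is therefore
a ~1-sigma statement, and individual seeds can land outside it without any
defect in the procedure.

## Run-length characteristics

Window size trades two quantities, both estimated by Monte Carlo with
common random numbers across compared configurations (paired seeds sharpen
monotonicity comparisons):

* **Average Run Length (ARL)** — samples until the first false alert on an
  in-control stream. Replicates with no alert before the stream ends are
  *censored*: counted and reported, never imputed, so short desk runs bias
  visibly rather than silently.
* **Average Delay Time (ADT)** — samples from bias onset to the first alert
  at or after onset. Replicates that alert before onset are false-alert
  contaminated; they are discarded from the mean and reported as a separate
  fraction. At tight limits and long pre-onset stretches this fraction
  approaches one, which is why delay experiments place the onset just past
  warm-up (zero-state style) rather than mid-stream.

Run lengths are measured in samples; conversion to months is a reporting
concern via `exams_per_month`. Larger windows lengthen both ARL (good) and
ADT (bad); the package exposes the surfaces (`run_length_grid()`) plus a
simple constrained pick — the largest window whose mean delay stays under a
user ceiling — clearly an extension layered on the surfaces, not part of the
monitoring procedure. No analytic ARL theory for median charts is attempted.

## Numerical choices

* The moving median is computed in C++ with a sorted sliding buffer
  (binary-search insert/remove per step); results are exactly the per-window
  sort-and-pick order statistics, verified against an independent oracle.
* Medians are location-equivariant, and the implementation preserves this at
  the bit level whenever the shifted central values are exactly
  representable — in particular the shifted phantom's fully-post-onset MM
  equals the stationary MM plus the magnitude, bit for bit; windows
  straddling the onset differ, as they must.
* The default experiment seed (20337) is recorded in every output; all
  Monte-Carlo estimators take explicit base seeds and derive one seed per
  replicate, which is what makes the paired-seed comparisons possible.
* Degenerate inputs fail loudly: windows longer than the series, constant
  effect series in the Granger regression, charts with fewer included values
  than the window, a delay estimate without a bias, onsets outside the
  series.
* Ties in exam dates keep file order (stable sort); invalid-date entries are
  retained, flagged, at the end of the cleaned series.

## Problem sizes used in the shipped checks

The phantom experiments run at the full 20,000-sample scale. Run-length
surfaces use 40–100 replicates per cell and streams of 10,000–20,000
samples; the Granger size check uses 200 white-noise pairs of length 200.
These sizes put Monte-Carlo standard errors comfortably inside the margins
the checks assert while keeping a desktop run in minutes.

## Known limitations

* Tolerance limits must be supplied; the shipped configuration values are
  placeholders for demonstration, not clinical limits.
* Only step distortions are generated; ramps and transients are extension
  points.
* The Granger screen is descriptive under nonstationarity, and the package
  deliberately stops short of automated root-cause conclusions.
* The per-year alert percentage equals a per-examination percentage only
  past warm-up; the first `w − 1` examinations of a stream are never
  scored.
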