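---
title: "Patient-based real-time QC: the transform-truncate-alarm workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patient-based real-time QC: the transform-truncate-alarm workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrtqc)
```

## The problem

Clinical laboratories run internal quality control at discrete time points,
but analytical shifts — a reagent lot change, a drifting calibration, a
deteriorating instrument — can arise between QC events. Patient-based
real-time quality control (PBRTQC) monitors the stream of routine patient
results itself: a rolling statistic of recent results is charted against
control limits, and a sustained excursion signals a systematic analytical
error at essentially zero marginal cost and much higher frequency than QC
material allows.

Classical control-chart statistics are sensitive to what patient-result
distributions actually look like: strictly positive, right-skewed, long
upper tails, occasional extreme values. This package therefore chains three
standardizing stages before any chart is read — *transform* (Box-Cox or
log), *truncate* (Winsorize against training-set quantile bounds), *alarm*
(a consecutive-point rule on top of the control limits) — and evaluates
three monitoring statistics inside that one framework: the moving average
(MA), the moving quantile (MQ), and the exponentially weighted moving
average (EWMA).

## The monitoring model

Let $x_1, x_2, \dots$ be the chronologically ordered patient results for
one analyte on one instrument.

**Transform.** A one-parameter Box-Cox transform
$z = ((x + c)^\lambda - 1)/\lambda$ is fitted on the training half by
maximizing the profile log-likelihood of $\lambda$ over $[-2, 2]$. The
offset $c$ is zero for strictly positive data and otherwise
$10^{-6}\,\mathrm{median}(|x|) - \min(x)$, the smallest shift that makes
the data admissible. When $|\hat\lambda| < 0.05$ — a conventional
"close to zero" cut — the continuous limit $z = \log(x + c)$ is used
instead and recorded as such. The aim is variance stabilization and skew
reduction, not strict normality: limits fitted on a roughly symmetric
statistic are far more robust to the patient mix than limits on the raw
scale.

**Truncate.** Winsorizing bounds are the empirical $f$ and $1 - f$
quantiles of the *training* transformed values (quantile type 7, linear
interpolation between order statistics — the single quantile definition
used everywhere in the package). Monitored values beyond a bound are
replaced by the bound. The factor $f$ is interpreted per tail, so
$f = 0.02$ clamps 2% low and 2% high, and $f = 0$ is a no-op. Bounds are
frozen from training and reused on validation and live streams, keeping
monitoring causal.

**Monitor.** Three statistics over the truncated transformed stream:

* MA: trailing-window mean, window $w$; undefined for the first $w - 1$
  positions (warm-up).
* MQ: trailing-window empirical quantile at level $q$ (default 0.5, a
  moving median); same warm-up.
* EWMA: $s_t = \lambda_s x_t + (1 - \lambda_s) s_{t-1}$ with $s_1 = x_1$,
  where $\lambda_s$ is the smoothing constant (the weight on the newest
  observation; distinct from the Box-Cox exponent). Initializing at the
  first observation rather than a training mean keeps the statistic causal
  and avoids leaking training information into the monitored stream; the
  cost is a short burn-in whose length scales like $1/\lambda_s$.

**Limits.** The chart center and spread are the mean and standard
deviation of the *statistic itself* on the bias-free training stream
(warm-up excluded): $UCL = m + a\,s$, $LCL = m - b\,s$. Basing limits on
the statistic's own empirical distribution makes the multipliers
$a, b \in \{1.64, 1.96, 2.58, 3\}$ behave as z-quantile multipliers
regardless of window or smoothing choice. Limits are frozen from training.

**Alarm.** A point is outside when the statistic strictly exceeds the UCL
or falls strictly below the LCL. An alarm requires $k$ consecutive outside
points; a qualifying run may mix sides (a statistic whiplashing across
both limits is at least as alarming as one camped on a single side). For
evaluation, the run is retrospectively attributed to its *first* point, so
a run that begins at error onset has detection delay zero.

## Simulated systematic error

Because real analytical failures are rare and unlabelled, performance is
measured on simulated errors embedded in real (or synthetic) bias-free
streams. A scenario suite contains, by default, ten scenarios: proportional
biases of 10, 30, 50, 70 and 90%, each in both directions. Each scenario
carries five error segments of 100–300 consecutive results, separated by
gaps of 250–500 unbiased results; the gap before the first segment is
drawn from [0, 100] (errors may begin soon after monitoring starts) and
the trailing gap absorbs the remainder, which is why realized trailing
gaps are large. Increase/decrease scenarios of the same magnitude share
one layout, so the two directions are compared on identical geometry.
Layout draws that overflow the stream are rejected and redrawn under the
same seed; geometry that cannot fit even at its minimum is refused
outright.

Bias is applied on the **original measurement scale** —
$x \mapsto x(1 + d\,m)$ with direction $d = \pm 1$ — before
transformation. A percent bias is a statement about reported results; its
image under a nonlinear transform has no fixed percentage meaning, so
injecting after transformation would make "30% bias" analyte- and
$\lambda$-dependent.

The drift variant models progressive deterioration: within each segment
the bias fraction at (1-based) position $j$ is
$b + (M - b)\min\{(j-1)/L,\, 1\}$ — baseline $b$ at onset, linear climb
over $L$ observations, plateau at $M$. With $b = M$ it reduces exactly to
the stepwise pattern, which the tests exploit as an equivalence check.

## Scoring

Per scenario, with warm-up positions excluded from every numerator and
denominator:

* **Sensitivity** (observation level, the default): alarmed-and-biased
  observations / biased observations. A segment-level variant
  (detected segments / total segments) is available; observation-level is
  the default because it varies continuously with partial detection and
  does not quantize to multiples of one over the segment count.
* **FPR**: alarmed-and-unbiased observations / unbiased observations.
  Carry-over matters here: a window or EWMA memory that still holds biased
  values just after a segment ends can alarm on unbiased points, and those
  count as false positives.
* **MNPed**: the median across detected segments of (first in-segment
  alarm-run start − segment start). A segment only counts as detected when
  a run *starts* inside it; runs starting in a gap and spilling into the
  segment do not, and their unbiased points count toward FPR. When nothing
  is detected MNPed is undefined.

The composite objective is

$$\mathrm{ME} = 0.0005\,\mathrm{Sens} + 0.999\,(1 - \mathrm{FPR})
  - 0.0005\,\sigma(\mathrm{MNPed}),\qquad
  \sigma(m) = \frac{1}{1 + e^{-0.05 (m - 101)}}.$$

The weights deliberately make false alarms dominant — a tolerance on the
order of $10^{-3}$, reflecting alarm-fatigue economics in high-volume
laboratories — with small, equal side payments for sensitivity and speed;
the delay penalty crosses 0.5 at about a hundred patients. An undefined
MNPed contributes the maximal penalty $\sigma = 1$: never detecting must
not outscore detecting slowly.

Across scenarios, sensitivity and FPR are aggregated by unweighted
averaging, and MNPed by pooling per-segment delays across scenarios and
taking their median (delays are counts on a common scale, so pooling is
meaningful and robust to scenarios with few detections). Two composite
orderings are reported: `me_score` evaluates the formula on the aggregated
triple, `me_score_mean` averages per-scenario composites. They differ in
general — the sigmoid is nonlinear and per-scenario MNPed can be undefined
— so a composite printed without its ordering cannot be recomputed from
aggregated rates alone; ranking uses the aggregate-then-score path.

## Optimization

A grid search scans, per algorithm: window $\{3, 5, 10, 20, 50\}$ (MA/MQ),
quantile $\{0.25, 0.5, 0.75\}$ (MQ), smoothing $0.1$–$0.9$ in steps of
$0.1$ (EWMA), truncation $\{0, 0.01, 0.02, 0.05\}$, $a, b$
$\{1.64, 1.96, 2.58, 3\}$, $k$ $\{1, 3, 5, 10\}$ — 2304 EWMA combinations,
for example. Every list is overridable, and a small `"reduced"` preset
supports quick runs. Configurations whose training statistic degenerates
are recorded as failed with a diagnostic, rank last, and never reach
stage 2. Evaluation is a pure map over configurations — results are
independent of evaluation order, which a test asserts by shuffling.

Selection is two-staged. Stage 1 ranks by ME_Score and retains the top 5%
(at least 20), which always includes the ME maximum. Stage 2 applies
clinical priorities lexicographically: lowest FPR, then highest
sensitivity, then smallest MNPed, with a deterministic tie-break on the
parameter fields. Before that ordering, stage 2 screens for an
*acceptable* MNPed: candidates that detect nothing in one or more
scenarios are set aside (falling back progressively if no candidate
detects everywhere). This screen exists because the truncation and limit
stages interact: a configuration whose Winsorizing bound sits inside a
control limit (e.g. clamping at the 98th percentile, roughly $2.05\,s$,
under a $3s$ limit) can never alarm on that side, achieves an FPR of
exactly zero on the blind side, and would otherwise win the FPR-first
ordering while being useless or half-useless as a monitor.

The selected configuration is then re-scored on the validation half with
its training-frozen transform, truncation bounds and limits — nothing is
re-estimated.

## The synthetic-data generator

Streams are drawn from a log-normal with
$\mu = \log(\mathrm{median})$, $\sigma = \sqrt{\log(1 + \mathrm{CV}^2)}$,
optionally thickened in the upper tail by multiplying a sparse fraction
($\min(0.01 \cdot \mathrm{skew\_strength}, 0.1)$) of observations by a
Uniform(2, 4) factor. Two presets bracket the analyte spectrum the
workflow targets:

* `tsh_like()` — median 1.8, CV 0.8, contaminated tail: a high-variability
  hormone whose Box-Cox exponent lands well below 1, exercising the
  transform branch and the hard end of detection.
* `pt_like()` — median 12, CV 0.03, no contamination: a tight coagulation
  time that is nearly normal already. On this preset even a 10% bias is
  a shift of roughly three population SDs, so a well-configured monitor
  should detect essentially everything; the acceptance checks exploit
  this as a strong end-to-end invariant (validation sensitivity
  $\ge 0.85$, FPR $\le 0.002$, MNPed $\le 7$).

What the generator does **not** emulate: diurnal and weekly patient-mix
cycles, autocorrelation from ward batching, instrument changeovers,
censored-value pileups at assay limits, or real preanalytical outliers.
Passing tests on synthetic streams therefore demonstrate the machinery —
transform estimation, causal truncation, alarm logic, scoring, selection —
not clinical performance on any particular analyte, which must be
re-established on each laboratory's own extracts.

## Numerical and design choices

* Quantiles: type 7 everywhere (truncation bounds, MQ, summaries).
* Box-Cox $\hat\lambda$ by `optimize` on the profile log-likelihood,
  interval $[-2, 2]$, tolerance defaults; the log fallback threshold is
  0.05.
* Strict inequalities at the limits; points exactly on a limit are inside.
* Warm-up positions are excluded from limit fitting, can never be outside,
  and are excluded from metric denominators.
* Indices are 1-based throughout, R's native convention; exported tables
  are 1-based as printed.
* Determinism: every stochastic step (stream synthesis, layout draws)
  takes an explicit seed and restores the RNG state afterwards
  (`withr::with_seed`), so identical inputs give bit-identical outputs.
* Degenerate inputs: constant series are rejected at transform estimation
  and at limit fitting with informative errors rather than NaN
  propagation.

## Problem sizes

The default study size is 7000 records split 1:1 — training and validation
halves of 3500, each carrying ten scenarios of five segments. The package
tests run mostly on 1600–3500-record streams with proportionally smaller
segment geometry, plus two full 7000-record EWMA runs; the complete suite
executes in well under a minute, and a full 2304-point EWMA grid on a
7000-record stream remains a desktop-scale computation (the map over
configurations parallelizes trivially via the `workers` argument).

## Limitations

* The grid's default ranges are pragmatic, not exhaustive; analytes with
  unusual dynamics may want windows or smoothings outside them.
* Observation-level sensitivity rewards long segments more than prompt
  detection; read it together with MNPed.
* The FPR of a frozen configuration is estimated from finite unbiased
  stretches (about 30k observations per suite), so its resolution is
  roughly $3 \times 10^{-5}$; differences below that are noise.
* CUSUM-type monitors and variance-adjusted (time-varying) EWMA limits are
  out of scope, as are multi-instrument harmonization and live LIS
  connectivity.
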