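---
title: "Surrogate decomposition and stability assessment for chamber sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate decomposition and stability assessment for chamber sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberqc)
```

## The problem

Controlled-environment agriculture systems hold air temperature on a strict
day/night schedule, so a healthy sensor stream is a square-ish diurnal wave
plus sensor noise. Real streams are not healthy: microcontrollers hang,
power fails, people open the door and lean over the canopy. This package
treats departures from the regular oscillation as the diagnostic signal: it
repairs gaps, removes the oscillation, standardizes what remains, and models
how the severity of the flagged excursions relates to accumulated human
activity in the chamber.

## The model, stage by stage

**Minute grid.** All analysis happens on a complete, regular 1-minute grid
over a half-open window. Sub-minute readings (10-second cadence is typical)
are averaged per half-open minute bin `[t, t+1min)`; a minute with no
readings is *missing*, represented by an explicit mask (`NA`), never a
sentinel value. Partially-filled minutes use the mean of whatever readings
exist — the cadence sources do not state a minimum count, and discarding
partial minutes would only create more gaps for imputation to fill.
Timestamps are naive local clock time (stored as UTC-pinned POSIXct): the
chamber schedule is local and strictly diurnal, and modelling DST folds
would add failure modes the data never exhibit.

**Surrogate profile.** For one sensor and one trial, the surrogate is the
median of all non-missing observations at each of the 1440 hh:mm slots.
The median is used because single-minute spikes should not contaminate the
"ideal day"; the profile is always computed per (sensor, trial) — setpoints
differ across trials, and sensors differ in bias — and always from the raw,
pre-imputation series, so imputed values can never reinforce themselves.
Slots that have no support on any day (a daily outage at a fixed time) are
filled by circular linear interpolation across the day boundary; such slots
are identifiable by `support == 0`.

**Coalescing and the alternative decomposition.** Missing minutes are
replaced by the surrogate value at their slot. Subtracting the tiled
surrogate then de-seasonalizes the series in one step:
`r(t) = x_c(t) − s(hh:mm(t))`. There is no trend term; the additive identity
is exact at every minute, and imputed minutes have residual exactly 0 —
a deliberate property: imputation must not be able to *create* outliers.
The classical additive decomposition (centered moving average trend with
split end-weights for the even period 1440, per-slot seasonal figure
centered to zero mean, residual as remainder; numerically equivalent to
`stats::decompose`) is kept as the comparator; its trend and residual are
undefined within half a period of the edges, and those rows are dropped
before z-scoring.

**Outlier rule.** Within each sensor × trial × method residual set,
`z = (r − mean(r))/sd(r)` with the sample (n−1) standard deviation — at
n ≈ 40,000 the denominator choice is numerically irrelevant, but it must be
fixed for reproducibility. A minute is an outlier when `|z| > Φ⁻¹(1 − α/2)`;
the default α = 0.001 gives a threshold of 3.2905 (displayed as 3.29, but
never pre-rounded in computation). The strict inequality follows the rule's
primary statement; a non-strict variant is exposed because summary-table
conventions sometimes count `≥`. A degenerate residual set (sd numerically
zero, as on a noiseless simulation) is an error at the API level; the
pipeline instead reports zero outliers there, with "numerically zero"
meaning `sd ≤ 1e-9·max(1, |mean|)` so that ~1e-14 float jitter from an
otherwise exact decomposition is not standardized into fake flags.

**Distribution of severities.** Outlier `|z|` values, pooled across the
low-cost sensors and all trials (the independent reference logger is
excluded from model fitting), are fitted with six two-parameter candidates:
normal, lognormal, gamma, weibull, logistic, cauchy. Default estimation is
maximum likelihood — closed form for normal/lognormal, Nelder-Mead on
log-transformed positive parameters otherwise — because likelihood-scale
comparisons (log-likelihood, AIC = 4 − 2ℓ, BIC = 2·ln(n) − 2ℓ) are then
internally consistent and checkable against closed forms. Maximum
goodness-of-fit estimation, minimizing the Cramér–von Mises distance, is
available as `method = "mge_cvm"` for fidelity with common practice in this
domain. One honest caveat, inherited from the method itself: flagged `|z|`
values are truncated below at the threshold, yet the candidates are
*unconditional* families. No truncation correction is applied; the fitted
parameters describe the flagged sample, not a latent untruncated law.

**Cumulative operations covariate.** Door and person-presence channels are
normalized to alternating 0/1 event logs (repeated presses collapse to the
first; an unterminated presence closes at the window end). A minute's
`person_count` is the number of channels present at the minute's start on
half-open `[on, off)` intervals; the door counts if open during any part of
the minute. The covariate is the prefix sum of
`w_person·person_count + w_door·door_open` with defaults (1, 0):
person-minutes with multiplicity — three simultaneous people count
three-fold, mirroring how three bodies load the chamber climate — and the
door excluded because no source defines its weight. Both weights are
configuration, recorded in output metadata. Outlier rows join the covariate
at their own minute.

**Stability GLM.** "Regression for a log-normal distribution" is realized as
a Gaussian-family identity-link GLM on `log|z|` — consistent with the
positivity of `|z|`, with a lognormal severity distribution, and with
reported intercepts sitting on the log scale near the fitted `meanlog`. A
Gamma/log-link GLM on `|z|` is available behind `family = "gamma_log"` for
sensitivity analysis. Sensors enter with treatment coding; the baseline is
the first sensor alphabetically, stated in the fit metadata, because the
published convention leaves the baseline ambiguous. Fitting uses outlier
rows only: non-outliers are >97 % of the data and would swamp the severity
signal. Per-trial fits (plus the combined fit) drop the sensor interaction
in any fit where a sensor cell has fewer than 10 outliers, avoiding
singular designs on sparse cells; the drop is warned about, never silent.

## The simulator: what it emulates, and what it does not

`simulate_chamber()` generates, deterministically per seed: a square wave
between day and night setpoints on the trial photoperiod; first-order
exponential approach to setpoint changes with a per-sensor time constant
(so "AC delay" anomalies are representable as temporary lag increases);
per-sensor constant bias plus iid Gaussian noise; routine daily visits
(person + door events); and planted anomalies — door/occupancy temperature
bumps with matching event-log entries, linear sensor drift, one-minute
surge spikes, block power outages (masked as missing) — each labelled per
affected minute.

Defaults state the emulated world: four sequential 35-day trials at day
setpoints 30/24/28/26 °C; 16.5 h day from 06:00 / 7.5 h night; 28-day
analysis windows that drop the first (uniform-conditions) week; three
low-cost sensors (biases 1.0/−0.8/0.0 °C, noise sd 0.4 °C) plus a reference
logger (noise sd 0.15 °C); a 12-minute transition lag. Night setpoints are
not published for the source design; day − 6 °C was chosen once (it matches
the canonical day-30/night-24 example) and not revisited. Noise levels sit
at the magnitude of the published residual standard deviations; biases are
within the spread of the published per-sensor raw means.

Not emulated: real HVAC dynamics (overshoot, hysteresis), plant-canopy
feedback on the microclimate, serially correlated sensor noise, humidity or
CO₂ (irregular seasonality — excluded from the method's scope), and
multi-sensor common-mode electrical events. A green test on simulator output
therefore establishes that the *pipeline machinery* is correct under the
stated world — exact identities, calibrated flag rates, faithful recovery of
planted effects — not that any particular real chamber satisfies the model's
assumptions.

One consequence worth knowing: with a finite number of days, the per-slot
median is itself an estimate, so residuals carry a small slot-level error
and the realized false-flag rate on clean minutes runs slightly above the
nominal α (e.g. ~2–3× at 7 days, shrinking with trial length). The nominal
calibration property is exact in the iid limit and is tested there; the
end-to-end detection test asserts the rate stays within a small multiple of
α rather than at α.

## Numerical choices

* Even-count medians are the mean of the two central order statistics
  (`stats::median`).
* The critical value is carried at full precision; 3.29 is display rounding.
* The MLE for lognormal/normal uses the n-denominator (true maximum
  likelihood) standard deviation; tests check it against the closed form.
* Optimizer: Nelder-Mead, positive parameters log-transformed, reltol 1e-12,
  start values from moments; non-convergence marks the candidate failed and
  never aborts the other candidates.
* Additive identities are asserted to ≤1e-12 (float addition is not exactly
  associative); agreement with `stats::decompose` to 1e-9.
* The simulator derives one RNG substream per (trial, sensor) from the
  master seed with stable offsets, so adding a sensor never perturbs
  existing streams; all derived seeds stay below 2³¹.

## Known limitations

* The surrogate assumes the diurnal pattern is stationary within a trial;
  slow setpoint drift would leak into residuals (by design — drift *is* an
  anomaly here, not a trend to absorb).
* The alternative method has no trend component, so multi-day excursions
  appear as long runs of same-sign residuals rather than a trend estimate.
* Severity fitting ignores threshold truncation (above).
* The stability GLM treats outlier minutes as independent observations;
  clustered excursions (a door left open) violate this, and its p-values
  should be read accordingly.
* Event logs are button-based and trust the operator; the simulator models
  compliant operators only.
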