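---
title: "Measuring myosin working strokes and attachment kinetics from three-bead trap recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring myosin working strokes and attachment kinetics from three-bead trap recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trapstroke)
```

## The assay and its signals

In the three-bead (dumbbell) geometry an actin filament is stretched between
two optically trapped beads and lowered onto a myosin molecule adsorbed on a
pedestal. While the motor is detached the two beads undergo strongly
correlated Brownian motion, because the taut filament couples them; when
myosin binds, the extra stiffness clamps the dumbbell and the *covariance* of
the two bead positions drops. That covariance drop, not the displacement
itself, is the change-point observable: individual working strokes
(a few nm) are buried in thermal noise of similar magnitude, but the
covariance separates bound from unbound robustly.

Three quantities are extracted from a recording:

* **Binding events** — intervals of reduced covariance, refined to
  sub-window precision.
* **The working stroke** — from time-forward and time-reversed ensemble
  averages of event-aligned displacement: a prompt first substep `d1`
  (associated with phosphate release), a delayed second substep `d2`
  (associated with ADP release), total `d_total = d1 + d2`, and the
  exponential rates of the forward rise (`k_obs` forward, the substep-2
  transition) and of the pre-detachment rise in the reversed average
  (`k_obs` reverse, ATP-binding-limited detachment at low ATP).
* **Attachment kinetics** — dead-time-truncated single- or two-exponential
  maximum-likelihood fits to the event-duration distribution, with
  log-likelihood-ratio model selection, bootstrap confidence intervals, and
  a duty ratio `V_max / k_detach`.

## Event detection

`compute_covariance()` evaluates the sample covariance of the two bead
positions in a centered sliding window at every sample (truncated windows at
the trace edges). The default window is 30 ms; the minimum detectable event
duration — the *dead time* — is half the window, 15 ms. The window is
exposed per molecule (`covariance_window_ms`), and `auto_window = TRUE`
searches 20, 25, 30 ms for the smallest window that still separates the
peaks.

`fit_covariance_peaks()` decomposes the distribution of covariance values
into two Gaussians (EM via `mclust`; a histogram least-squares route is the
cross-check). The molecule is analyzable only when
`unbound_mean - unbound_sd > bound_mean + bound_sd`; otherwise the pipeline
refuses it, mirroring the exclusion practice for noisy molecules.

`detect_events()` requires a full excursion: from at or above the unbound
peak mean, down to at or below the bound peak mean, and back. The raw start
and end are the first crossings of the bound and unbound means.
`refine_events()` then sharpens both boundaries, because the windowed
covariance lags the true transitions: the start moves to the earliest
crossing below the halfway level near the raw start, the end to the first
crossing above 80% of the span back toward the unbound peak near the raw
end, where "near" means within min(1.5 dead times, the raw duration).
Finally starts and ends are shifted by −/+ 0.75 dead times. Events whose
refined duration falls below one dead time are excluded, as are overlapping
pairs (both dropped, conservatively).

Two edge cases are left open by the published description and are resolved
here as follows:

* **Stalled markers.** When the covariance hovers just short of a threshold,
  the raw marker can lag the true transition by several dead times, so the
  refinement's near-window opens entirely beyond its threshold. The
  implementation then walks back to the first sample of the ongoing
  beyond-threshold run (bounded look-back of four dead times), recovering
  the crossing the near-window rule intended. Without this, simulated
  recordings show a heavy late tail in detected event ends.
* **Interior recoveries.** Two attachments separated by a gap shorter than
  the averaging window never re-cross the unbound mean and would merge into
  one long "event". Events whose covariance re-crosses the 80% level
  strictly inside the refined bounds are therefore excluded
  (reason `interior_recovery`). This is an addition beyond the published
  rules, in the spirit of its false-positive minimization; simulated
  mixtures show these merged events otherwise contaminate the time-reversed
  average.

## Ensemble averaging and the working stroke

Events are aligned at refined starts (forward) or refined ends (reversed).
To average events of different lengths, each event's trace is extended
beyond its detachment (forward) or before its attachment (reversed) by a
constant boundary level.

Because the ±0.75-dead-time display shifts deliberately overshoot the bound
interval (and the 80% end-crossing itself sits past detachment for a
centered window), all boundary levels are measured at *interior anchors*
derived from the crossing rules: the attachment anchor sits
`shift = 0.75 t_d` past the refined start, the detachment anchor
`shift + (end_threshold − 0.5) · window` before the refined end. A small
guard (0.4 dead times) separates every level window from its anchor so that
detection jitter does not leak detached samples into the level estimate.

The pre-detachment level is averaged over one dead time (the displacement
there is stationary). The post-attachment level uses a short window of a
quarter dead time: the level evolves on the 1/k2 timescale, and a longer
average folds more of the second substep into the putative `d1` level. Even
so, the post-attachment window plus detection lag always contains part of
the substep-2 rise, so the measured `d2` is attenuated by roughly the
fraction of that rise completed within ~10 ms of attachment. This is a
resolution property of the method itself: at a 99 s⁻¹ forward rate and a
15 ms dead time (k2 · t_d ≈ 1.5) the substep split is semi-quantitative,
which is also why fast or small second steps are reported as
"not detected" (< 0.2 nm floor) rather than as numbers.

Boundary levels are pooled per molecule by default
(`extension_level = "molecule"`). Per-event levels correlate with event
duration through the substep clock (short events sample less of the rise),
and since an event's level enters the average exactly where that event is
extended, the correlation tilts the extension region and biases the
reversed-average rate. Pooling removes the coupling;
`extension_level = "per_event"` restores the literal per-interaction
extension.

Molecules are combined with equal weight regardless of event count. The
baseline is the minimum of the 8-ms-smoothed *ensemble* trace within
±0.2 s of the alignment point. (Applying the minimum rule to raw
single-event excerpts instead would add an extreme-value bias of the order
of the thermal SD, ~2 nm, to every total step; on the ensemble trace the
residual bias is a few hundredths of a nm at typical event counts.) The
total step is the mean over the final 20% of the 0.5 s extension span minus
that baseline; the second substep is the total minus the reversed average's
backward extension level (same baseline), so `d1 + d2 = d_total` by
construction.

## Rise-rate fits

`fit_rise()` fits `y = a + b (1 − exp(−k τ))` (forward) or
`y = a + b exp(−k |τ|)` (reversed) by Levenberg–Marquardt least squares,
with the initial rate from the half-rise time of a lightly smoothed curve
and the fit window `5 / k`, iterated to self-consistency (a fixed window
can be supplied instead). Constant series are flagged as unidentifiable
rather than fitted — single-step molecules have no forward rise to fit.

The pipeline starts the forward fit at the attachment anchor itself:
detection lags the true attachment by a couple of milliseconds on average,
so the prompt edge lies before the anchor for essentially all events, and an
exponential convolved with a fixed per-event offset keeps its rate exactly.
The reversed fit starts one dead time past the detachment anchor, clearing
the post-detachment overshoot region. Simulated recordings reveal one
further, irreducible artifact: detection is driven by the covariance of the
same thermal noise that the displacement average is built from, which
imprints a small (~0.2 nm) bump near the anchor decaying over about one
averaging window. At forward rates approaching 100 s⁻¹ this overlaps the
rise and depresses the fitted forward rate by several percent; the
recovered rates in the acceptance report should be read with that in mind.

## Attachment-duration likelihood

Durations below the dead time are excluded upstream, so the mixture density
is renormalized over the observable region:

`f(t) = Σ A_i k_i exp(−k_i t) / Σ A_i exp(−k_i t_d)`, for `t ≥ t_d`.

`fit_lifetimes()` maximizes this by bounded multi-start optimization (rates
in 10⁻³–10⁴ s⁻¹, mixture fraction in 0.01–0.99, 20 deterministic starts);
the single-exponential optimum is checked against its closed form
`k = 1 / (mean(t) − t_d)`. Components are labeled dominant-first (largest
amplitude, ties to the faster rate). `select_model()` compares orders by
`D = 2 (lnL₂ − lnL₁)` against χ² with 2 degrees of freedom at α = 0.05 —
conservative for a mixture boundary, which simulation confirms (type-I
error below α). `bootstrap_ci()` gives percentile 95% intervals from
nonparametric resampling (default 1000 resamples). Molecules enter the
pooled duration analysis only with more than 75 events.

`duty_ratio()` implements `V_max / k_detach` (time strongly bound over
cycle time). With the printed inputs this gives 5.1/54.4 = 0.094 and
5.7/69.7 = 0.082, close to but not identical with the published 0.095 and
0.078; the exact inputs behind those figures are not stated, so the
definition is implemented and the discrepancy simply noted.

## The synthetic dumbbell generator

The generator exists so that every stage can be tested by parameter
recovery. The default, phenomenological mode writes
`bead_a = c + d/2`, `bead_b = c − d/2` with `c` (common mode) and `d`
(differential mode) exactly discretized Ornstein–Uhlenbeck processes — the
AR(1) update reproduces the OU autocovariance with no step-size bias, so
stationary variances are exact at any sample rate. Attachment events arrive
as a Poisson process (arrivals during a bound interval are discarded; the
assay interrogates one molecule), shift the common-mode mean by `d1` at
attachment and by `d2` after an Exp(k2) dwell, reduce the common-mode SD
while bound, and detach after an Exp(k3) dwell, optionally drawn from a
fast/slow two-population mixture.

Defaults are physical rather than free knobs: trap stiffness 0.06 pN/nm
(midpoint of the instrument's 0.05–0.07 range), 250 nm beads, T = 293 K
(kBT = 4.045 pN nm), relaxation time γ/κ ≈ 79 µs from Stokes drag in
water, unbound common-mode SD from equipartition `sqrt(kBT / 2κ)` =
5.81 nm, bound SD from equipartition with a 2 pN/nm myosin spring
(1.38 nm), differential SD 3 nm, attachment rate 1 s⁻¹. The default sample
rate is 25 kHz — the covariance estimator's information per window is set
by the ratio of window to relaxation time, so little is lost relative to
the instrument's 250 kHz acquisition, at a tenth of the cost; the rate is a
config field.

The mechanistic mode integrates the two coupled overdamped Langevin
equations of the trap + inter-bead link (+ bound myosin spring) stiffness
network in normal modes, again with exact OU discretization. The myosin
anchor moves by `d (1 + 2κ/κ_m)` so the expected bead displacement is `d`
exactly (series-spring attenuation `κ_m / (κ_m + 2κ)` cancels by
construction); equipartition against the stiffness matrix is a test.

What the generator does **not** emulate: hydrodynamic coupling between the
beads, detector/anti-aliasing filtering, QPD calibration, position-dependent
binding (real motors bind preferentially at favorable target-zone
fluctuations, which gives the pre-attachment minimum rule its original
meaning), and slow instrumental drift. Passing recovery tests therefore
shows the pipeline implements the stated procedure faithfully under an
idealized but physically scaled noise model — not that it is robust to
every pathology of real recordings.

## Problem sizes, determinism, numerics

The recovery analyses use five molecules of roughly 100–150 events each at
25 kHz (a few minutes of CPU); duration-MLE studies use n = 5000 with 1000
bootstrap resamples; unit tests use smaller, 10 kHz versions of the same
conditions. All randomness flows from explicit integer seeds
(`withr::local_seed`), so traces, fixtures and reports are byte-reproducible.
Threshold crossings count equality as crossed and take the first sample
beyond the threshold; all event times are seconds from trace start with
half-open `[start, end)` intervals; covariance accumulations subtract global
means before forming cumulative sums to keep cancellation at the 1e−9
level.

## Known limitations

* The substep decomposition is attenuated when `1/k2` is comparable to the
  dead time (see above); `d_total` and the rise rates are the robust
  outputs.
* The forward-rate fit inherits a small negative bias from the
  detection–noise correlation artifact at fast rates.
* Event durations measured through the refinement rules overshoot the true
  bound intervals by about two dead times (the deliberate boundary shifts),
  so pipeline duration fits report the refined-duration scale; the
  standalone duration-MLE path is exact.
* The covariance-threshold detector is the published method; no
  hidden-Markov or Bayesian change-point alternatives are provided.
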