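# trapstroke

Analysis of single-molecule myosin recordings from the three-bead
("dumbbell") optical trapping assay, in R.

In this assay an actin filament is stretched between two optically trapped
beads and lowered onto a surface-bound myosin. Binding stiffens the dumbbell
and drops the covariance of the two bead position signals; the working
stroke displaces the dumbbell by a few nanometers. `trapstroke` implements
the complete measurement chain used to characterize β-cardiac myosin
working strokes and attachment kinetics:

1. **Covariance event detection** — sliding-window covariance (default
   30 ms window; dead time = half window), two-Gaussian bound/unbound peak
   decomposition with a peak-separation gate, full-excursion threshold
   detection, and two-step boundary refinement (halfway / 80% crossings,
   ∓0.75-dead-time shifts, sub-dead-time exclusion).
2. **Ensemble averaging** — time-forward and time-reversed averages of
   event-aligned displacement with boundary-level extension and equal
   molecule weighting, giving the total working stroke
   `d_total = d1 + d2`, the substeps, and single-exponential rise rates
   `y(τ) = a + b·(1 − e^(−kτ))` (forward) and `y(τ) = a + b·e^(−k|τ|)`
   (reversed).
3. **Attachment-duration MLE** — dead-time-truncated exponential mixtures
   `f(t) = Σ A_i k_i e^(−k_i t) / Σ A_i e^(−k_i t_d)`, log-likelihood-ratio
   model selection (χ², 2 df), bootstrap 95% CIs, the >75-events molecule
   filter, and the duty ratio `V_max / k_detach`.
4. **A bead-dumbbell simulator** — exactly discretized Ornstein–Uhlenbeck
   common/differential modes with stochastic attachments, one- or
   two-substep strokes, exponential dwells and optional fast/slow
   detachment mixtures (plus a mechanistic coupled-Langevin mode), with a
   ground-truth event channel so every stage is testable by parameter
   recovery.

It is aimed at single-molecule biophysicists who want a tested, scriptable
reimplementation of this analysis, and at anyone who wants to study the
estimator properties of the covariance method on synthetic data.

## Worked example

Simulate five wild-type-like molecules (two-substep stroke 3.32 + 1.09 nm,
forward rate 99.1 s⁻¹, detachment 4.59 s⁻¹ — 1 µM-ATP-like kinetics) and
run the full pipeline:

```r
library(trapstroke)

traces <- lapply(1:5, function(i) {
  simulate_dumbbell(sim_config(
    sample_rate = 25000, duration = 150, seed = 51000 + i, attach_rate = 1,
    substep1 = 3.32, substep2 = 1.09, substep2_rate = 99.1,
    detach_rate = 4.59, molecule_id = sprintf("mol%02d", i)))$trace
})
report <- run_pipeline(traces, pipeline_config())
print(report)
```

```
<run_report> 5 molecule(s), 502 events (dead time 15.0 ms)
<step_measurement> total 4.46 nm (d1 4.15, d2 0.31) | k_fwd 92.7 s^-1 | k_rev 4.75 s^-1 | 499 events / 5 molecule(s)
<lifetime_fit> single exponential: k = 3.876 s^-1 (n = 502, t_d = 0.015 s)
```

Reading the numbers: the total working stroke (4.46 nm) and both ensemble
rates recover the generating parameters (4.41 nm, 99.1 s⁻¹, 4.59 s⁻¹) to
within the estimator's Monte-Carlo spread. The substep split is
attenuated — at a 99 s⁻¹ forward rate much of the second substep completes
within the detector's dead time, so `d2` is a lower bound here (the methods
vignette quantifies this resolution limit). The pooled pipeline duration
fit reports the refined-duration scale, which overshoots true bound
intervals by about two dead times by construction.

Duration kinetics at full precision come from the standalone MLE path:

```r
d <- sample_durations(c(54.4, 7.5), c(0.97, 0.03), 5000,
                      dead_time = 0.015, seed = 7102)
fits <- fit_lifetimes(d, dead_time = 0.015)
select_model(fits$order1, fits$order2)$chosen$model_order  # 2
bootstrap_ci(d, 0.015, fits$order2, n_boot = 1000, seed = 7103)
```

```
<lifetime_fit> two exponentials: k1 = 53.58 (A = 0.968), k2 = 7.675 s^-1 (n = 5000, t_d = 0.015 s)
  95% CI k1: [51.66, 55.8]
  95% CI k2: [6.384, 9.217]
  95% CI amplitude_A: [0.9592, 0.9753]
```

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the study
end to end, writing tables and figures under `results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate_fixtures.R` | reference synthetic recordings + manifest |
| `analysis/02_detect_events.R` | covariance detection benchmarked against ground truth |
| `analysis/03_ensemble_steps.R` | working-stroke table for wild-type-like, single-step and drug-rescue conditions |
| `analysis/04_lifetimes.R` | truncated-MLE kinetics, model selection, bootstrap CIs, duty ratios |

Run them in order from the repository root with `Rscript`.

## Scope

No load/force-clamp analysis, no instrument drivers or native acquisition
formats, no hidden-Markov change-point alternatives: the package implements
the covariance-threshold method and its companion analyses, plus the
simulator needed to validate them.
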