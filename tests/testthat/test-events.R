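## Hand-constructable covariance series for the threshold-crossing logic.
cov_from_values <- function(v, dt = 1e-3, window = 0.03) {
  structure(
    list(times = (seq_along(v) - 1) * dt, values = v,
         window = window, dead_time = window / 2,
         sample_interval = dt, molecule_id = "hand"),
    class = "cov_series"
  )
}

peaks_hand <- function(bound = 0.2, unbound = 1.0, bsd = 0.05, usd = 0.1) {
  structure(
    list(bound_mean = bound, bound_sd = bsd, unbound_mean = unbound,
         unbound_sd = usd, mixture_weight = 0.5,
         separated = covariance_separated(bound, bsd, unbound, usd),
         method = "em", log_likelihood = NA, molecule_id = "hand"),
    class = "cov_peaks"
  )
}

test_that("unseparated peaks refuse analysis", {
  cv <- cov_from_values(rep(1, 100))
  pk <- peaks_hand(bound = 0.5, unbound = 0.8, bsd = 0.2, usd = 0.2)
  expect_error(detect_events(cv, pk), "not analyzable")
})

test_that("a constant unbound covariance yields no events", {
  cv <- cov_from_values(rep(1, 500))
  expect_equal(nrow(detect_events(cv, peaks_hand())), 0L)
})

test_that("a square-wave covariance yields events at the low plateaus", {
  ## 100 ms at the unbound level, 50 ms at the bound level, repeated
  v <- rep(c(rep(1.0, 100), rep(0.2, 50)), 6)
  cv <- cov_from_values(c(v, rep(1.0, 100)))
  ev <- detect_events(cv, peaks_hand())
  expect_equal(nrow(ev), 6L)
  expect_equal(ev$raw_start, 0.1 + 0.15 * (0:5), tolerance = 1e-9)
  expect_equal(ev$raw_end, 0.15 + 0.15 * (0:5), tolerance = 1e-9)
})

test_that("an excursion that never reaches the bound level is not an event", {
  v <- c(rep(1.0, 100), rep(0.55, 50), rep(1.0, 100))  # halfway only
  ev <- detect_events(cov_from_values(v), peaks_hand())
  expect_equal(nrow(ev), 0L)
})

test_that("refinement of an ideal step applies the halfway/80%/shift rules", {
  ## instant drop 1.0 -> 0.2 at t0 = 0.5 s for 200 ms; dead time 15 ms
  dt <- 1e-3
  v <- rep(1.0, 1500); v[501:700] <- 0.2
  cv <- cov_from_values(v, dt = dt, window = 0.03)
  pk <- peaks_hand()
  ev <- detect_events(cv, pk)
  expect_equal(nrow(ev), 1L)
  ref <- refine_events(cv, pk, ev)
  expect_equal(ref$refined_start, 0.5 - 0.01125, tolerance = 1e-9)
  expect_equal(ref$refined_end, 0.7 + 0.01125, tolerance = 1e-9)
  expect_equal(ref$duration, 0.2225, tolerance = 1e-9)

  ## idempotence: refining the refined bounds changes nothing
  ev2 <- ref
  ev2$raw_start <- ref$refined_start; ev2$raw_end <- ref$refined_end
  ev2$raw_start_idx <- round(ev2$raw_start / dt) + 1L
  ev2$raw_end_idx <- round(ev2$raw_end / dt) + 1L
  ref2 <- refine_events(cv, pk, ev2)
  expect_equal(ref2$refined_start, ref$refined_start, tolerance = 1e-9)
  expect_equal(ref2$refined_end, ref$refined_end, tolerance = 1e-9)
})

test_that("events shorter than the dead time are excluded", {
  dt <- 1e-3
  v <- rep(1.0, 1000); v[501:510] <- 0.2       # 10 ms plateau < 15 ms dead time
  cv <- cov_from_values(v, dt = dt, window = 0.03)
  pk <- peaks_hand()
  ## without the display shifts the refined duration equals the 10 ms
  ## plateau, which is below the 15 ms dead time
  ref <- refine_events(cv, pk, detect_events(cv, pk),
                       shift_fraction_of_dead_time = 0)
  expect_equal(nrow(ref), 0L)
  expect_true(all(attr(ref, "excluded")$reason == "shorter_than_dead_time"))
})

test_that("refined durations never fall below the dead time", {
  sim <- wt_molecule()
  m <- analyze_molecule(sim$trace, pipeline_config(min_events_per_molecule = 10L))
  expect_true(all(m$events$duration >= m$cov$dead_time))
})

test_that("detection achieves high recall and a low false-positive rate", {
  sim <- wt_molecule()
  cov <- compute_covariance(sim$trace, 0.03)
  pk <- fit_covariance_peaks(cov)
  expect_true(pk$separated)
  ev <- refine_events(cov, pk, detect_events(cov, pk))
  stats <- match_events_to_truth(ev, sim$truth,
                                 min_true_duration = 2 * cov$dead_time)
  expect_gte(stats$recall, 0.95)
  expect_lte(stats$false_positive_rate, 0.05)
})

test_that("detected event lists are sorted and non-overlapping", {
  sim <- wt_molecule()
  m <- analyze_molecule(sim$trace, pipeline_config(min_events_per_molecule = 10L))
  ev <- m$events
  expect_true(all(diff(ev$refined_start) > 0))
  expect_true(all(ev$refined_start[-1] >= ev$refined_end[-nrow(ev)]))
})
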