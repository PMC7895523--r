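td0 <- 0.015  # dead time used for hand-built event tables

test_that("event_displacement returns the chosen signal over the padded window", {
  tr <- ideal_trace(2, 1000, list(list(start = 0.5, end = 1.0, level = 4.4)))
  ev <- event_table(0.5, 1.0, td0)
  d <- event_displacement(tr, ev[1, ], pad = 0.1)
  expect_equal(range(d$time), c(0.4, 1.1), tolerance = 1e-9)
  expect_equal(max(d$displacement), 4.4)
  ## identical beads: any signal choice gives the same series
  expect_equal(event_displacement(tr, ev[1, ], pad = 0.1,
                                  signal = "bead_a")$displacement,
               d$displacement)
  ## sign flag is an exact involution
  expect_equal(event_displacement(tr, ev[1, ], pad = 0.1, sign = -1)$displacement,
               -d$displacement)
  ## pad beyond the trace is truncated and flagged
  d2 <- event_displacement(tr, ev[1, ], pad = 1)
  expect_true(attr(d2, "truncated"))
})

test_that("forward extension averages two clean plateaus to their mean", {
  tr <- ideal_trace(6, 1000, list(
    list(start = 1.0, end = 1.4, level = 1),
    list(start = 3.0, end = 3.4, level = 3)))
  ev <- event_table(c(1.0, 3.0), c(1.4, 3.4), td0)
  fwd <- forward_average(tr, ev, extension_span = 0.5, pre_span = 0.2)
  plateau <- fwd$mean_displacement[fwd$tau > 0.42]
  expect_equal(mean(plateau), 2, tolerance = 1e-6)
})

test_that("a single event averages to its own extended displacement", {
  tr <- ideal_trace(4, 1000, list(list(start = 1.0, end = 1.5, level = 2.5)))
  ev <- event_table(1.0, 1.5, td0)
  fwd <- forward_average(tr, ev, extension_span = 0.5, pre_span = 0.2)
  expect_equal(fwd$n_events, 1L)
  expect_equal(fwd$mean_displacement[fwd$tau > 0.46], rep(2.5, sum(fwd$tau > 0.46)))
})

test_that("single-step events give equal forward plateau and reverse extension level", {
  tr <- ideal_trace(8, 1000, lapply(seq(1, 7, by = 1.5), function(s)
    list(start = s, end = s + 0.2, level = 1.3)))
  ev <- event_table(seq(1, 7, by = 1.5), seq(1, 7, by = 1.5) + 0.2, td0)
  fwd <- forward_average(tr, ev, extension_span = 0.5, pre_span = 0.2)
  rev <- reverse_average(tr, ev, extension_span = 0.5, post_span = 0.2)
  f_plateau <- mean(fwd$mean_displacement[fwd$tau > 0.4])
  r_level <- mean(rev$mean_displacement[rev$tau < -0.4])
  expect_equal(f_plateau, r_level, tolerance = 1e-6)
  expect_equal(f_plateau, 1.3, tolerance = 1e-6)
})

test_that("two-substep ideal events show the pre-detachment rise in reverse", {
  ## level 3.32 shortly after attach, 4.41 until detach; events short enough
  ## that the far-back region is backward extension at the post-attach level
  evs <- lapply(seq(1, 19, by = 2), function(s)
    list(start = s, end = s + 0.3, level = 3.32, t2 = s + 0.05, level2 = 4.41))
  tr <- ideal_trace(21, 1000, evs)
  ev <- event_table(seq(1, 19, by = 2), seq(1, 19, by = 2) + 0.3, td0)
  rev <- reverse_average(tr, ev, extension_span = 0.9, post_span = 0.1)
  near_end <- mean(rev$mean_displacement[rev$tau > -0.1 & rev$tau < -0.05])
  far_back <- mean(rev$mean_displacement[rev$tau < -0.85])
  expect_equal(near_end, 4.41, tolerance = 0.01)
  expect_equal(far_back, 3.32, tolerance = 0.01)
})

test_that("molecules combine with equal weight regardless of event counts", {
  mk <- function(plateau, n_ev, id) {
    structure(list(alignment = "forward", tau = seq(0, 1, by = 0.01),
                   mean_displacement = rep(plateau, 101), n_events = n_ev,
                   n_molecules = 1L, extension_span = 1, dead_time = td0,
                   molecule_id = id), class = "ensemble_average")
  }
  a <- mk(2, 10L, "a"); b <- mk(4, 1000L, "b")
  comb <- combine_molecules(list(a, b))
  expect_equal(unique(comb$mean_displacement), 3)   # not the pooled 3.98
  expect_equal(comb$n_events, 1010L)
  expect_equal(comb$n_molecules, 2L)
  ## permutation invariance and single-molecule identity
  expect_equal(combine_molecules(list(b, a))$mean_displacement,
               comb$mean_displacement)
  expect_equal(combine_molecules(list(a))$mean_displacement,
               a$mean_displacement)
  ## mixed alignments refuse
  r <- mk(2, 10L, "r"); r$alignment <- "reverse"
  expect_error(combine_molecules(list(a, r)), "alignment")
})

test_that("total step measurement subtracts the pre-attachment baseline", {
  evs <- lapply(seq(1, 9, by = 2), function(s)
    list(start = s, end = s + 0.3, level = 4.41))
  tr <- ideal_trace(11, 1000, evs, baseline = 0)
  ev <- event_table(seq(1, 9, by = 2), seq(1, 9, by = 2) + 0.3, td0)
  fwd <- forward_average(tr, ev, extension_span = 0.5, pre_span = 0.25)
  st <- measure_total_step(fwd)
  expect_equal(st$d_total, 4.41, tolerance = 1e-6)
  expect_equal(st$baseline, 0, tolerance = 1e-6)

  ## a constant offset on the whole trace leaves the step unchanged
  tr2 <- trap_trace(tr$bead_a + 5, tr$bead_b + 5, tr$sample_interval,
                    molecule_id = "off")
  fwd2 <- forward_average(tr2, ev, extension_span = 0.5, pre_span = 0.25)
  expect_equal(measure_total_step(fwd2)$d_total, 4.41, tolerance = 1e-6)

  ## a flat trace has zero step
  trf <- trap_trace(rep(1, 11000), rep(1, 11000), 1e-3, molecule_id = "flat")
  fwdf <- forward_average(trf, ev, extension_span = 0.5, pre_span = 0.25)
  expect_equal(measure_total_step(fwdf)$d_total, 0, tolerance = 1e-9)
})

test_that("substep decomposition follows the reverse extension level", {
  mk_rev <- function(level) {
    structure(list(alignment = "reverse", tau = seq(-0.5, 0, by = 0.001),
                   mean_displacement = rep(level, 501), n_events = 10L,
                   n_molecules = 1L, extension_span = 0.5, dead_time = td0,
                   molecule_id = "r"), class = "ensemble_average")
  }
  s <- measure_substeps(mk_rev(3.32), d_total = 4.41, baseline = 0)
  expect_equal(s$d2, 1.09, tolerance = 1e-9)
  expect_equal(s$d1, 3.32, tolerance = 1e-9)
  expect_equal(s$d1 + s$d2, 4.41)
  expect_true(s$d2_detected)

  ## extension level equal to the total: d2 exactly zero, below the floor
  s0 <- measure_substeps(mk_rev(4.41), d_total = 4.41, baseline = 0)
  expect_equal(s0$d2, 0)
  expect_false(s0$d2_detected)

  ## magnitude below the 0.2 nm floor reported as not detected
  s1 <- measure_substeps(mk_rev(4.30), d_total = 4.41, baseline = 0)
  expect_false(s1$d2_detected)
})

test_that("rise fits recover noiseless exponentials to high precision", {
  tau <- seq(0, 0.25, by = 1e-4)
  fwd <- structure(list(alignment = "forward", tau = tau,
                        mean_displacement = 3.32 + 1.09 * (1 - exp(-99.1 * tau)),
                        n_events = 1L, n_molecules = 1L, extension_span = 0.25,
                        dead_time = td0, molecule_id = "f"),
                   class = "ensemble_average")
  f <- fit_rise(fwd)
  expect_false(f$flagged)
  expect_equal(f$k, 99.1, tolerance = 1e-6)
  expect_equal(f$b, 1.09, tolerance = 1e-6)

  tau_r <- seq(-1.5, 0, by = 1e-3)
  rev <- structure(list(alignment = "reverse", tau = tau_r,
                        mean_displacement = 3.32 + 1.09 * exp(-4.59 * abs(tau_r)),
                        n_events = 1L, n_molecules = 1L, extension_span = 1.5,
                        dead_time = td0, molecule_id = "r"),
                   class = "ensemble_average")
  r <- fit_rise(rev)
  expect_equal(r$k, 4.59, tolerance = 1e-6)

  ## a shifted fit origin changes amplitude, not the rate
  f2 <- fit_rise(fwd, t0 = 0.01)
  expect_equal(f2$k, 99.1, tolerance = 1e-5)
})

test_that("a constant series is flagged as unidentifiable", {
  flat <- structure(list(alignment = "forward", tau = seq(0, 0.5, by = 1e-3),
                         mean_displacement = rep(2, 501), n_events = 1L,
                         n_molecules = 1L, extension_span = 0.5,
                         dead_time = td0, molecule_id = "c"),
                    class = "ensemble_average")
  expect_true(fit_rise(flat)$flagged)
})

test_that("the pipeline recovers generator parameters on moderate kinetics", {
  sims <- moderate_sim()
  ## extension span long enough for the 3 s^-1 reverse decay to converge
  cfg <- pipeline_config(extension_span_s = 1.2)
  per <- lapply(sims, function(s) analyze_molecule(s$trace, cfg))
  expect_true(all(!vapply(per, function(m) is.null(m$steps), TRUE)))
  n_ev <- sum(vapply(per, `[[`, 0L, "n_events"))
  expect_gte(n_ev, 500L)

  fwd <- combine_molecules(lapply(per, `[[`, "forward"))
  rev <- combine_molecules(lapply(per, `[[`, "reverse"))
  steps <- measure_steps(fwd, rev, cfg)

  ## d1 + d2 = d_total holds exactly by construction
  expect_equal(steps$d1 + steps$d2, steps$d_total, tolerance = 1e-12)

  ## recovery within 3 Monte-Carlo SEs (across-molecule spread / sqrt(5))
  per_tot <- vapply(per, function(m) m$steps$d_total, 0)
  se_tot <- sd(per_tot) / sqrt(length(per_tot))
  expect_lt(abs(steps$d_total - 4.0), 3 * se_tot + 0.1)

  per_kf <- vapply(per, function(m) m$steps$k_forward, 0)
  se_kf <- sd(per_kf) / sqrt(length(per_kf))
  expect_lt(abs(steps$k_forward - 25), 3 * se_kf + 0.1 * 25)

  per_kr <- vapply(per, function(m) m$steps$k_reverse, 0)
  se_kr <- sd(per_kr) / sqrt(length(per_kr))
  expect_lt(abs(steps$k_reverse - 3), 3 * se_kr + 0.1 * 3)

  ## The substep split carries a predictable attenuation: the post-attach
  ## level window (which defines the reverse extension) already contains
  ## 1 - exp(-k2 t) of the second substep, so the measured d2 is bounded by
  ## the true amplitude and must exceed the attenuation floor.
  expect_true(steps$d2_detected)
  expect_gt(steps$d2, 0.5 * 1.5)
  expect_lt(steps$d2, 1.1 * 1.5)
})

test_that("combined averages are invariant to molecule order", {
  sims <- moderate_sim()[1:3]
  cfg <- pipeline_config()
  per <- lapply(sims, function(s) analyze_molecule(s$trace, cfg))
  fwd_ab <- combine_molecules(lapply(per, `[[`, "forward"))
  fwd_ba <- combine_molecules(lapply(rev(per), `[[`, "forward"))
  expect_equal(fwd_ab$mean_displacement, fwd_ba$mean_displacement)
})
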