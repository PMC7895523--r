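test_that("config validation rejects nonphysical parameters", {
  expect_error(sim_config(sample_rate = 0), "sample_rate")
  expect_error(sim_config(detach_rate = -1), "detach_rate")
  expect_error(sim_config(slow_population_fraction = 1.5), "slow_population_fraction")
  expect_error(sim_config(trap_stiffness = NaN), "trap_stiffness")
})

test_that("defaults encode the physical constants of the dumbbell", {
  cfg <- sim_config()
  expect_equal(thermal_energy(293), 4.045, tolerance = 1e-3)
  expect_equal(cfg$unbound_common_sd, sqrt(4.045 / 0.12), tolerance = 1e-3)
  ## tau_c = gamma / kappa with Stokes drag of a 250 nm bead in water
  expect_equal(cfg$common_mode_relax_time,
               stokes_drag(250) / 0.06, tolerance = 1e-9)
})

test_that("with no attachments the trace is a stationary OU pair", {
  cfg <- sim_config(attach_rate = 0, duration = 40, sample_rate = 10000,
                    seed = 5)
  sim <- simulate_dumbbell(cfg)
  expect_equal(nrow(sim$truth), 0L)
  cm <- (sim$trace$bead_a + sim$trace$bead_b) / 2
  ## stationary variance of the common mode within sampling error
  n_eff <- length(cm) * tanh(5e-5 / cfg$common_mode_relax_time)
  se <- cfg$unbound_common_sd^2 * sqrt(2 / n_eff)
  expect_lt(abs(var(cm) - cfg$unbound_common_sd^2), 4 * se)
})

test_that("OU discretization is exact: variance and autocovariance", {
  ## coarse sampling is the regime where naive Euler schemes go wrong
  for (dt_fac in c(0.25, 2)) {
    cfg <- sim_config(attach_rate = 0, duration = 30,
                      sample_rate = 1 / (dt_fac * 7.87e-5), seed = 11)
    sim <- simulate_dumbbell(cfg)
    cm <- (sim$trace$bead_a + sim$trace$bead_b) / 2
    tau <- cfg$common_mode_relax_time
    v <- cfg$unbound_common_sd^2
    ac1 <- mean(cm[-1] * cm[-length(cm)])
    expect_equal(var(cm), v, tolerance = 0.05)
    expect_equal(ac1, v * exp(-sim$trace$sample_interval / tau),
                 tolerance = 0.08)
  }
})

test_that("applied shifts match the configured substep amplitudes", {
  cfg <- sim_config(duration = 30, seed = 2, substep1 = 3.3, substep2 = 1.1,
                    sample_rate = 2000, attach_rate = 2)
  sim <- simulate_dumbbell(cfg)
  expect_gt(nrow(sim$truth), 5)
  expect_true(all(sim$truth$applied_shift_1 == 3.3))
  expect_true(all(sim$truth$applied_shift_2 == 1.1))
  expect_true(all(sim$truth$applied_shift_1 + sim$truth$applied_shift_2 == 4.4))
  with(sim$truth, {
    expect_true(all(attach_time < substep2_time))
    expect_true(all(substep2_time < detach_time))
  })
})

test_that("single-step mode has no substep-2 times and zero second shift", {
  sim <- simulate_dumbbell(sim_config(duration = 30, seed = 3, substep2 = 0,
                                      sample_rate = 2000, attach_rate = 2))
  expect_gt(nrow(sim$truth), 5)
  expect_true(all(is.na(sim$truth$substep2_time)))
  expect_true(all(sim$truth$applied_shift_2 == 0))
})

test_that("ground-truth dwells are exponential (KS test at alpha = 0.01)", {
  cfg <- sim_config(duration = 1100, sample_rate = 1000, seed = 8,
                    attach_rate = 20, substep2_rate = 200, detach_rate = 20)
  sim <- simulate_dumbbell(cfg)
  dwell <- sim$truth$detach_time - sim$truth$substep2_time
  expect_gt(length(dwell), 5000)
  expect_gt(suppressWarnings(ks.test(dwell, "pexp", 20))$p.value, 0.01)
  s2 <- sim$truth$substep2_time - sim$truth$attach_time
  expect_gt(suppressWarnings(ks.test(s2, "pexp", 200))$p.value, 0.01)
})

test_that("bound intervals reduce the windowed covariance", {
  sim <- wt_molecule()
  cov <- compute_covariance(sim$trace, 0.03)
  tt <- cov$times
  bound <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(sim$truth))) {
    bound[tt >= sim$truth$attach_time[i] & tt < sim$truth$detach_time[i]] <- TRUE
  }
  expect_lt(mean(cov$values[bound]), mean(cov$values[!bound]))
})

test_that("mechanistic mode satisfies equipartition", {
  cfg <- sim_config(mode = "mechanistic", attach_rate = 0, duration = 25,
                    sample_rate = 50000, seed = 13)
  sim <- simulate_dumbbell(cfg)
  expect_gte(length(sim$trace$bead_a), 1e6)
  kbt <- thermal_energy(cfg$temperature)
  ## var(bead) = var(common) + var(diff)/4 from the stiffness matrix
  v_th <- kbt / (2 * cfg$trap_stiffness) +
    0.25 * 2 * kbt / (cfg$trap_stiffness + 2 * cfg$link_stiffness)
  expect_equal(var(sim$trace$bead_a), v_th, tolerance = 0.05)
  expect_equal(var(sim$trace$bead_b), v_th, tolerance = 0.05)
})

test_that("mechanistic anchor calibration reproduces the intended displacement", {
  ## closed form: a stiff myosin spring anchored at d (1 + 2 kappa / kappa_m)
  ## displaces the dumbbell by exactly d through series-spring attenuation
  cfg <- sim_config(mode = "mechanistic", duration = 60, sample_rate = 10000,
                    seed = 14, attach_rate = 5, detach_rate = 0.5,
                    substep2_rate = 500, myosin_stiffness = 6)
  sim <- simulate_dumbbell(cfg)
  tt <- trace_times(sim$trace)
  disp <- (sim$trace$bead_a + sim$trace$bead_b) / 2
  bound <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(sim$truth))) {
    bound[tt >= sim$truth$substep2_time[i] + 0.01 &
            tt < sim$truth$detach_time[i]] <- TRUE
  }
  expect_gt(sum(bound), 1e5)
  expect_equal(mean(disp[bound]), cfg$substep1 + cfg$substep2,
               tolerance = 0.02)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_dumbbell(sim_config(duration = 5, seed = 21, sample_rate = 5000))
  b <- simulate_dumbbell(sim_config(duration = 5, seed = 21, sample_rate = 5000))
  expect_identical(a$trace$bead_a, b$trace$bead_a)
  expect_identical(a$truth, b$truth)
})

test_that("sample_durations draws the truncated mixture correctly", {
  expect_error(sample_durations(numeric(0), 1, 10), "non-empty")
  expect_error(sample_durations(c(1, 2), c(0.6, 0.5), 10), "sum to 1")
  expect_error(sample_durations(c(1, -2), c(0.5, 0.5), 10), "> 0")

  ## untruncated exponential mean
  d0 <- sample_durations(10, 1, 2e4, dead_time = 0, seed = 1)
  expect_equal(mean(d0), 0.1, tolerance = 0.03)

  ## memorylessness: truncation shifts the mean by the dead time
  d1 <- sample_durations(10, 1, 1e4, dead_time = 0.1, seed = 2)
  expect_true(all(d1 >= 0.1))
  expect_equal(mean(d1), 0.2, tolerance = 0.03)

  ## mixture truncation keeps every sample above the dead time
  d2 <- sample_durations(c(54.4, 7.5), c(0.97, 0.03), 5000,
                         dead_time = 0.015, seed = 3)
  expect_true(all(d2 >= 0.015))

  ## deterministic given seed
  expect_identical(sample_durations(5, 1, 100, seed = 9),
                   sample_durations(5, 1, 100, seed = 9))
})
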