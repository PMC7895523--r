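#' Simulation configuration for the bead-actin-bead dumbbell generator
#'
#' Collects every knob of the synthetic two-bead generator. Defaults describe a
#' wild-type-like human beta-cardiac myosin molecule at 1 uM MgATP held in two
#' 0.06 pN nm^-1 traps: a two-substep working stroke (3.32 nm followed by
#' 1.09 nm), a 99.1 s^-1 transition to the second substep, and a 4.59 s^-1
#' detachment rate from the post-substep state.
#'
#' Two generative modes are available. The default `"phenomenological"` mode
#' writes the bead pair as `bead_a = c + d/2`, `bead_b = c - d/2` where `c`
#' (common mode) and `d` (differential mode) are exactly discretized
#' Ornstein-Uhlenbeck processes; myosin binding reduces the common-mode
#' standard deviation from `unbound_common_sd` to `bound_common_sd` and shifts
#' the common-mode mean by the working-stroke substeps. The `"mechanistic"`
#' mode integrates the two coupled overdamped Langevin equations of the
#' trap + inter-bead link (+ bound myosin spring) stiffness network; the myosin
#' anchor is moved by `d * (1 + 2 * trap_stiffness / myosin_stiffness)` so the
#' expected bead displacement equals `d` exactly.
#'
#' @param sample_rate Acquisition rate in Hz.
#' @param duration Trace length in seconds.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param temperature Temperature in K.
#' @param trap_stiffness Stiffness of each trap, pN nm^-1.
#' @param bead_radius Bead radius in nm (drag via Stokes' law).
#' @param common_mode_relax_time Relaxation time of the common mode in s;
#'   `NULL` computes `gamma / trap_stiffness` from Stokes drag in water.
#' @param unbound_common_sd,bound_common_sd Stationary SD (nm) of the common
#'   mode while myosin is detached / attached. `NULL` computes the
#'   equipartition values `sqrt(kB T / (2 kappa))` (unbound) and
#'   `sqrt(kB T / (2 kappa + kappa_m))` (bound: the attached myosin spring
#'   stiffens the dumbbell).
#' @param differential_sd Stationary SD (nm) of the differential mode.
#' @param attach_rate Poisson attachment rate lambda, s^-1 (arrivals during a
#'   bound interval are discarded; the assay interrogates one molecule).
#' @param substep1,substep2 Working-stroke substep amplitudes d1, d2 in nm;
#'   `substep2 = 0` selects single-step mode.
#' @param substep2_rate Rate k2 (s^-1) of the exponential dwell between
#'   attachment and the second substep.
#' @param detach_rate Rate k3 (s^-1) of the exponential dwell between the
#'   second substep (or attachment, in single-step mode) and detachment.
#' @param slow_population_fraction Fraction of events drawing their detachment
#'   rate from a second, slow population.
#' @param slow_detach_rate Detachment rate (s^-1) of the slow population.
#' @param mode `"phenomenological"` or `"mechanistic"`.
#' @param myosin_stiffness Myosin spring stiffness kappa_m (pN nm^-1),
#'   mechanistic mode only.
#' @param link_stiffness Bead-bead (actin tether) stiffness (pN nm^-1),
#'   mechanistic mode only.
#' @param molecule_id,condition Metadata copied into the trace.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sample_rate = 25000,
                       duration = 20,
                       seed = 1L,
                       temperature = 293,
                       trap_stiffness = 0.06,
                       bead_radius = 250,
                       common_mode_relax_time = NULL,
                       unbound_common_sd = NULL,
                       bound_common_sd = NULL,
                       differential_sd = 3.0,
                       attach_rate = 2,
                       substep1 = 3.32,
                       substep2 = 1.09,
                       substep2_rate = 99.1,
                       detach_rate = 4.59,
                       slow_population_fraction = 0,
                       slow_detach_rate = 1,
                       mode = c("phenomenological", "mechanistic"),
                       myosin_stiffness = 2,
                       link_stiffness = 0.5,
                       molecule_id = "sim",
                       condition = "synthetic") {
  mode <- match.arg(mode)
  .check_scalar(sample_rate, "sample_rate", min = 0, strict_min = TRUE)
  .check_scalar(duration, "duration", min = 0, strict_min = TRUE)
  .check_scalar(temperature, "temperature", min = 0, strict_min = TRUE)
  .check_scalar(trap_stiffness, "trap_stiffness", min = 0, strict_min = TRUE)
  .check_scalar(bead_radius, "bead_radius", min = 0, strict_min = TRUE)
  kbt <- thermal_energy(temperature)
  if (is.null(common_mode_relax_time)) {
    common_mode_relax_time <- stokes_drag(bead_radius) / trap_stiffness
  }
  if (is.null(unbound_common_sd)) {
    unbound_common_sd <- sqrt(kbt / (2 * trap_stiffness))
  }
  if (is.null(bound_common_sd)) {
    bound_common_sd <- sqrt(kbt / (2 * trap_stiffness + myosin_stiffness))
  }
  .check_scalar(common_mode_relax_time, "common_mode_relax_time",
                min = 0, strict_min = TRUE)
  for (nm in c("unbound_common_sd", "bound_common_sd", "differential_sd",
               "attach_rate", "substep2_rate", "detach_rate",
               "slow_detach_rate", "myosin_stiffness", "link_stiffness")) {
    .check_scalar(get(nm), nm, min = 0)
  }
  .check_scalar(slow_population_fraction, "slow_population_fraction",
                min = 0, max = 1)
  if (!is.numeric(substep1) || !is.finite(substep1) ||
      !is.numeric(substep2) || !is.finite(substep2)) {
    stop("substep amplitudes must be finite", call. = FALSE)
  }
  cfg <- list(
    sample_rate = sample_rate, duration = duration, seed = as.integer(seed),
    temperature = temperature, trap_stiffness = trap_stiffness,
    bead_radius = bead_radius,
    common_mode_relax_time = common_mode_relax_time,
    unbound_common_sd = unbound_common_sd,
    bound_common_sd = bound_common_sd,
    differential_sd = differential_sd,
    attach_rate = attach_rate,
    substep1 = substep1, substep2 = substep2,
    substep2_rate = substep2_rate, detach_rate = detach_rate,
    slow_population_fraction = slow_population_fraction,
    slow_detach_rate = slow_detach_rate,
    mode = mode, myosin_stiffness = myosin_stiffness,
    link_stiffness = link_stiffness,
    molecule_id = molecule_id, condition = condition
  )
  structure(cfg, class = "sim_config")
}

## Draw the ground-truth event schedule: Poisson arrivals, exponential dwells,
## arrivals during a bound interval discarded. Events whose detachment falls
## beyond the trace are dropped.
.draw_event_schedule <- function(config) {
  single_step <- config$substep2 == 0
  attach <- numeric(0); sub2 <- numeric(0); detach <- numeric(0)
  k3 <- numeric(0)
  t <- 0
  if (config$attach_rate > 0) {
    repeat {
      t_attach <- t + stats::rexp(1, config$attach_rate)
      if (t_attach >= config$duration) break
      slow <- config$slow_population_fraction > 0 &&
        stats::runif(1) < config$slow_population_fraction
      k_det <- if (slow) config$slow_detach_rate else config$detach_rate
      if (single_step) {
        t_sub2 <- NA_real_
        t_detach <- t_attach + stats::rexp(1, k_det)
      } else {
        t_sub2 <- t_attach + stats::rexp(1, config$substep2_rate)
        t_detach <- t_sub2 + stats::rexp(1, k_det)
      }
      if (t_detach >= config$duration) break
      attach <- c(attach, t_attach); sub2 <- c(sub2, t_sub2)
      detach <- c(detach, t_detach); k3 <- c(k3, k_det)
      t <- t_detach
    }
  }
  data.frame(
    event_index = seq_along(attach),
    attach_time = attach, substep2_time = sub2, detach_time = detach,
    applied_shift_1 = rep(config$substep1, length(attach)),
    applied_shift_2 = rep(config$substep2, length(attach)),
    detach_rate_drawn = k3
  )
}

## Exact piecewise-stationary OU discretization. segments: data.frame with
## columns from, to (sample indices), tau, sd, mean. The AR(1) update
## x[i] = m + phi (x[i-1] - m) + sd sqrt(1-phi^2) z reproduces the OU
## autocovariance sd^2 exp(-dt/tau) with no step-size bias.
.ou_piecewise <- function(segments, dt, init) {
  n_total <- segments$to[nrow(segments)]
  out <- numeric(n_total)
  prev <- init
  for (s in seq_len(nrow(segments))) {
    idx <- segments$from[s]:segments$to[s]
    phi <- exp(-dt / segments$tau[s])
    innov <- (1 - phi) * segments$mean[s] +
      segments$sd[s] * sqrt(1 - phi^2) * stats::rnorm(length(idx))
    out[idx] <- stats::filter(innov, phi, method = "recursive",
                              init = prev)
    prev <- out[idx[length(idx)]]
  }
  out
}

## Split [1, n] into alternating unbound/bound(pre-sub2)/bound(post-sub2)
## segments from the event schedule; returns data.frame(from, to, state)
## with state 0 = unbound, 1 = bound pre-substep-2, 2 = bound post-substep-2.
.event_segments <- function(truth, n, sample_rate) {
  bounds <- 1L
  states <- integer(0)
  to_idx <- function(t) pmin(pmax(1L, as.integer(floor(t * sample_rate)) + 1L), n)
  cur <- 1L
  from <- integer(0); to <- integer(0); state <- integer(0)
  add <- function(a, b, s) {
    if (b >= a) {
      from <<- c(from, a); to <<- c(to, b); state <<- c(state, s)
    }
  }
  if (nrow(truth) > 0) {
    for (i in seq_len(nrow(truth))) {
      ia <- to_idx(truth$attach_time[i])
      id <- to_idx(truth$detach_time[i])
      add(cur, ia - 1L, 0L)
      if (is.na(truth$substep2_time[i])) {
        add(ia, id - 1L, 1L)
      } else {
        is2 <- to_idx(truth$substep2_time[i])
        add(ia, is2 - 1L, 1L)
        add(is2, id - 1L, 2L)
      }
      cur <- id
    }
  }
  add(cur, n, 0L)
  data.frame(from = from, to = to, state = state)
}

#' Simulate a two-bead dumbbell trace with known attachment events
#'
#' Generates synchronized bead positions for the three-bead assay together
#' with the ground-truth event list (attachment, second-substep and
#' detachment times, applied shifts), so detection, ensemble averaging and
#' lifetime fitting can all be benchmarked by parameter recovery.
#'
#' @param config A [sim_config()].
#' @return A list with elements `trace` (a [trap_trace()]) and `truth`
#'   (data.frame of ground-truth events).
#' @export
simulate_dumbbell <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config")
  withr::local_seed(config$seed)
  n <- as.integer(round(config$duration * config$sample_rate))
  if (n < 2L) stop("duration too short for the sample rate")
  dt <- 1 / config$sample_rate

  truth <- .draw_event_schedule(config)
  seg <- .event_segments(truth, n, config$sample_rate)

  if (config$mode == "phenomenological") {
    mean_c <- c(0, config$substep1, config$substep1 + config$substep2)[seg$state + 1L]
    sd_c <- ifelse(seg$state == 0L, config$unbound_common_sd,
                   config$bound_common_sd)
    seg_c <- data.frame(from = seg$from, to = seg$to,
                        tau = config$common_mode_relax_time,
                        sd = sd_c, mean = mean_c)
    cm <- .ou_piecewise(seg_c, dt,
                        init = stats::rnorm(1, 0, config$unbound_common_sd))
    seg_d <- data.frame(from = 1L, to = n,
                        tau = config$common_mode_relax_time,
                        sd = config$differential_sd, mean = 0)
    dm <- .ou_piecewise(seg_d, dt,
                        init = stats::rnorm(1, 0, config$differential_sd))
  } else {
    kbt <- thermal_energy(config$temperature)
    gam <- stokes_drag(config$bead_radius)
    kap <- config$trap_stiffness
    km <- config$myosin_stiffness
    kl <- config$link_stiffness
    ## normal modes: c = (xa+xb)/2 (drag 2 gamma, stiffness 2 kap [+ km]),
    ## u = xa - xb (drag gamma/2, stiffness kap/2 + kl)
    k_c <- 2 * kap + ifelse(seg$state == 0L, 0, km)
    ## anchor calibrated so the expected common-mode shift equals d exactly
    target <- c(0, config$substep1, config$substep1 + config$substep2)[seg$state + 1L]
    mean_c <- ifelse(seg$state == 0L, 0, km * (target * (1 + 2 * kap / km)) / k_c)
    seg_c <- data.frame(from = seg$from, to = seg$to,
                        tau = 2 * gam / k_c,
                        sd = sqrt(kbt / k_c), mean = mean_c)
    cm <- .ou_piecewise(seg_c, dt, init = stats::rnorm(1, 0, sqrt(kbt / (2 * kap))))
    k_u <- kap / 2 + kl
    seg_d <- data.frame(from = 1L, to = n,
                        tau = (gam / 2) / k_u,
                        sd = sqrt(kbt / k_u), mean = 0)
    dm <- .ou_piecewise(seg_d, dt, init = stats::rnorm(1, 0, sqrt(kbt / k_u)))
  }

  trace <- trap_trace(
    bead_a = cm + dm / 2, bead_b = cm - dm / 2,
    sample_interval = dt,
    trap_stiffness_a = config$trap_stiffness,
    trap_stiffness_b = config$trap_stiffness,
    molecule_id = config$molecule_id,
    condition = config$condition,
    source = "simulated"
  )
  list(trace = trace, truth = truth)
}

#' Sample attachment durations from a dead-time-truncated exponential mixture
#'
#' Draws `n` durations from `sum_i A_i k_i exp(-k_i t)` conditioned on
#' exceeding the instrument dead time, by draw-and-reject. Used to exercise
#' the lifetime MLE with known generating parameters.
#'
#' @param rates Component rates in s^-1 (all > 0).
#' @param amplitudes Component fractions summing to 1.
#' @param n Number of durations.
#' @param dead_time Minimum observable duration in s.
#' @param seed Integer seed.
#' @return Numeric vector of `n` durations, all `>= dead_time`.
#' @export
sample_durations <- function(rates, amplitudes = 1, n, dead_time = 0, seed = 1L) {
  if (length(rates) == 0) stop("'rates' must be non-empty")
  if (any(!is.finite(rates)) || any(rates <= 0)) stop("rates must be > 0")
  if (length(amplitudes) != length(rates)) {
    stop("'amplitudes' must match 'rates' in length")
  }
  if (abs(sum(amplitudes) - 1) > 1e-9) stop("amplitudes must sum to 1")
  .check_scalar(n, "n", min = 1)
  .check_scalar(dead_time, "dead_time", min = 0)
  withr::local_seed(as.integer(seed))
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    comp <- sample.int(length(rates), m, replace = TRUE, prob = amplitudes)
    draw <- stats::rexp(m, rates[comp])
    out <- c(out, draw[draw >= dead_time])
  }
  out[seq_len(n)]
}
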