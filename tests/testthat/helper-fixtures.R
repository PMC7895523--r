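## Shared simulated fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## A medium dumbbell simulation with moderate two-substep kinetics: slow
## enough that the detector resolves both substeps comfortably.
moderate_sim <- function() {
  cached("moderate_sim", {
    lapply(1:5, function(i) simulate_dumbbell(sim_config(
      sample_rate = 10000, duration = 165,
      seed = 4200 + i, attach_rate = 1,
      substep1 = 2.5, substep2 = 1.5,
      substep2_rate = 25, detach_rate = 3,
      molecule_id = paste0("mod", i))))
  })
}

## One wild-type-like molecule for detection benchmarks.
wt_molecule <- function() {
  cached("wt_molecule", {
    simulate_dumbbell(sim_config(
      sample_rate = 10000, duration = 80, seed = 77,
      attach_rate = 1, molecule_id = "wt1"))
  })
}

## Build an ideal noiseless trace holding given plateau levels over given
## event windows; everything else sits at `baseline`.
ideal_trace <- function(duration, sample_rate, events, baseline = 0,
                        molecule_id = "ideal") {
  n <- round(duration * sample_rate)
  tt <- (seq_len(n) - 1) / sample_rate
  x <- rep(baseline, n)
  for (e in events) {
    sel <- tt >= e$start & tt < e$end
    x[sel] <- e$level
    if (!is.null(e$level2) && !is.null(e$t2)) {
      x[tt >= e$t2 & tt < e$end] <- e$level2
    }
  }
  trap_trace(x, x, 1 / sample_rate, 0.06, 0.06, molecule_id, "", "simulated")
}

## Refined-event table from explicit times (carries the dead time).
event_table <- function(starts, ends, dead_time, molecule_id = "ideal") {
  out <- data.frame(
    raw_start = starts, raw_end = ends,
    refined_start = starts, refined_end = ends,
    duration = ends - starts,
    molecule_id = molecule_id
  )
  attr(out, "dead_time") <- dead_time
  out
}

## Brute-force centered sliding covariance (the oracle for the O(n) path).
brute_covariance <- function(a, b, w) {
  n <- length(a)
  half <- floor(w / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    stats::cov(a[lo:hi], b[lo:hi])
  }, 0)
}
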