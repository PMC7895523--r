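## Reference parameter sets for the fixture suite. Working-stroke amplitudes
## and ensemble rates follow the wild-type, mutant and drug-rescue conditions
## of the reference single-molecule study; detachment mixtures follow its
## saturating-ATP lifetime fits.

.fixture_params <- function() {
  list(
    wt_like = list(
      substep1 = 3.32, substep2 = 1.09,
      substep2_rate = 99.1, detach_rate = 4.59,
      slow_population_fraction = 0, slow_detach_rate = 1,
      condition = "WT-like, 1 uM ATP"
    ),
    r712l_like = list(
      substep1 = 1.29, substep2 = 0,
      substep2_rate = 99.1,  # unused in single-step mode
      detach_rate = 7.56,
      slow_population_fraction = 0, slow_detach_rate = 1,
      condition = "R712L-like single-step, 1 uM ATP"
    ),
    om_rescue_like = list(
      substep1 = 2.28, substep2 = 1.14,
      substep2_rate = 41.8, detach_rate = 6.29,
      slow_population_fraction = 0, slow_detach_rate = 1,
      condition = "R712L-like + 200 uM OM, 1 uM ATP"
    ),
    wt_sat_mixture = list(
      substep1 = 3.32, substep2 = 1.09,
      substep2_rate = 99.1, detach_rate = 54.4,
      slow_population_fraction = 0.03, slow_detach_rate = 7.5,
      condition = "WT-like, saturating ATP, two-population detachment"
    ),
    r712l_sat_mixture = list(
      substep1 = 1.29, substep2 = 0,
      substep2_rate = 99.1, detach_rate = 69.7,
      slow_population_fraction = 0.09, slow_detach_rate = 7.4,
      condition = "R712L-like, saturating ATP, two-population detachment"
    )
  )
}

#' Write the standard simulated fixture suite
#'
#' Generates one trace + ground-truth pair per reference condition
#' (wild-type-like two-substep, mutant-like single-step, drug-rescue
#' two-substep, and two fast/slow detachment mixtures) and a JSON manifest
#' recording every parameter and per-fixture seed. Output is byte-identical
#' for a given seed.
#'
#' @param out_dir Writable output directory (created if missing).
#' @param seed Master integer seed; per-fixture seeds are derived from it.
#' @param duration Trace length in s per fixture.
#' @param sample_rate Sampling rate in Hz.
#' @return Invisibly, the manifest as a list (also written to
#'   `manifest.json`).
#' @export
make_fixture_suite <- function(out_dir, seed = 1L, duration = 20,
                               sample_rate = 25000) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  }
  params <- .fixture_params()
  manifest <- list(master_seed = as.integer(seed),
                   duration_s = duration, sample_rate_hz = sample_rate,
                   fixtures = list())
  for (i in seq_along(params)) {
    name <- names(params)[i]
    p <- params[[i]]
    fseed <- as.integer(seed) + i
    cfg <- sim_config(
      sample_rate = sample_rate, duration = duration, seed = fseed,
      substep1 = p$substep1, substep2 = p$substep2,
      substep2_rate = p$substep2_rate, detach_rate = p$detach_rate,
      slow_population_fraction = p$slow_population_fraction,
      slow_detach_rate = p$slow_detach_rate,
      molecule_id = name, condition = p$condition
    )
    sim <- simulate_dumbbell(cfg)
    trace_path <- file.path(out_dir, paste0(name, "_trace.tsv"))
    truth_path <- file.path(out_dir, paste0(name, "_truth.csv"))
    tryCatch({
      write_trace(sim$trace, trace_path, seed = fseed)
      write_truth(sim$truth, truth_path)
    }, error = function(e) {
      stop("fixture I/O failure at ", trace_path, ": ", conditionMessage(e))
    })
    manifest$fixtures[[name]] <- list(
      trace = basename(trace_path), truth = basename(truth_path),
      seed = fseed, n_events = nrow(sim$truth),
      parameters = cfg[setdiff(names(cfg), NULL)]
    )
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
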