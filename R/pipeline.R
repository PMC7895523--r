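.pipeline_defaults <- function() {
  list(
    schema_version = 1L,
    covariance_window_ms = 30,
    auto_window = FALSE,             # search {20, 25, 30} ms, smallest separated
    start_threshold_fraction = 0.5,
    end_threshold_fraction = 0.8,
    shift_fraction_of_dead_time = 0.75,
    near_window_factor = 1.5,
    min_duration_dead_times = 1.0,
    min_events_per_molecule = 76L,
    extension_span_s = 0.5,
    pre_span_s = 0.25,
    baseline_smooth_s = 0.008,
    baseline_halfwidth_s = 0.2,
    plateau_fraction = 0.2,
    substep_floor_nm = 0.2,
    displacement_signal = "mean",
    displacement_sign = 1,
    edge_guard_fraction = 0.4,
    rev_level_window_fraction = 0.25,
    extension_level = "molecule",
    fit_guard_dead_times_forward = 0,
    fit_guard_dead_times_reverse = 1.0,
    mle_rate_bounds = c(1e-3, 1e4),
    mle_n_starts = 20L,
    n_boot = 1000L,
    alpha = 0.05,
    v_max_s = NA_real_,
    seed = 1L
  )
}

#' Pipeline configuration
#'
#' All knobs of the detection, ensemble-averaging and lifetime stages, with
#' defaults reproducing the reference analysis settings (30 ms covariance
#' window, halfway/80% refinement thresholds, 0.75-dead-time boundary shifts,
#' > 75 events per molecule). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults (see
#'   [run_pipeline()] and the package vignette for meanings and units).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- .pipeline_defaults()
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

## covariance + peaks with optional automatic window search:
## smallest window in {20, 25, 30} ms that keeps the peaks separated
.covariance_stage <- function(trace, config) {
  windows <- if (isTRUE(config$auto_window)) c(20, 25, 30) / 1e3
             else config$covariance_window_ms / 1e3
  last <- NULL
  for (w in windows) {
    cov <- compute_covariance(trace, w)
    peaks <- fit_covariance_peaks(cov)
    last <- list(cov = cov, peaks = peaks)
    if (peaks$separated) return(last)
  }
  last
}

#' Analyze a single molecule's trace
#'
#' Runs covariance -> peak decomposition -> separation gate -> detection ->
#' refinement -> forward/reverse ensemble averages -> step measurement for
#' one trace. Used by [run_pipeline()] per molecule and by
#' [compare_conditions()] per condition segment.
#'
#' @param trace A [trap_trace()].
#' @param config A [pipeline_config()].
#' @param gate_events Apply the minimum-events-per-molecule gate (default
#'   TRUE; condition segments use FALSE and are flagged instead).
#' @return List with `cov`, `peaks`, `events`, `forward`, `reverse`,
#'   `steps`, `n_events`, `excluded`, `flags`.
#' @export
analyze_molecule <- function(trace, config = pipeline_config(),
                             gate_events = TRUE) {
  stage <- .covariance_stage(trace, config)
  cov <- stage$cov; peaks <- stage$peaks
  if (!peaks$separated) {
    return(list(cov = cov, peaks = peaks, events = NULL, forward = NULL,
                reverse = NULL, steps = NULL, n_events = 0L,
                excluded = "peaks_not_separated", flags = character(0)))
  }
  raw <- detect_events(cov, peaks)
  ev <- refine_events(cov, peaks, raw,
                      start_threshold_fraction = config$start_threshold_fraction,
                      end_threshold_fraction = config$end_threshold_fraction,
                      shift_fraction_of_dead_time = config$shift_fraction_of_dead_time,
                      near_window_factor = config$near_window_factor,
                      min_duration_dead_times = config$min_duration_dead_times)
  if (gate_events && nrow(ev) < config$min_events_per_molecule) {
    return(list(cov = cov, peaks = peaks, events = ev, forward = NULL,
                reverse = NULL, steps = NULL, n_events = nrow(ev),
                excluded = "fewer_than_min_events", flags = character(0)))
  }
  flags <- character(0)
  if (nrow(ev) < 10L) flags <- c(flags, "fewer_than_10_events")
  ens_args <- list(
    trace = trace, events = ev,
    extension_span = config$extension_span_s,
    dead_time = cov$dead_time,
    signal = config$displacement_signal, sign = config$displacement_sign,
    start_threshold_fraction = config$start_threshold_fraction,
    end_threshold_fraction = config$end_threshold_fraction,
    shift_fraction_of_dead_time = config$shift_fraction_of_dead_time,
    edge_guard_fraction = config$edge_guard_fraction,
    rev_level_window_fraction = config$rev_level_window_fraction,
    extension_level = config$extension_level)
  fwd <- do.call(forward_average, c(ens_args, list(pre_span = config$pre_span_s)))
  rev <- do.call(reverse_average, c(ens_args, list(post_span = config$pre_span_s)))
  steps <- measure_steps(fwd, rev, config)
  list(cov = cov, peaks = peaks, events = ev, forward = fwd, reverse = rev,
       steps = steps, n_events = nrow(ev), excluded = NULL, flags = flags)
}

#' Step measurement bundle from a forward/reverse ensemble pair
#'
#' Total working stroke, substeps, and forward/reverse rise rates. The rise
#' fits start one detection-jitter guard past the interior anchors (see the
#' vignette), so the reported rates are those of the underlying kinetics.
#'
#' @param forward,reverse `ensemble_average` objects.
#' @param config A [pipeline_config()].
#' @return List of class `step_measurement`: `d_total`, `d1`, `d2`,
#'   `d2_detected`, `baseline`, `k_forward`, `k_forward_se`, `k_reverse`,
#'   `k_reverse_se`, `n_events`, `n_molecules`.
#' @export
measure_steps <- function(forward, reverse, config = pipeline_config()) {
  td <- forward$dead_time
  total <- measure_total_step(forward,
                              smooth = config$baseline_smooth_s,
                              baseline_halfwidth = config$baseline_halfwidth_s,
                              plateau_fraction = config$plateau_fraction)
  sub <- measure_substeps(reverse, total$d_total, total$baseline,
                          plateau_fraction = config$plateau_fraction,
                          floor = config$substep_floor_nm)
  t0_f <- .start_inset(td, config$start_threshold_fraction,
                       config$shift_fraction_of_dead_time) +
    config$fit_guard_dead_times_forward * td
  t0_r <- .end_inset(td, config$end_threshold_fraction,
                     config$shift_fraction_of_dead_time) +
    config$fit_guard_dead_times_reverse * td
  kf <- fit_rise(forward, t0 = t0_f)
  kr <- fit_rise(reverse, t0 = t0_r)
  structure(
    list(d_total = total$d_total, d1 = sub$d1, d2 = sub$d2,
         d2_detected = sub$d2_detected, baseline = total$baseline,
         reverse_level = sub$reverse_level,
         k_forward = kf$k, k_forward_se = kf$k_se, k_forward_flagged = kf$flagged,
         k_reverse = kr$k, k_reverse_se = kr$k_se, k_reverse_flagged = kr$flagged,
         n_events = forward$n_events, n_molecules = forward$n_molecules),
    class = "step_measurement"
  )
}

#' @export
print.step_measurement <- function(x, ...) {
  cat(sprintf(
    paste0("<step_measurement> total %.2f nm (d1 %.2f, d2 %.2f%s) | ",
           "k_fwd %.3g s^-1 | k_rev %.3g s^-1 | %d events / %d molecule(s)\n"),
    x$d_total, x$d1, x$d2, if (x$d2_detected) "" else ", not detected",
    x$k_forward, x$k_reverse, x$n_events, x$n_molecules))
  invisible(x)
}

#' Run the full analysis pipeline over one or more molecules
#'
#' Per molecule: covariance, two-Gaussian peak decomposition, separation
#' gate, event detection and refinement, minimum-event gate, forward and
#' reverse ensemble averages. Molecules are then combined with equal
#' weighting, the working stroke and rise rates measured on the combined
#' averages, and the pooled refined durations fit with the truncated
#' exponential MLE including model selection. Deterministic given the
#' config seed.
#'
#' @param traces A [trap_trace()] or list of them (one per molecule).
#' @param config A [pipeline_config()].
#' @param bootstrap Compute bootstrap CIs for the selected lifetime model
#'   (default FALSE; uses `config$n_boot` and `config$seed`).
#' @return A list of class `run_report`.
#' @export
run_pipeline <- function(traces, config = pipeline_config(), bootstrap = FALSE) {
  if (inherits(traces, "trap_trace")) traces <- list(traces)
  if (length(traces) < 1L) stop("need at least one trace")
  per <- lapply(traces, analyze_molecule, config = config)
  ids <- vapply(traces, `[[`, "", "molecule_id")
  names(per) <- ids
  ok <- !vapply(per, function(m) is.null(m$forward), TRUE)
  exclusions <- data.frame(
    molecule_id = ids[!ok],
    reason = vapply(per[!ok], function(m) m$excluded %||% "unknown", ""),
    n_events = vapply(per[!ok], `[[`, 0L, "n_events")
  )
  if (!any(ok)) {
    stop("no molecule passed the gates: ",
         paste(sprintf("%s (%s)", exclusions$molecule_id, exclusions$reason),
               collapse = "; "))
  }
  kept <- per[ok]
  fwd <- combine_molecules(lapply(kept, `[[`, "forward"))
  rev <- combine_molecules(lapply(kept, `[[`, "reverse"))
  steps <- measure_steps(fwd, rev, config)
  durations <- unlist(lapply(kept, function(m) m$events$duration), use.names = FALSE)
  td <- kept[[1L]]$cov$dead_time
  fits <- fit_lifetimes(durations, dead_time = td,
                        n_starts = config$mle_n_starts,
                        rate_bounds = config$mle_rate_bounds)
  sel <- select_model(fits$order1, fits$order2, alpha = config$alpha)
  if (bootstrap) {
    sel$chosen <- bootstrap_ci(durations, td, sel$chosen,
                               n_boot = config$n_boot, seed = config$seed)
  }
  duty <- if (is.finite(config$v_max_s)) {
    duty_ratio(sel$chosen$k1, config$v_max_s)
  }
  structure(
    list(
      per_molecule = lapply(kept, function(m)
        list(molecule_id = m$forward$molecule_id, n_events = m$n_events,
             steps = m$steps, flags = m$flags)),
      combined = steps,
      forward = fwd, reverse = rev,
      lifetimes = list(order1 = fits$order1, order2 = fits$order2,
                       selected = sel$chosen, p_value = sel$p_value),
      duty_ratio = duty,
      dead_time = td,
      exclusions = exclusions,
      n_molecules = sum(ok), n_events = sum(vapply(kept, `[[`, 0L, "n_events")),
      config = unclass(config),
      seed = config$seed,
      version = as.character(utils::packageVersion("trapstroke"))
    ),
    class = "run_report"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d molecule(s), %d events (dead time %.1f ms)\n",
              x$n_molecules, x$n_events, 1e3 * x$dead_time))
  print(x$combined)
  print(x$lifetimes$selected)
  if (!is.null(x$duty_ratio)) {
    cat(sprintf("  duty ratio: %.3f\n", x$duty_ratio$value))
  }
  if (nrow(x$exclusions)) {
    cat(sprintf("  excluded: %s\n",
                paste(sprintf("%s (%s)", x$exclusions$molecule_id,
                              x$exclusions$reason), collapse = "; ")))
  }
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  strip <- function(x) {
    if (inherits(x, "step_measurement") || inherits(x, "lifetime_fit")) {
      unclass(x)
    } else if (inherits(x, "ensemble_average")) {
      NULL  # bulky arrays go to CSV via write_ensemble, not the report
    } else if (is.list(x) && !is.data.frame(x)) {
      Filter(Negate(is.null), lapply(x, strip))
    } else x
  }
  jsonlite::write_json(strip(unclass(report)), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' Write an ensemble average as CSV
#'
#' Columns: `alignment`, `tau_s`, `mean_nm`, `n_events`, `n_molecules`.
#'
#' @param ensemble An `ensemble_average`.
#' @param path Output path.
#' @export
write_ensemble <- function(ensemble, path) {
  utils::write.csv(
    data.frame(alignment = ensemble$alignment,
               tau_s = as.numeric(ensemble$tau),
               mean_nm = unname(as.numeric(ensemble$mean_displacement)),
               n_events = ensemble$n_events,
               n_molecules = ensemble$n_molecules),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Paired per-condition analysis of one molecule under buffer exchange
#'
#' Splits a single molecule's recording into condition segments (e.g. drug /
#' washout / re-addition), runs the full detection -> ensemble -> step
#' pipeline independently on each, and reports the paired step measurements
#' plus differences against the first segment. Segments with fewer than 10
#' events are flagged but still reported.
#'
#' @param trace A [trap_trace()].
#' @param segments data.frame with columns `condition`, `start`, `end`
#'   (seconds within the trace, non-overlapping).
#' @param config A [pipeline_config()].
#' @return List with `per_condition` (named list of `step_measurement` plus
#'   `n_events` and `flags`) and `differences` (data.frame of condition,
#'   `delta_d_total` vs the first segment).
#' @export
compare_conditions <- function(trace, segments, config = pipeline_config()) {
  if (nrow(segments) < 2L) stop("need at least two condition segments")
  o <- order(segments$start)
  segments <- segments[o, ]
  if (any(segments$start[-1L] < segments$end[-nrow(segments)])) {
    stop("condition segments overlap")
  }
  out <- list()
  for (i in seq_len(nrow(segments))) {
    sub <- trace_window(trace, segments$start[i], segments$end[i])
    res <- analyze_molecule(sub, config, gate_events = FALSE)
    if (is.null(res$steps)) {
      out[[segments$condition[i]]] <- list(steps = NULL, n_events = res$n_events,
                                           flags = res$excluded)
    } else {
      out[[segments$condition[i]]] <- list(steps = res$steps,
                                           n_events = res$n_events,
                                           flags = res$flags)
    }
  }
  have <- !vapply(out, function(x) is.null(x$steps), TRUE)
  ref <- which(have)[1L]
  diffs <- data.frame(
    condition = names(out)[have],
    d_total = vapply(out[have], function(x) x$steps$d_total, 0),
    delta_d_total = vapply(out[have], function(x)
      x$steps$d_total - out[[ref]]$steps$d_total, 0)
  )
  list(per_condition = out, differences = diffs)
}
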