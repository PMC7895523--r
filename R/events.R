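#' Detect candidate binding events from covariance threshold crossings
#'
#' An event requires a full excursion of the covariance signal from the
#' unbound peak mean down to the bound peak mean and back: the raw start is
#' the first sample at or below the bound mean within the excursion, the raw
#' end the first subsequent sample at or above the unbound mean. Requiring
#' the full excursion (rather than a single threshold) suppresses false
#' positives from covariance noise.
#'
#' @param cov A `cov_series` from [compute_covariance()].
#' @param peaks A `cov_peaks` from [fit_covariance_peaks()]; must be
#'   separated, otherwise the molecule is refused as not analyzable.
#' @return data.frame with columns `raw_start`, `raw_end` (s), sample indices
#'   `raw_start_idx`, `raw_end_idx`, and `molecule_id`.
#' @export
detect_events <- function(cov, peaks) {
  if (!inherits(cov, "cov_series")) stop("'cov' must be a cov_series")
  if (!inherits(peaks, "cov_peaks")) stop("'peaks' must be a cov_peaks")
  if (!isTRUE(peaks$separated)) {
    stop("molecule not analyzable: bound/unbound covariance peaks not separated (",
         cov$molecule_id, ")")
  }
  v <- cov$values
  ## code samples: +1 at/above unbound mean, -1 at/below bound mean
  z <- integer(length(v))
  z[v >= peaks$unbound_mean] <- 1L
  z[v <= peaks$bound_mean] <- -1L
  idx <- which(z != 0L)
  starts <- integer(0); ends <- integer(0)
  if (length(idx) > 1L) {
    r <- rle(z[idx])
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (r$values[j] == -1L && j > 1L && j < length(r$values)) {
        ## runs are alternating in the compressed sequence, so the
        ## neighbours are +1 runs: a complete high-low-high excursion
        starts <- c(starts, idx[run_start[j]])
        ends <- c(ends, idx[run_start[j + 1L]])
      }
    }
  }
  data.frame(
    raw_start = cov$times[starts], raw_end = cov$times[ends],
    raw_start_idx = starts, raw_end_idx = ends,
    molecule_id = rep(cov$molecule_id, length(starts))
  )
}

## Earliest threshold crossing (downward if dir < 0, upward if dir > 0)
## within [lo, hi]. When the window opens already beyond the threshold the
## crossing happened earlier than the search window (e.g. the raw end marker
## lagged a stalled covariance recovery): walk back to the first sample of
## the ongoing beyond-threshold run, within a bounded look-back. When the
## threshold is never crossed inside the window, keep `at`.
.earliest_crossing <- function(v, at, lo, hi, thr, dir, max_back = 0L) {
  win <- lo:hi
  crossed <- if (dir < 0) v[win] <= thr else v[win] >= thr
  if (!any(crossed)) return(at)
  if (crossed[1L]) {
    j <- lo
    floor_j <- max(1L, lo - max_back)
    while (j > floor_j &&
           (if (dir < 0) v[j - 1L] <= thr else v[j - 1L] >= thr)) {
      j <- j - 1L
    }
    return(j)
  }
  k <- which(crossed & c(FALSE, !crossed[-length(crossed)]))
  win[k[1L]]
}

#' Refine raw event boundaries
#'
#' The covariance is a delayed indicator of attachment and detachment, so the
#' raw threshold times are refined in two steps. The start moves to the
#' earliest crossing below the halfway level between the bound and unbound
#' peaks near the raw start; the end moves to the first crossing above 80%
#' of the way back toward the unbound peak near the raw end. "Near" means
#' within 1.5x the dead time or within the raw event duration, whichever is
#' smaller. Finally starts and ends are shifted by -/+ 0.75x the dead time to
#' undo the symmetric smearing of the finite averaging window. Events whose
#' refined duration falls below the dead time are excluded; refined events
#' that overlap after the shifts are both dropped.
#'
#' @param cov A `cov_series`.
#' @param peaks A `cov_peaks`.
#' @param events Raw events from [detect_events()].
#' @param start_threshold_fraction,end_threshold_fraction Crossing levels as
#'   fractions of the bound-to-unbound span (defaults 0.5 and 0.8).
#' @param shift_fraction_of_dead_time Boundary shift in dead-time units
#'   (default 0.75).
#' @param near_window_factor "Near" search radius in dead-time units
#'   (default 1.5).
#' @param min_duration_dead_times Minimum refined duration in dead-time units
#'   (default 1).
#' @return data.frame with `raw_start`, `raw_end`, `refined_start`,
#'   `refined_end`, `duration`, `molecule_id`; excluded events are recorded
#'   in `attr(, "excluded")` with machine-readable reasons.
#' @export
refine_events <- function(cov, peaks, events,
                          start_threshold_fraction = 0.5,
                          end_threshold_fraction = 0.8,
                          shift_fraction_of_dead_time = 0.75,
                          near_window_factor = 1.5,
                          min_duration_dead_times = 1.0) {
  v <- cov$values
  n <- length(v)
  dt <- cov$sample_interval
  td <- cov$dead_time
  span <- peaks$unbound_mean - peaks$bound_mean
  thr_start <- peaks$bound_mean + start_threshold_fraction * span
  thr_end <- peaks$bound_mean + end_threshold_fraction * span
  shift <- shift_fraction_of_dead_time * td

  m <- nrow(events)
  refined_start <- numeric(m); refined_end <- numeric(m)
  interior_recovery <- logical(m)
  for (i in seq_len(m)) {
    dur <- events$raw_end[i] - events$raw_start[i]
    w <- as.integer(round(min(near_window_factor * td, dur) / dt))
    i0 <- events$raw_start_idx[i]; i1 <- events$raw_end_idx[i]
    back <- as.integer(round(4 * td / dt))  # bounded look-back for stalled markers
    js <- .earliest_crossing(v, i0, max(1L, i0 - w), min(n, i0 + w),
                             thr_start, dir = -1, max_back = back)
    je <- .earliest_crossing(v, i1, max(1L, i1 - w), min(n, i1 + w),
                             thr_end, dir = +1, max_back = back)
    refined_start[i] <- cov$times[js] - shift
    refined_end[i] <- cov$times[je] + shift
    ## a covariance excursion back above the end threshold strictly inside
    ## the event marks a partial recovery: two attachments separated by a
    ## gap too short to re-cross the unbound mean
    if (je - js > 2L) {
      interior_recovery[i] <- any(v[(js + 1L):(je - 1L)] >= thr_end)
    }
  }
  duration <- refined_end - refined_start
  out <- data.frame(
    raw_start = events$raw_start, raw_end = events$raw_end,
    refined_start = refined_start, refined_end = refined_end,
    duration = duration,
    molecule_id = events$molecule_id
  )
  excluded <- out[0, ]; excluded$reason <- character(0)

  if (any(interior_recovery)) {
    ex <- out[interior_recovery, ]; ex$reason <- "interior_recovery"
    excluded <- rbind(excluded, ex)
    out <- out[!interior_recovery, ]
  }

  short <- out$duration < min_duration_dead_times * td
  if (any(short)) {
    ex <- out[short, ]; ex$reason <- "shorter_than_dead_time"
    excluded <- rbind(excluded, ex)
    out <- out[!short, ]
  }
  ## the +/- shifts can make neighbours overlap: drop both, conservatively
  if (nrow(out) > 1L) {
    ov <- out$refined_start[-1L] < out$refined_end[-nrow(out)]
    bad <- unique(c(which(ov), which(ov) + 1L))
    if (length(bad)) {
      ex <- out[bad, ]; ex$reason <- "overlap_after_refinement"
      excluded <- rbind(excluded, ex)
      out <- out[-bad, ]
    }
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "dead_time") <- td
  out
}

#' Benchmark detected events against simulator ground truth
#'
#' Matches detected events to ground-truth events by interval overlap and
#' reports recall and the false-positive rate, restricted (for recall) to
#' true events longer than a minimum duration.
#'
#' @param events Refined events from [refine_events()].
#' @param truth Ground-truth data.frame from [simulate_dumbbell()].
#' @param min_true_duration Only true events at least this long (s) count
#'   toward recall (short events are below the detection floor by design).
#' @param min_overlap Minimum fractional overlap of the true interval
#'   (default 0.5).
#' @return List with `recall`, `false_positive_rate`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
match_events_to_truth <- function(events, truth, min_true_duration = 0,
                                  min_overlap = 0.5) {
  t_start <- truth$attach_time; t_end <- truth$detach_time
  eligible <- (t_end - t_start) >= min_true_duration
  matched_truth <- logical(nrow(truth))
  matched_det <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    ov <- pmin(events$refined_end[i], t_end) - pmax(events$refined_start[i], t_start)
    frac <- ov / (t_end - t_start)
    hit <- which(frac >= min_overlap)
    if (length(hit)) {
      matched_truth[hit] <- TRUE
      matched_det[i] <- TRUE
    }
  }
  list(
    recall = if (any(eligible)) mean(matched_truth[eligible]) else NA_real_,
    false_positive_rate = if (nrow(events)) mean(!matched_det) else 0,
    n_true = sum(eligible), n_detected = nrow(events),
    n_matched = sum(matched_truth[eligible])
  )
}
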