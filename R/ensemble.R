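## Ensemble averaging of event-aligned displacement and substep extraction.
##
## Geometry note: refined event bounds deliberately overshoot the bound
## interval (the start is shifted earlier and the end later by 0.75 dead
## times, and the 80% end-crossing itself sits past detachment), so all
## level estimates are taken at interior anchors derived from the crossing
## rules: the attachment anchor sits `shift` past the refined start and the
## detachment anchor `shift + (end_threshold - 0.5) * window` before the
## refined end. These insets follow from the configured thresholds, not from
## tuning.

.start_inset <- function(dead_time, start_threshold_fraction = 0.5,
                         shift_fraction_of_dead_time = 0.75) {
  shift_fraction_of_dead_time * dead_time +
    (start_threshold_fraction - 0.5) * 2 * dead_time
}

.end_inset <- function(dead_time, end_threshold_fraction = 0.8,
                       shift_fraction_of_dead_time = 0.75) {
  shift_fraction_of_dead_time * dead_time +
    (end_threshold_fraction - 0.5) * 2 * dead_time
}

## displacement signal of a trace: mean of the beads (default), or one bead
.displacement <- function(trace, signal = c("mean", "bead_a", "bead_b"),
                          sign = 1) {
  signal <- match.arg(signal)
  s <- switch(signal,
              mean = (trace$bead_a + trace$bead_b) / 2,
              bead_a = trace$bead_a,
              bead_b = trace$bead_b)
  sign * s
}

#' Displacement excerpt around one event
#'
#' Returns the (averaged-bead, by default) displacement over
#' `[refined_start - pad, refined_end + pad]`, baseline-unsubtracted. A pad
#' reaching beyond the trace is truncated and flagged.
#'
#' @param trace A [trap_trace()].
#' @param event One row of a refined event data.frame.
#' @param pad Padding in s on both sides.
#' @param signal Which displacement signal to use: `"mean"` (average of both
#'   beads), `"bead_a"`, or `"bead_b"`.
#' @param sign +1 or -1; flips the displacement sign convention.
#' @return data.frame(`time`, `displacement`) with attribute `truncated`.
#' @export
event_displacement <- function(trace, event, pad = 0,
                               signal = "mean", sign = 1) {
  disp <- .displacement(trace, signal, sign)
  dt <- trace$sample_interval
  n <- length(disp)
  i0 <- as.integer(round((event$refined_start - pad) / dt)) + 1L
  i1 <- as.integer(round((event$refined_end + pad) / dt)) + 1L
  truncated <- i0 < 1L || i1 > n
  i0 <- max(i0, 1L); i1 <- min(i1, n)
  if (i1 < i0) stop("event lies outside the trace")
  out <- data.frame(time = (seq(i0, i1) - 1L) * dt,
                    displacement = disp[i0:i1])
  attr(out, "truncated") <- truncated
  out
}

## shared worker for forward/reverse ensemble averages
.ensemble_average <- function(trace, events, alignment,
                              extension_span, outer_span,
                              dead_time,
                              signal, sign,
                              start_threshold_fraction,
                              end_threshold_fraction,
                              shift_fraction_of_dead_time,
                              edge_guard_fraction,
                              rev_level_window_fraction,
                              extension_level = "molecule") {
  if (nrow(events) < 1L) stop("need at least one event")
  if (is.null(dead_time)) dead_time <- attr(events, "dead_time")
  if (is.null(dead_time)) stop("dead_time not supplied and not carried by events")
  disp <- .displacement(trace, signal, sign)
  dt <- trace$sample_interval
  n <- length(disp)
  g <- edge_guard_fraction * dead_time
  ins_s <- .start_inset(dead_time, start_threshold_fraction,
                        shift_fraction_of_dead_time)
  ins_e <- .end_inset(dead_time, end_threshold_fraction,
                      shift_fraction_of_dead_time)

  if (alignment == "forward") {
    tau_idx <- seq(-as.integer(round(outer_span / dt)),
                   as.integer(round(extension_span / dt)))
  } else {
    tau_idx <- seq(-as.integer(round(extension_span / dt)),
                   as.integer(round(outer_span / dt)))
  }
  tau <- tau_idx * dt
  mean_range <- function(t_lo, t_hi) {
    j0 <- max(1L, as.integer(round(t_lo / dt)) + 1L)
    j1 <- min(n, as.integer(round(t_hi / dt)) + 1L)
    if (j1 < j0) j1 <- j0
    mean(disp[j0:j1])
  }
  ## first pass: per-event boundary-level estimates and extension cuts
  m <- nrow(events)
  level <- numeric(m); cut_tau <- numeric(m); anchor_idx <- integer(m)
  ok <- logical(m)
  for (i in seq_len(m)) {
    rs <- events$refined_start[i]; re <- events$refined_end[i]
    est_attach <- rs + ins_s
    est_detach <- re - ins_e
    if (est_detach <= est_attach) est_detach <- est_attach + dt
    if (alignment == "forward") {
      anchor <- rs
      ## level just before detachment, held beyond the event
      level[i] <- mean_range(max(est_attach + g, est_detach - g - dead_time),
                             est_detach - g)
      cut_tau[i] <- (est_detach - g) - anchor
    } else {
      anchor <- re
      ## level just after attachment, held before the event
      lvl_hi <- min(est_attach + g + rev_level_window_fraction * dead_time,
                    est_detach - g)
      level[i] <- mean_range(est_attach + g, lvl_hi)
      cut_tau[i] <- (est_attach + g) - anchor
    }
    anchor_idx[i] <- as.integer(round(anchor / dt)) + 1L
    lim <- anchor_idx[i] + range(tau_idx[if (alignment == "forward")
      tau <= cut_tau[i] else tau >= cut_tau[i]])
    ok[i] <- lim[1L] >= 1L && lim[2L] <= n  # else: too close to a trace edge
  }
  if (!any(ok)) stop("no event fits inside the trace with the requested spans")
  ## pooled extension levels remove the coupling between an event's duration
  ## and its boundary-level estimate (which otherwise tilts the extension
  ## region of the average; see the methods vignette)
  if (identical(extension_level, "molecule")) {
    level[] <- mean(level[ok])
  }
  acc <- numeric(length(tau))
  used <- 0L
  for (i in which(ok)) {
    real <- if (alignment == "forward") tau <= cut_tau[i] else tau >= cut_tau[i]
    idx <- anchor_idx[i] + tau_idx
    vals <- numeric(length(tau))
    vals[real] <- disp[idx[real]]
    vals[!real] <- level[i]
    acc <- acc + vals
    used <- used + 1L
  }
  structure(
    list(alignment = alignment, tau = tau, mean_displacement = acc / used,
         n_events = used, n_molecules = 1L,
         extension_span = extension_span, dead_time = dead_time,
         molecule_id = events$molecule_id[1L]),
    class = "ensemble_average"
  )
}

#' Time-forward ensemble average
#'
#' Aligns events at their refined starts and averages the displacement
#' point-wise out to `extension_span`; beyond each event's detachment the
#' trace is replaced by the constant level it held just before detachment
#' (averaged over one dead time inside the bound interval), so events of
#' different lengths can be averaged together.
#'
#' @param trace A [trap_trace()].
#' @param events Refined events from [refine_events()].
#' @param extension_span Span in s after the alignment point.
#' @param pre_span Span in s before the alignment point (baseline region).
#' @param dead_time Instrument dead time in s; taken from `events` if `NULL`.
#' @param signal,sign See [event_displacement()].
#' @param start_threshold_fraction,end_threshold_fraction,shift_fraction_of_dead_time
#'   Refinement-rule constants used to locate the interior anchors.
#' @param edge_guard_fraction Guard, in dead-time units, kept between an
#'   anchor and any level-estimation window.
#' @param rev_level_window_fraction Length, in dead-time units, of the
#'   post-attachment level window used by the reverse average.
#' @param extension_level `"molecule"` (default) holds one pooled boundary
#'   level per molecule when extending events; `"per_event"` holds each
#'   event's own boundary level.
#' @return An `ensemble_average` object.
#' @export
forward_average <- function(trace, events, extension_span = 0.5,
                            pre_span = 0.25, dead_time = NULL,
                            signal = "mean", sign = 1,
                            start_threshold_fraction = 0.5,
                            end_threshold_fraction = 0.8,
                            shift_fraction_of_dead_time = 0.75,
                            edge_guard_fraction = 0.4,
                            rev_level_window_fraction = 0.25,
                            extension_level = c("molecule", "per_event")) {
  .ensemble_average(trace, events, "forward", extension_span, pre_span,
                    dead_time, signal, sign,
                    start_threshold_fraction, end_threshold_fraction,
                    shift_fraction_of_dead_time, edge_guard_fraction,
                    rev_level_window_fraction, match.arg(extension_level))
}

#' Time-reversed ensemble average
#'
#' Mirror of [forward_average()]: events are aligned at their refined ends;
#' before each event's attachment the trace is replaced by the level it held
#' just after attachment.
#'
#' @inheritParams forward_average
#' @param post_span Span in s after the alignment point (detached baseline).
#' @return An `ensemble_average` object.
#' @export
reverse_average <- function(trace, events, extension_span = 0.5,
                            post_span = 0.25, dead_time = NULL,
                            signal = "mean", sign = 1,
                            start_threshold_fraction = 0.5,
                            end_threshold_fraction = 0.8,
                            shift_fraction_of_dead_time = 0.75,
                            edge_guard_fraction = 0.4,
                            rev_level_window_fraction = 0.25,
                            extension_level = c("molecule", "per_event")) {
  .ensemble_average(trace, events, "reverse", extension_span, post_span,
                    dead_time, signal, sign,
                    start_threshold_fraction, end_threshold_fraction,
                    shift_fraction_of_dead_time, edge_guard_fraction,
                    rev_level_window_fraction, match.arg(extension_level))
}

#' @export
print.ensemble_average <- function(x, ...) {
  cat(sprintf("<ensemble_average> %s | %d events, %d molecule(s) | tau %.3f..%.3f s\n",
              x$alignment, x$n_events, x$n_molecules,
              min(x$tau), max(x$tau)))
  invisible(x)
}

#' Combine per-molecule ensemble averages with equal molecule weighting
#'
#' Each molecule contributes equally regardless of how many events it
#' produced; event counts are summed for bookkeeping only.
#'
#' @param per_molecule List of `ensemble_average` objects sharing alignment
#'   and tau grid.
#' @return A combined `ensemble_average`.
#' @export
combine_molecules <- function(per_molecule) {
  if (length(per_molecule) == 0L) stop("empty input")
  al <- vapply(per_molecule, `[[`, "", "alignment")
  if (length(unique(al)) != 1L) stop("mixed alignments cannot be combined")
  tau <- per_molecule[[1L]]$tau
  for (e in per_molecule) {
    if (length(e$tau) != length(tau) || max(abs(e$tau - tau)) > 1e-9) {
      stop("tau grids differ between molecules")
    }
  }
  m <- vapply(per_molecule, `[[`, numeric(length(tau)), "mean_displacement")
  structure(
    list(alignment = al[1L], tau = tau,
         mean_displacement = rowMeans(m),
         n_events = sum(vapply(per_molecule, `[[`, 0L, "n_events")),
         n_molecules = sum(vapply(per_molecule, `[[`, 0L, "n_molecules")),
         extension_span = per_molecule[[1L]]$extension_span,
         dead_time = per_molecule[[1L]]$dead_time,
         molecule_id = "combined"),
    class = "ensemble_average"
  )
}

#' Total working stroke from the forward ensemble average
#'
#' The baseline is the minimum of the 8-ms-smoothed ensemble trace within
#' +/- 0.2 s of the alignment point (the detected event start); the total
#' step is the mean of the forward extension region (final 20% of the
#' extension span) minus that baseline.
#'
#' @param forward A forward `ensemble_average`.
#' @param smooth Baseline smoothing window in s (default 8 ms).
#' @param baseline_halfwidth Half-width in s of the baseline search window.
#' @param plateau_fraction Final fraction of the extension span averaged as
#'   the plateau (default 0.2).
#' @return List with `d_total` (nm) and `baseline` (nm).
#' @export
measure_total_step <- function(forward, smooth = 0.008,
                               baseline_halfwidth = 0.2,
                               plateau_fraction = 0.2) {
  if (forward$alignment != "forward") stop("needs a forward ensemble average")
  tau <- forward$tau
  dt <- tau[2L] - tau[1L]
  plateau_sel <- tau >= forward$extension_span * (1 - plateau_fraction)
  if (sum(plateau_sel) < 10L) stop("extension region shorter than 10 samples")
  sm <- .rolling_mean(forward$mean_displacement, max(1L, round(smooth / dt)))
  base_sel <- abs(tau) <= baseline_halfwidth
  baseline <- min(sm[base_sel])
  list(d_total = mean(forward$mean_displacement[plateau_sel]) - baseline,
       baseline = baseline)
}

#' Substep decomposition from the time-reversed ensemble average
#'
#' The second substep is the total step minus the backward-extension level of
#' the reverse average (referenced to the same baseline); the first substep
#' is the remainder, so `d1 + d2 = d_total` by construction. A second-substep
#' magnitude below the resolution floor is reported as not detected.
#'
#' @param reverse A reverse `ensemble_average`.
#' @param d_total,baseline From [measure_total_step()].
#' @param plateau_fraction Final fraction of the backward span averaged as
#'   the extension level.
#' @param floor Detection floor for `|d2|` in nm (default 0.2).
#' @return List with `d1`, `d2`, `d2_detected`, `reverse_level`.
#' @export
measure_substeps <- function(reverse, d_total, baseline,
                             plateau_fraction = 0.2, floor = 0.2) {
  if (reverse$alignment != "reverse") stop("needs a reverse ensemble average")
  tau <- reverse$tau
  sel <- tau <= -reverse$extension_span * (1 - plateau_fraction)
  if (sum(sel) < 10L) stop("backward extension region shorter than 10 samples")
  reverse_level <- mean(reverse$mean_displacement[sel])
  d2 <- d_total - (reverse_level - baseline)
  list(d1 = d_total - d2, d2 = d2,
       d2_detected = abs(d2) >= floor,
       reverse_level = reverse_level)
}

#' Single-exponential fit to the rising phase of an ensemble average
#'
#' Fits `y = a + b (1 - exp(-k (tau - t0)))` to a forward average (for
#' `tau >= t0`) or `y = a + b exp(-k (|tau| - t0))` to a reverse average
#' (for `tau <= -t0`). The fit window is `5 / k_init` past `t0`, with
#' `k_init` from a log-linear pre-fit. A series with no resolvable amplitude
#' is flagged rather than fitted.
#'
#' @param ensemble An `ensemble_average`.
#' @param t0 Fit origin in s past the alignment point (see Details in the
#'   package vignette: in the pipeline this is the interior anchor plus a
#'   detection-jitter guard).
#' @param k_init Optional initial rate; estimated when `NULL`.
#' @param window Optional fixed fit window in s past `t0`; when `NULL` the
#'   window is `5 / k`, iterated to self-consistency with the fitted rate.
#' @return List with `k`, `k_se`, `a`, `b`, `flagged`, `alignment`,
#'   `fit_window`.
#' @export
fit_rise <- function(ensemble, t0 = 0, k_init = NULL, window = NULL) {
  tau <- ensemble$tau
  y_all <- ensemble$mean_displacement
  forward <- ensemble$alignment == "forward"
  if (forward) {
    sel <- tau >= t0
    x <- tau[sel] - t0
  } else {
    sel <- tau <= -t0
    x <- rev(abs(tau[sel]) - t0)
  }
  y <- if (forward) y_all[sel] else rev(y_all[sel])
  bad <- list(k = NA_real_, k_se = NA_real_, a = NA_real_, b = NA_real_,
              flagged = TRUE, alignment = ensemble$alignment,
              fit_window = NA_real_)
  if (length(x) < 10L || stats::sd(y) < 1e-12) return(bad)

  dx <- x[2L] - x[1L]
  ## lightly smoothed curve for initialization only (1% of the span)
  ys <- .rolling_mean(y, max(3L, round(length(y) * 0.01)))
  y_0 <- ys[1L]
  y_inf <- mean(ys[x >= 0.8 * max(x)])
  b0 <- if (forward) y_inf - y_0 else y_0 - y_inf
  if (is.null(k_init)) {
    ## half-rise time of the smoothed curve; robust against plateau noise,
    ## unlike a log-linear regression over the whole span
    frac <- (ys - y_0) / (y_inf - y_0)
    half <- which(frac >= 0.5)
    x_half <- if (length(half)) x[half[1L]] else max(x) / 3
    x_half <- min(max(x_half, 2 * dx), max(x) / 2)
    k_init <- log(2) / x_half
  }
  form <- if (forward) y ~ a + b * (1 - exp(-k * x)) else y ~ a + b * exp(-k * x)
  fit_in_window <- function(win, starts_k) {
    use <- x <= win
    if (sum(use) < 30L) use <- x <= 30L * dx
    df <- data.frame(x = x[use], y = y[use])
    best <- NULL
    for (k0 in starts_k) {
      st <- if (forward) list(a = y_0, b = b0, k = k0)
            else list(a = y_inf, b = b0, k = k0)
      fit <- tryCatch(
        minpack.lm::nlsLM(form, data = df, start = st,
                          lower = c(-Inf, -Inf, 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
      }
    }
    best
  }
  if (!is.null(window)) {
    win <- min(max(x), window)
    best <- fit_in_window(win, k_init * c(1, 0.3, 3))
    if (is.null(best)) return(bad)
  } else {
    ## self-consistent fit window: refit until the window 5/k agrees with
    ## the fitted rate (guards against a poor k_init locking in a poor
    ## window)
    win <- min(max(x), 5 / k_init)
    best <- fit_in_window(win, k_init * c(1, 0.3, 3))
    if (is.null(best)) return(bad)
    for (it in 1:3) {
      k_hat <- stats::coef(best$fit)[["k"]]
      win2 <- min(max(x), 5 / k_hat)
      if (abs(win2 - win) <= 0.2 * win) break
      win <- win2
      nxt <- fit_in_window(win, k_hat * c(1, 0.3, 3))
      if (is.null(nxt)) break
      best <- nxt
    }
  }
  cf <- summary(best$fit)$coefficients
  k <- cf["k", "Estimate"]; k_se <- cf["k", "Std. Error"]
  b <- cf["b", "Estimate"]
  flagged <- !is.finite(k_se) || k_se > abs(k) || abs(b) < 1e-9
  list(k = k, k_se = k_se, a = cf["a", "Estimate"], b = b,
       flagged = flagged, alignment = ensemble$alignment, fit_window = win)
}
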