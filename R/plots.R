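#' Plot a displacement trace with its covariance signal and detected events
#'
#' Two stacked panels: the (5-ms display-smoothed) displacement with event
#' bars, and the windowed covariance with the bound/unbound peak means and
#' the detected intervals. The smoothing is cosmetic; measurements never use
#' it.
#'
#' @param trace A [trap_trace()].
#' @param cov A `cov_series`.
#' @param events Refined events.
#' @param peaks A `cov_peaks`.
#' @param from,to Time range to draw (defaults to the whole trace).
#' @param display_smooth Display smoothing in s (default 5 ms).
#' @export
plot_covariance_events <- function(trace, cov, events, peaks,
                                   from = 0, to = NULL,
                                   display_smooth = 0.005) {
  tt <- trace_times(trace)
  if (is.null(to)) to <- max(tt)
  sel <- tt >= from & tt <= to
  disp <- .rolling_mean(.displacement(trace),
                        max(1L, round(display_smooth / trace$sample_interval)))
  old <- graphics::par(mfrow = c(2, 1), mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(tt[sel], disp[sel], type = "l", col = "grey30",
                 xlab = "", ylab = "displacement (nm)")
  if (nrow(events)) {
    graphics::rect(events$refined_start, graphics::par("usr")[3],
                   events$refined_end, graphics::par("usr")[3] +
                     0.05 * diff(graphics::par("usr")[3:4]),
                   col = "forestgreen", border = NA)
  }
  csel <- cov$times >= from & cov$times <= to
  graphics::plot(cov$times[csel], cov$values[csel], type = "l", col = "grey60",
                 xlab = "time (s)", ylab = expression(covariance ~ (nm^2)))
  graphics::abline(h = c(peaks$bound_mean, peaks$unbound_mean),
                   col = c("firebrick", "steelblue"), lty = 2)
  invisible(NULL)
}

#' Plot ensemble averages with their exponential fits
#'
#' @param forward,reverse `ensemble_average` objects.
#' @param steps Optional `step_measurement` whose rise fits are overlaid.
#' @export
plot_ensemble <- function(forward, reverse, steps = NULL) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(forward$tau, forward$mean_displacement, type = "l",
                 xlab = "time from event start (s)", ylab = "displacement (nm)")
  if (!is.null(steps) && is.finite(steps$k_forward)) {
    xx <- forward$tau[forward$tau >= 0]
    graphics::lines(xx, steps$baseline + steps$d1 + steps$d2 *
                      (1 - exp(-steps$k_forward * pmax(xx, 0))),
                    col = "goldenrod", lwd = 2)
  }
  graphics::plot(reverse$tau, reverse$mean_displacement, type = "l",
                 xlab = "time to event end (s)", ylab = "displacement (nm)")
  if (!is.null(steps) && is.finite(steps$k_reverse)) {
    xx <- reverse$tau[reverse$tau <= 0]
    graphics::lines(xx, steps$baseline + steps$d1 + steps$d2 *
                      exp(-steps$k_reverse * abs(xx)),
                    col = "goldenrod", lwd = 2)
  }
  invisible(NULL)
}
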