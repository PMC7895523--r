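#' Trap stiffness from the position power spectrum
#'
#' Calibrates a trap from unbound bead motion two ways: (i) a Lorentzian fit
#' to the one-sided power spectrum gives the corner frequency `f_c` and
#' `kappa = 2 pi gamma f_c` with Stokes drag `gamma`; (ii) equipartition,
#' `kappa = kB T / var(x)`. Both are reported; on a flat (trap-free) spectrum
#' the Lorentzian route is flagged as failed.
#'
#' @param x Numeric vector of bead positions (nm), or a [trap_trace()] (its
#'   `bead_a` is used).
#' @param sample_rate Sampling rate in Hz (taken from the trace if omitted).
#' @param bead_radius Bead radius in nm for the drag coefficient.
#' @param temperature Temperature in K.
#' @param n_bins Number of log-spaced frequency bins for the spectrum fit.
#' @return List with `kappa_spectrum`, `corner_frequency`,
#'   `kappa_equipartition` (all pN nm^-1 / Hz), and `flagged` (TRUE when the
#'   Lorentzian fit failed or found no corner inside the band).
#' @export
estimate_trap_stiffness <- function(x, sample_rate = NULL,
                                    bead_radius = 250, temperature = 293,
                                    n_bins = 60L) {
  if (inherits(x, "trap_trace")) {
    sample_rate <- 1 / x$sample_interval
    x <- x$bead_a
  }
  if (is.null(sample_rate)) stop("'sample_rate' is required for a plain vector")
  if (length(x) < 1e5) stop("need at least 1e5 samples of unbound motion")
  gam <- stokes_drag(bead_radius)
  kbt <- thermal_energy(temperature)
  kappa_eq <- kbt / stats::var(x)

  n <- length(x)
  xc <- x - mean(x)
  sp <- abs(stats::fft(xc))^2 * (1 / (sample_rate * n))  # one-sided up to factor 2
  freq <- (seq_len(n) - 1L) * sample_rate / n
  keep <- seq(2L, floor(n / 2))
  freq <- freq[keep]; sp <- 2 * sp[keep]
  ## log-spaced binning tames the exponential scatter of the periodogram
  edges <- exp(seq(log(freq[1]), log(freq[length(freq)]), length.out = n_bins + 1L))
  bin <- cut(freq, edges, include.lowest = TRUE)
  pf <- tapply(sp, bin, mean)
  ff <- tapply(freq, bin, mean)
  ok <- is.finite(pf) & is.finite(ff)
  pf <- as.numeric(pf[ok]); ff <- as.numeric(ff[ok])

  nyquist <- sample_rate / 2
  f0 <- ff[which.min(abs(pf - pf[1] / 2))]  # half-power initial guess
  ## discretely sampled OU: fit the aliased (AR(1)) form of the Lorentzian,
  ## S(f) = s0 (1 - phi^2) / (1 - 2 phi cos(2 pi f dt) + phi^2) with
  ## phi = exp(-2 pi f_c dt); the plain Lorentzian is badly biased when the
  ## corner is not far below the Nyquist frequency
  dtt <- 1 / sample_rate
  fit <- tryCatch(
    minpack.lm::nlsLM(
      log(pf) ~ log(s0 * (1 - exp(-4 * pi * fc * dtt)) /
                      (1 - 2 * exp(-2 * pi * fc * dtt) * cos(2 * pi * ff * dtt) +
                         exp(-4 * pi * fc * dtt))),
      start = list(s0 = pf[1], fc = max(f0, freq[2])),
      lower = c(0, freq[1]), upper = c(Inf, 10 * nyquist),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(kappa_spectrum = NA_real_, corner_frequency = NA_real_,
                kappa_equipartition = kappa_eq, flagged = TRUE))
  }
  fc <- stats::coef(fit)[["fc"]]
  flagged <- !is.finite(fc) || fc >= 0.5 * nyquist
  list(
    kappa_spectrum = if (flagged) NA_real_ else 2 * pi * gam * fc,
    corner_frequency = fc,
    kappa_equipartition = kappa_eq,
    flagged = flagged
  )
}
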