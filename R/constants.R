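## Physical constants and small helpers shared across modules.

## Boltzmann constant in pN nm K^-1
.kB <- 0.0138065

#' Thermal energy
#'
#' @param temperature Temperature in kelvin.
#' @return `k_B * T` in pN nm (4.045 pN nm at 293 K).
#' @export
thermal_energy <- function(temperature = 293) .kB * temperature

#' Stokes drag coefficient of a sphere in water
#'
#' @param bead_radius Bead radius in nm.
#' @param viscosity Dynamic viscosity in Pa s (default: water at 20 C).
#' @return Drag coefficient gamma in pN s nm^-1.
#' @export
stokes_drag <- function(bead_radius = 250, viscosity = 1.002e-3) {
  ## 1 Pa s = 1 N s m^-2 = 1e-6 pN s nm^-2
  6 * pi * (viscosity * 1e-6) * bead_radius
}

## stopifnot-style scalar checks with readable messages
.check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    stop(sprintf("'%s' = %g out of range", name, x), call. = FALSE)
  }
  invisible(x)
}

## centered rolling mean with truncated edge windows
.rolling_mean <- function(x, width) {
  n <- length(x)
  half <- floor(width / 2)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
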