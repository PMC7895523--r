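#' Sliding-window covariance of the two bead positions
#'
#' The change-point observable of the three-bead assay: while the dumbbell
#' fluctuates freely the two bead positions co-vary strongly; myosin binding
#' stiffens the system and the covariance drops. Computed at every sample
#' over a centered window; samples within half a window of either edge use
#' the truncated available window. The instrument dead time (minimum
#' detectable event duration) is half the averaging window.
#'
#' @param trace A [trap_trace()].
#' @param window Averaging window in s (paper-scale choice: 20-30 ms).
#' @return An object of class `cov_series` with fields `times`, `values`
#'   (nm^2), `window`, `dead_time = window / 2`, `sample_interval`,
#'   `molecule_id`.
#' @export
compute_covariance <- function(trace, window = 0.030) {
  if (!inherits(trace, "trap_trace")) stop("'trace' must be a trap_trace")
  dt <- trace$sample_interval
  n <- length(trace$bead_a)
  w <- as.integer(round(window / dt))
  if (w < 3L) stop("window must span at least 3 samples")
  if (w > n) stop("covariance window longer than the trace")
  ## center globally first so the cumulative sums are numerically tame
  a <- trace$bead_a - mean(trace$bead_a)
  b <- trace$bead_b - mean(trace$bead_b)
  half <- floor(w / 2)
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cnt <- hi - lo + 1L
  csa <- cumsum(c(0, a)); csb <- cumsum(c(0, b)); csab <- cumsum(c(0, a * b))
  sa <- csa[hi + 1L] - csa[lo]
  sb <- csb[hi + 1L] - csb[lo]
  sab <- csab[hi + 1L] - csab[lo]
  vals <- (sab - sa * sb / cnt) / (cnt - 1L)
  structure(
    list(times = (i - 1L) * dt, values = vals,
         window = w * dt, dead_time = w * dt / 2,
         sample_interval = dt, molecule_id = trace$molecule_id),
    class = "cov_series"
  )
}

#' @export
print.cov_series <- function(x, ...) {
  cat(sprintf("<cov_series> %s | %d samples | window %.1f ms (dead time %.2f ms)\n",
              x$molecule_id, length(x$values), 1e3 * x$window, 1e3 * x$dead_time))
  invisible(x)
}

#' Peak-separation rule for the bound/unbound covariance decomposition
#'
#' A molecule is analyzable only when the unbound peak mean minus its SD
#' exceeds the bound peak mean plus its SD.
#'
#' @param bound_mean,bound_sd,unbound_mean,unbound_sd Two-Gaussian parameters
#'   in nm^2.
#' @return Logical.
#' @export
covariance_separated <- function(bound_mean, bound_sd, unbound_mean, unbound_sd) {
  (unbound_mean - unbound_sd) > (bound_mean + bound_sd)
}

#' Two-Gaussian decomposition of the covariance distribution
#'
#' Splits the distribution of windowed covariance values into a bound
#' (lower-mean) and an unbound (higher-mean) Gaussian component and evaluates
#' the peak-separation rule. The default route is EM for a two-component
#' unequal-variance 1-D Gaussian mixture; a histogram least-squares fit of
#' the same model is available as a cross-check and the two must agree
#' closely on well-separated data.
#'
#' @param cov A `cov_series` from [compute_covariance()], or a numeric vector
#'   of covariance values.
#' @param method `"em"` (default) or `"histogram"`.
#' @param max_points Cap on the number of values used for fitting; larger
#'   series are thinned deterministically (evenly spaced).
#' @return An object of class `cov_peaks`: `bound_mean`, `bound_sd`,
#'   `unbound_mean`, `unbound_sd`, `mixture_weight` (bound fraction),
#'   `separated`, `method`, `log_likelihood` (EM route).
#' @export
fit_covariance_peaks <- function(cov, method = c("em", "histogram"),
                                 max_points = 20000L) {
  method <- match.arg(method)
  vals <- if (inherits(cov, "cov_series")) cov$values else as.numeric(cov)
  id <- if (inherits(cov, "cov_series")) cov$molecule_id else "values"
  if (length(vals) < 1000L) {
    stop("need at least 1000 covariance samples to decompose peaks")
  }
  if (length(vals) > max_points) {
    vals <- vals[seq(1L, length(vals), length.out = max_points)]
  }
  if (method == "em") {
    fit <- tryCatch(
      Mclust(vals, G = 2, modelNames = "V", verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$parameters)) {
      stop("two-Gaussian EM failed to converge for trace '", id, "'")
    }
    mu <- as.numeric(fit$parameters$mean)
    sd <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
    if (length(sd) == 1L) sd <- rep(sd, 2L)
    pro <- as.numeric(fit$parameters$pro)
    ll <- fit$loglik
  } else {
    h <- .hist_two_gauss(vals)
    mu <- h$mu; sd <- h$sd; pro <- h$pro; ll <- NA_real_
  }
  lo <- which.min(mu); hi <- which.max(mu)
  peaks <- list(
    bound_mean = mu[lo], bound_sd = sd[lo],
    unbound_mean = mu[hi], unbound_sd = sd[hi],
    mixture_weight = pro[lo],
    separated = covariance_separated(mu[lo], sd[lo], mu[hi], sd[hi]),
    method = method, log_likelihood = ll, molecule_id = id
  )
  structure(peaks, class = "cov_peaks")
}

#' @export
print.cov_peaks <- function(x, ...) {
  cat(sprintf(
    "<cov_peaks> bound %.3g +/- %.3g | unbound %.3g +/- %.3g nm^2 | bound fraction %.2f | %s\n",
    x$bound_mean, x$bound_sd, x$unbound_mean, x$unbound_sd, x$mixture_weight,
    if (x$separated) "separated" else "NOT separated"))
  invisible(x)
}

## histogram least-squares two-Gaussian fit with k-means initialization and
## jittered restarts
.hist_two_gauss <- function(vals, bins = 100L, restarts = 10L) {
  h <- graphics::hist(vals, breaks = bins, plot = FALSE)
  x <- h$mids; y <- h$density
  km <- stats::kmeans(vals, centers = range(vals), iter.max = 50)
  ord <- order(km$centers)
  mu0 <- as.numeric(km$centers)[ord]
  sd0 <- vapply(ord, function(cl) stats::sd(vals[km$cluster == cl]), 0)
  pro0 <- as.numeric(table(factor(km$cluster, levels = ord)) / length(vals))
  sd0[!is.finite(sd0) | sd0 <= 0] <- stats::sd(vals) / 4
  best <- NULL
  for (r in seq_len(restarts)) {
    jit <- if (r == 1L) c(1, 1) else exp(stats::runif(2, -0.3, 0.3))
    start <- list(m1 = mu0[1] * jit[1], m2 = mu0[2] * jit[2],
                  s1 = sd0[1], s2 = sd0[2],
                  q = stats::qlogis(min(max(pro0[1], 0.05), 0.95)))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ stats::plogis(q) * stats::dnorm(x, m1, abs(s1)) +
          (1 - stats::plogis(q)) * stats::dnorm(x, m2, abs(s2)),
        start = start, control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) stop("histogram two-Gaussian fit failed to converge")
  cf <- stats::coef(best$fit)
  list(mu = c(cf[["m1"]], cf[["m2"]]),
       sd = abs(c(cf[["s1"]], cf[["s2"]])),
       pro = c(stats::plogis(cf[["q"]]), 1 - stats::plogis(cf[["q"]])))
}
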