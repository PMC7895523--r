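#!/usr/bin/env Rscript

## Step 4 — attachment-duration kinetics by dead-time-truncated MLE.
##
## Draws durations from the published detachment models (single exponentials
## at rate-limiting ATP; fast/slow two-population mixtures at saturating
## ATP), fits single- and two-exponential truncated models, selects the
## order by log-likelihood ratio, bootstraps confidence intervals for the
## flagship mixture, and computes duty ratios from the dominant rates and
## steady-state ATPase rates.

library(trapstroke)

dead_time <- 0.015  # s, half of the 30 ms covariance window
n <- 5000

datasets <- list(
  wt_1uM = list(rates = 6.89, amps = 1, v_max = 5.1),
  wt_saturating = list(rates = c(54.4, 7.5), amps = c(0.97, 0.03), v_max = 5.1),
  r712l_1uM = list(rates = 7.56, amps = 1, v_max = 5.7),
  r712l_saturating = list(rates = c(69.7, 7.4), amps = c(0.91, 0.09), v_max = 5.7)
)

rows <- list()
for (nm in names(datasets)) {
  p <- datasets[[nm]]
  d <- sample_durations(p$rates, p$amps, n, dead_time = dead_time,
                        seed = 7000 + match(nm, names(datasets)))
  fits <- fit_lifetimes(d, dead_time)
  sel <- select_model(fits$order1, fits$order2)
  chosen <- sel$chosen
  ## duty ratio is meaningful only where the dominant rate is the
  ## saturating-ATP detachment rate (the cycle's strongly bound exit)
  duty <- if (length(p$rates) > 1) duty_ratio(chosen$k1, p$v_max)$value else NA
  rows[[nm]] <- data.frame(
    dataset = nm, n = n, order = chosen$model_order,
    k1 = round(chosen$k1, 2), k1_true = p$rates[1],
    k2 = round(chosen$k2, 2),
    A = round(chosen$amplitude_A, 3),
    p_lrt = signif(sel$p_value, 3),
    duty_ratio = round(duty, 3)
  )
  cat(sprintf("%-17s order %d | k1 %.2f /s (true %.2f) | A %s | duty %s\n",
              nm, chosen$model_order, chosen$k1, p$rates[1],
              if (chosen$model_order == 2) sprintf("%.3f", chosen$amplitude_A) else "-",
              if (is.na(duty)) "-" else sprintf("%.3f", duty)))
}

## bootstrap confidence intervals for the wild-type saturating mixture
d <- sample_durations(c(54.4, 7.5), c(0.97, 0.03), n, dead_time = dead_time,
                      seed = 7102)
fit2 <- fit_lifetimes(d, dead_time)$order2
fit2 <- bootstrap_ci(d, dead_time, fit2, n_boot = 1000, seed = 7103)
cat("\nBootstrap 95% CIs (wild-type-like saturating mixture):\n")
print(fit2)

dir.create("results", showWarnings = FALSE)
utils::write.csv(do.call(rbind, rows),
                 file.path("results", "lifetime_fits.csv"), row.names = FALSE)
cat("\nLifetime table written to results/lifetime_fits.csv\n")
cat("Finding: single exponentials suffice at rate-limiting ATP; at\n",
    "saturating ATP the log-likelihood ratio test demands the second,\n",
    "minor slow component, and the recovered rates, fractions and duty\n",
    "ratios track the generating values.\n")
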