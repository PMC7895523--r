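#!/usr/bin/env Rscript

## Step 1 — reference synthetic recordings.
##
## Generates the standard fixture suite: dumbbell traces with ground-truth
## event channels for a wild-type-like two-substep motor, a mutant-like
## single-step motor, a drug-rescued two-substep motor, and two
## fast/slow detachment mixtures. Short (20 s) versions are written here for
## inspection; the heavier analyses below re-simulate at full length from
## the same parameter sets.

library(trapstroke)

out <- file.path("results", "fixtures")
manifest <- make_fixture_suite(out, seed = 20260926, duration = 20,
                               sample_rate = 25000)

cat("Wrote", length(manifest$fixtures), "fixtures to", out, "\n")
for (nm in names(manifest$fixtures)) {
  fx <- manifest$fixtures[[nm]]
  cat(sprintf("  %-18s %3d events | d1 %.2f nm, d2 %.2f nm, k2 %.1f /s, k3 %.1f /s\n",
              nm, fx$n_events, fx$parameters$substep1, fx$parameters$substep2,
              fx$parameters$substep2_rate, fx$parameters$detach_rate))
}
cat("Manifest: ", file.path(out, "manifest.json"), "\n")
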