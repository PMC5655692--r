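#!/usr/bin/env Rscript
# Stage 1: synthetic inflation-extension data.
#
# Generates a protocol-faithful dataset (pressures 20-200 mmHg by 20, axial
# stretches 1.3/1.5, passive and K+-activated states) from a known ground
# truth (IM-layer Heart 1 constants, default synthetic geometry), both
# noiseless and with 2% measurement noise, and reduces the records to
# mean-wall 1st PK stress points.

suppressPackageStartupMessages(library(triaxwall))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L
dir.create("results", showWarnings = FALSE)

k <- published_constants("IM", "Heart 1")
truth <- ground_truth(k$passive, k$active)

clean <- generate_dataset(truth, protocol_spec())
noisy <- generate_dataset(truth, protocol_spec(noise_cv = 0.02, seed = seed))
write_measurements(clean, "results/measurements_noiseless.csv")
write_measurements(noisy, "results/measurements_noisy.csv")

red <- reduce_dataset(noisy, truth$A0, truth$l0)
utils::write.csv(red, "results/reduced_stresses_noisy.csv", row.names = FALSE)

pts <- generate_stress_points(truth, protocol_spec())
utils::write.csv(pts, "results/stress_points_model.csv", row.names = FALSE)

cat(sprintf("generated %d records (seed %d); lam_theta span %.3f-%.3f\n",
            nrow(clean), seed, min(red$lam_theta), max(red$lam_theta)))
cat(sprintf("circumferential stress span %.1f-%.1f kPa (noisy, reduced)\n",
            min(red$T_theta), max(red$T_theta)))
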