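#!/usr/bin/env Rscript
# Diffusion-MRI ADC distributions: simulate five consecutive scans of a
# three-group phantom plate (control, mutant with a +9% ADC offset, and a
# treated group back at control level), run the segmentation -> ADC map ->
# 100-bin distribution -> Fourier denoising -> 2/3-Imax pipeline, and
# compare groups by per-scan relative deviation with a matched t test.

suppressPackageStartupMessages(library(organoidmech))
dir.create("results", showWarnings = FALSE)

wells <- data.frame(
  x = rep(round(96 * c(0.18, 0.50, 0.82)), each = 3),
  y = rep(round(96 * c(0.20, 0.50, 0.80)), times = 3),
  radius = 10,
  group = rep(c("control", "mutant", "treated"), each = 3))

scans <- gen_dwi_phantom(
  grid = c(96, 96), wells = wells,
  adc_mean = c(control = 1.00e-3, mutant = 1.09e-3, treated = 1.01e-3),
  n_scans = 5, snr_b0 = 30, scan_drift = 0.02, seed = 42)

res <- adc_pipeline(scans, reference_group = "control")
write.csv(res$positions, "results/adc_positions.csv", row.names = FALSE)
write.csv(res$comparison$deviations, "results/adc_deviations.csv",
          row.names = FALSE)

cat("Maximal-likelihood ADC positions per scan and group (mm^2/s):\n")
print(reshape(res$positions[c("scan_id", "group", "ml_position")],
              idvar = "scan_id", timevar = "group", direction = "wide"),
      digits = 4, row.names = FALSE)
cat("\nNote the common upward drift over consecutive scans; the per-scan\n")
cat("relative deviation from control removes it.\n\n")
stats <- list()
for (g in names(res$comparison$tests)) {
  t <- res$comparison$tests[[g]]
  cat(sprintf("%s vs control: %+.1f%% +/- %.1f%% (matched t = %.2f, df = %d, p = %.3g)\n",
              g, t$mean_pct, t$sd_pct, t$statistic, t$df, t$p_value))
  stats[[g]] <- t
}
jsonlite::write_json(stats, "results/adc_tests.json", auto_unbox = TRUE,
                     digits = NA)
cat("\nThe injected 9% mutant offset is recovered while the treated group\n")
cat("stays statistically indistinguishable from control.\n")
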