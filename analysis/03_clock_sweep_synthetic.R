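#!/usr/bin/env Rscript
# Generates noise-free synthetic lesions across angular modulation depths,
# runs the full imaging chain (segmentation -> radial profile -> clock-sweep
# statistic), checks recovery of the analytic value 2A, and renders an
# annotated overlay example.

suppressMessages(library(clocksweep))
dir.create("results", recursive = TRUE, showWarnings = FALSE)
seed <- 1L

amps <- c(0.05, 0.1, 0.2, 0.4)
rows <- lapply(seq_along(amps), function(i) {
  spec <- lesion_spec(modulation_amplitude = amps[i], seed = seed + i)
  img <- generate_lesion_image(spec)
  s <- sweep_image(img$image)
  data.frame(amplitude = amps[i],
             analytic = 2 * amps[i],
             measured = s$result$statistic,
             rel_error_pct = 100 * abs(s$result$statistic - 2 * amps[i]) /
                             (2 * amps[i]))
})
recovery <- do.call(rbind, rows)
print(recovery, digits = 4)
cat(sprintf("max relative recovery error: %.2f%%\n",
            max(recovery$rel_error_pct)))
write.csv(recovery, "results/clock_sweep_recovery.csv", row.names = FALSE)

# annotated overlay for the A = 0.2 lesion, with an illustrative risk score
img <- generate_lesion_image(lesion_spec(modulation_amplitude = 0.2,
                                         noise_sd = 4,
                                         boundary_harmonics = data.frame(
                                           order = c(2, 3),
                                           amplitude = c(0.12, 0.05),
                                           phase = c(0.6, 2.1)),
                                         seed = seed))
s <- sweep_image(img$image)
cat(sprintf("example lesion: delta/mean = %.2f (analytic 0.40)\n",
            s$result$statistic))
write_sweep_json(s$result, "results/example_sweep.json")
png::writePNG(render_overlay(img$image, s$mask, s$result, risk_score = 0.17),
              "results/example_overlay.png")
write_run_manifest("results/clock_sweep_manifest.json",
                   config = list(seed = seed, n_angles = 360,
                                 smoothing_window = 5,
                                 amplitudes = amps))
cat("wrote results/clock_sweep_recovery.csv, example_overlay.png,",
    "example_sweep.json\n")
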