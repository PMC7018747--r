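#!/usr/bin/env Rscript
# Analytic information-transfer comparison of the tilt-schemes: per-frequency
# transfer spectra under cumulative-dose damage and tilt-dependent effective
# thickness, and the resulting scheme ranking.

library(tiltbench)

out_dir <- "results/transfer"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

schemes <- benchmark_schemes()[c("continuous", "bidirectional", "DS",
                                 "DS_dec", "DS_inc")]
exposures <- lapply(schemes, assign_dose, 3.5)

spectra <- lapply(exposures, scheme_transfer)
write_transfer_csv(spectra, file.path(out_dir, "transfer_spectra.csv"))

png(file.path(out_dir, "transfer_spectra.png"), width = 900, height = 600)
plot_transfer(spectra, main = "Scheme transfer score vs spatial frequency")
dev.off()

ranking <- rank_schemes(exposures, k_eval = 0.2)
write.csv(ranking, file.path(out_dir, "ranking_k0.2.csv"), row.names = FALSE)
cat("Ranking at k = 0.2 1/A (5 A):\n")
print(ranking, row.names = FALSE)
cat("\nThe dose-symmetric orders transfer the most high-frequency signal;\n")
cat("the continuous scheme loses most of it because its least-exposed\n")
cat("projections are collected at high tilt where the effective thickness\n")
cat("is largest. The constant increment beats the decreasing one; the\n")
cat("increasing increment scores marginally higher still because it packs\n")
cat("projections at low tilt — a gain this spectral proxy credits but that\n")
cat("non-uniform angular sampling erodes in real averaging, which is why\n")
cat("the empirical benchmark still favours the constant increment.\n")
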