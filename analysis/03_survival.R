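#!/usr/bin/env Rscript
# In vivo survival modeling: per-interval LQ survival with protraction on
# a heterogeneous dose-rate map, interval chaining, the radiosensitivity
# sweep, minimal effective dose rates and the internal/external RBE.
suppressPackageStartupMessages(library(prrtdosim))
dir.create("results", showWarnings = FALSE)

truth <- ground_truth()
rb <- truth$radiobiology
spec <- tissue_phantom_spec(grid_shape = c(48, 48, 24), seed = 3)
grid <- generate_tissue(spec)
act <- generate_activity_map(grid, 1, specificity = 0.9)
dose <- convolve_dose(act, build_kernel(), r_max_um = 400)
tumor <- grid$labels == 2L
# spatial shape from the per-decay map, tumor mean anchored to the
# kinetics initial dose rate (30 MBq reference injection)
r0_map <- dose$values / mean(dose$values[grid$labels == 2L]) * truth$kinetics$R0

b <- c(0, 2, 5, 11, 14)
res <- lapply(seq_len(4), function(j) {
  scale_j <- dose_rate(truth$kinetics, b[j] * 24) / truth$kinetics$R0
  survival_map(r0_map * scale_j, truth$kinetics, rb, (b[j + 1] - b[j]) * 24,
               mask = tumor)
})
per_int <- data.frame(interval = paste0(b[1:4], "-", b[2:5], "d"),
                      mean_E = sapply(res, function(r) r$summary[["mean"]]),
                      sd_E = sapply(res, function(r) r$summary[["sd"]]))
print(per_int)
chained <- chain_intervals(res, n_samples = 1e5, seed = 4)
cat(sprintf("chained 0-14 d survival: mean %.3g (sd %.3g)\n",
            chained$summary[["mean"]], chained$summary[["sd"]]))

sweep <- expand.grid(alpha = c(0.1, 0.14, 0.264), alpha_beta = c(5, 10, 100))
sweep$mean_E <- NA; sweep$medr_mGy_h <- NA
for (i in seq_len(nrow(sweep))) {
  rbi <- radiobiology_params(sweep$alpha[i], sweep$alpha_beta[i],
                             T_mu_h = 60, T_D_d = 14.5)
  sweep$mean_E[i] <- survival_map(r0_map, truth$kinetics, rbi, 14 * 24,
                                  mask = tumor)$summary[["mean"]]
  sweep$medr_mGy_h[i] <- minimal_effective_dose_rate(rbi)
}
print(sweep)
cat(sprintf("RBE of the best-matching internal alpha (0.1) vs EBRT (0.264): %.1f\n",
            rbe(0.1, 0.264)))

write.csv(per_int, "results/03_survival_intervals.csv", row.names = FALSE)
write.csv(sweep, "results/03_radiosensitivity_sweep.csv", row.names = FALSE)
cat("wrote results/03_*.csv\n")
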