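#!/usr/bin/env Rscript
# Synthetic tissue phantom -> activity map -> per-decay dose map.
# Compares the heterogeneous tumor S value against the uniform-sphere
# reference of equal tissue volume.
suppressPackageStartupMessages(library(prrtdosim))
dir.create("results", showWarnings = FALSE)

spec <- tissue_phantom_spec(grid_shape = c(64, 64, 32), tumor_fraction = 0.97,
                            seed = 1)
grid <- generate_tissue(spec)
print(grid)
act <- generate_activity_map(grid, total_activity_Bq = 1, specificity = 0.9)

kern <- build_kernel()
print(kern)
# truncated kernel keeps this demonstration grid (0.73 x 0.73 x 0.64 mm)
# fast; the tail beyond 400 um carries ~9% of the energy
dose <- convolve_dose(act, kern, r_max_um = 400)
tumor <- grid$labels == 2L
sv_het <- s_value(dose, tumor)
print(sv_het)

tissue_mm3 <- sum(grid$labels > 0L) * prod(spec$voxel_size_um) / 1e9
sph <- sphere_phantom(volume_mm3 = tissue_mm3, spacing_um = 10)
dose_hom <- convolve_dose(sph$activity, kern, r_max_um = 400)
sv_hom <- s_value(dose_hom, sph$grid$labels == 2L, method = "homogeneous-sphere")
print(sv_hom)

cmp <- compare_s_values(sv_het$S, sv_hom$S)
cat(sprintf("heterogeneous S value is %.1f%% vs the homogeneous sphere\n",
            cmp$percent_diff))

write.csv(data.frame(
  region = c("tumor_heterogeneous", "sphere_homogeneous"),
  S_Gy_per_decay = c(sv_het$S, sv_hom$S),
  n_voxels = c(sv_het$n_voxels, sv_hom$n_voxels)),
  "results/01_s_values.csv", row.names = FALSE)
cat("wrote results/01_s_values.csv\n")
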