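# shared fixtures: packaged kernel (loaded once) and small helpers

lu_kernel <- build_kernel()

# coarse voxel kernels reused across dose-engine tests
coarse_kernel_50 <- kernel_to_voxels(lu_kernel, rep(50, 3))
small_kernel_40 <- kernel_to_voxels(lu_kernel, rep(40, 3), r_max_um = 200)

default_truth <- ground_truth()

ref_kinetics <- kinetic_params(R0 = 10, P = 2, lambda_e = 0.02)

# brute-force pairwise S-value oracle: direct double sum over
# source-target voxel pairs with the resampled voxel kernel
brute_force_dose <- function(activity, voxel_kernel) {
  p <- activity$values / sum(activity$values)
  ctr <- attr(voxel_kernel, "center")
  dk <- dim(voxel_kernel)
  da <- dim(p)
  out <- array(0, dim = da)
  src <- which(p > 0, arr.ind = TRUE)
  for (s in seq_len(nrow(src))) {
    ps <- p[src[s, 1], src[s, 2], src[s, 3]]
    for (x in seq_len(da[1])) for (y in seq_len(da[2])) for (z in seq_len(da[3])) {
      o <- c(x, y, z) - src[s, ] + ctr
      if (all(o >= 1 & o <= dk))
        out[x, y, z] <- out[x, y, z] +
          ps * voxel_kernel[o[1], o[2], o[3]]
    }
  }
  m <- prod(activity$spacing) * 1e-18 * 1000
  out * 1.602176634e-16 / m
}
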