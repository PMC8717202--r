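#' Activity map container
#'
#' @param values numeric 3-D array of per-voxel activities (Bq).
#' @param spacing voxel size, um (length 3).
#' @return object of class `activity_map` with fields `values`, `spacing`,
#'   `total` (Bq).
#' @export
activity_map <- function(values, spacing) {
  if (any(values < 0)) stop("activities must be nonnegative", call. = FALSE)
  structure(list(values = values, spacing = as.numeric(spacing),
                 total = sum(values)),
            class = "activity_map")
}

# smallest highly-composite FFT size >= n (factors 2, 3, 5)
good_fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (f in c(2, 3, 5)) while (m %% f == 0) m <- m / f
    if (m == 1) return(k)
    k <- k + 1
  }
}

#' Convolve an activity map with a dose-point kernel
#'
#' Computes the per-decay 3-D absorbed dose map: decay sites are
#' distributed proportionally to the activity map and each decay deposits
#' energy according to the radial kernel. The convolution is FFT-based
#' with zero padding at least as wide as the kernel support, so energy
#' leaving the grid is physically lost (escape), never wrapped around.
#' Dose is linear in activity; with the kernel fully contained, the
#' deposited energy equals the kernel total.
#'
#' @param activity an `activity_map`.
#' @param kernel a `dose_kernel` (resampled internally), or a prebuilt
#'   voxel kernel array from [kernel_to_voxels()] on the same spacing.
#' @param r_max_um optional kernel truncation radius (um), forwarded to
#'   [kernel_to_voxels()].
#' @return object of class `dose_map`: `values` (Gy per decay), `spacing`,
#'   `units = "Gy/decay"`, plus the total deposited energy fraction
#'   `contained_fraction`.
#' @export
convolve_dose <- function(activity, kernel, r_max_um = NULL) {
  stopifnot(inherits(activity, "activity_map"))
  if (inherits(kernel, "dose_kernel")) {
    K <- kernel_to_voxels(kernel, activity$spacing,
                          r_max_um = if (is.null(r_max_um)) kernel$r_max
                                     else r_max_um)
  } else {
    K <- kernel
    if (!isTRUE(all.equal(attr(K, "spacing"), activity$spacing)))
      stop("voxel kernel spacing does not match the activity grid",
           call. = FALSE)
  }
  A <- activity$values
  if (activity$total <= 0) {
    out <- A * 0
  } else {
    p <- A / activity$total                    # decay-site distribution
    da <- dim(p); dk <- dim(K); ctr <- attr(K, "center")
    dims <- vapply(da + dk - 1L, good_fft_size, numeric(1))
    pa <- array(0, dims); pa[1:da[1], 1:da[2], 1:da[3]] <- p
    pk <- array(0, dims); pk[1:dk[1], 1:dk[2], 1:dk[3]] <- K
    FA <- fft(pa); rm(pa)
    FK <- fft(pk); rm(pk)
    FA <- FA * FK; rm(FK)
    cv <- Re(fft(FA, inverse = TRUE)) / prod(dims)
    rm(FA)
    out <- cv[ctr[1]:(ctr[1] + da[1] - 1L),
              ctr[2]:(ctr[2] + da[2] - 1L),
              ctr[3]:(ctr[3] + da[3] - 1L)]
    out[out < 0] <- 0                          # FFT round-off
    rm(cv)
  }
  m <- voxel_mass(activity$spacing)$mass_kg
  dose <- out * KEV_TO_J / m                   # Gy per decay
  structure(list(values = dose, spacing = activity$spacing,
                 units = "Gy/decay",
                 contained_fraction = sum(out) / attr(K, "total_keV")),
            class = "dose_map")
}

#' Uniform water sphere phantom
#'
#' Voxelized sphere of water with uniform activity, the homogeneous
#' reference geometry against which heterogeneous exposures are compared.
#' The default volume, 24.1 mm^3, matches a 507 x 507 x 289 voxel stack at
#' 5.7 x 5.7 x 10 um pitch (radius ~1.79 mm).
#'
#' @param volume_mm3 sphere volume, mm^3.
#' @param spacing_um isotropic voxel pitch, um.
#' @param total_activity_Bq total activity placed uniformly in the sphere.
#' @return list with `grid` (a `voxel_grid`, tumor-labeled sphere),
#'   `activity` (an `activity_map`) and `radius_um`.
#' @export
sphere_phantom <- function(volume_mm3 = 24.1, spacing_um = 20,
                           total_activity_Bq = 1) {
  if (volume_mm3 <= 0) stop("volume must be positive", call. = FALSE)
  r_um <- (3 * volume_mm3 / (4 * pi))^(1 / 3) * 1000
  n_half <- ceiling(r_um / spacing_um)
  n <- 2L * as.integer(n_half) + 1L
  if ((4 / 3 * pi * r_um^3) / spacing_um^3 < 1000)
    stop("volume too small for >= 1000 voxels at this pitch; ",
         "reduce `spacing_um`", call. = FALSE)
  ax <- (seq_len(n) - (n_half + 1)) * spacing_um
  r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  inside <- r2 <= r_um^2
  labels <- array(0L, dim = c(n, n, n)); labels[inside] <- 2L
  grid <- voxel_grid(c(n, n, n), rep(spacing_um, 3), labels = labels)
  act <- array(0, dim = c(n, n, n))
  act[inside] <- total_activity_Bq / sum(inside)
  list(grid = grid,
       activity = activity_map(act, rep(spacing_um, 3)),
       radius_um = r_um)
}

#' Region S value
#'
#' Mean absorbed dose per decay over a region. With uniform (water)
#' density the mass-weighted mean reduces to the arithmetic mean over the
#' region's voxels.
#'
#' @param dose_map a `dose_map` in Gy/decay.
#' @param mask logical array selecting the region.
#' @param method tag recorded in the result.
#' @return object of class `svalue_result`: `S` (Gy/decay), `n_voxels`,
#'   `method`.
#' @export
s_value <- function(dose_map, mask, method = "heterogeneous") {
  stopifnot(inherits(dose_map, "dose_map"))
  if (!any(mask)) stop("empty region mask", call. = FALSE)
  structure(list(S = mean(dose_map$values[mask]), n_voxels = sum(mask),
                 method = method),
            class = "svalue_result")
}

#' @export
print.svalue_result <- function(x, ...) {
  cat(sprintf("S value [%s]: %.4e Gy/decay over %d voxels\n",
              x$method, x$S, x$n_voxels))
  invisible(x)
}

# decays per hour at time t for an injected activity following the
# normalized biexponential retention shape of `params`
decays_per_hour <- function(params, injected_MBq, t_h) {
  shape <- dose_rate(params, t_h) / params$R0[1]
  injected_MBq * 1e6 * 3600 * shape
}

#' Scale a per-decay dose map to a dose-rate map
#'
#' The voxel dose rate at time `t_h` is the per-decay dose map times the
#' decay rate implied by the biexponential retention time course,
#' normalized to the injected activity (the shape is the kinetics model
#' divided by its initial amplitude).
#'
#' @param dose_map per-decay `dose_map` (Gy/decay).
#' @param params `kinetic_params` giving the retention shape.
#' @param injected_MBq injected activity, MBq.
#' @param t_h time, hours.
#' @return `dose_map` with `units = "mGy/h"`.
#' @export
scale_to_dose_rate <- function(dose_map, params, injected_MBq, t_h) {
  stopifnot(inherits(dose_map, "dose_map"),
            identical(dose_map$units, "Gy/decay"))
  rate <- dose_map$values * decays_per_hour(params, injected_MBq, t_h) * 1000
  structure(list(values = rate, spacing = dose_map$spacing, units = "mGy/h",
                 t_h = t_h),
            class = "dose_map")
}

#' Absorbed dose over a time interval
#'
#' Integrates the dose-rate map between `t1_h` and `t2_h` (hours;
#' `t2_h = Inf` gives the dose to complete decay), using the closed-form
#' integral of the retention shape.
#'
#' @inheritParams scale_to_dose_rate
#' @param t1_h,t2_h interval boundaries, hours, `t2_h > t1_h`.
#' @return `dose_map` with `units = "Gy"`.
#' @export
integrate_interval <- function(dose_map, params, injected_MBq, t1_h, t2_h) {
  stopifnot(inherits(dose_map, "dose_map"),
            identical(dose_map$units, "Gy/decay"))
  if (!(t2_h > t1_h)) stop("need t2_h > t1_h", call. = FALSE)
  # cumulative decays: integral of the normalized shape, per unit R0
  cum <- cumulative_dose(kinetic_params(1, params$P / params$R0[1],
                                        params$lambda_e, params$lambda_p),
                         c(t1_h, t2_h))
  n_decays <- injected_MBq * 1e6 * 3600 * diff(cum)
  structure(list(values = dose_map$values * n_decays,
                 spacing = dose_map$spacing, units = "Gy",
                 t_h = c(t1_h, t2_h)),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("dose_map [%s]: %s voxels, mean %.4g, max %.4g\n",
              x$units, paste(dim(x$values), collapse = " x "),
              mean(x$values), max(x$values)))
  invisible(x)
}
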