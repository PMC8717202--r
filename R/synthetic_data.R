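#' Tissue phantom specification
#'
#' Parameters of the synthetic excised-tissue phantom: grid shape and
#' voxel size, the fraction of tissue voxels that are tumor (excised NCI-H69
#' xenograft sections are typically 94-100% tumor), the correlation length and contrast of
#' the receptor-expression-like intensity field, and the generation seed.
#'
#' The default grid is 128 x 128 x 64 voxels at 11.4 x 11.4 x 20 um
#' (twice the 5.7 x 5.7 x 10 um pitch of full-resolution tissue stacks)
#' so full runs stay at desk
#' scale; the full-resolution shape is supported but not the default.
#'
#' @param grid_shape three positive integers, voxels.
#' @param voxel_size_um three positive voxel sizes, um.
#' @param tumor_fraction fraction of tissue voxels labeled tumor, in
#'   `[0, 1]`.
#' @param expression_correlation_length_um correlation length of the
#'   expression field, um (> 0).
#' @param expression_contrast ratio of high/low expression intensity
#'   modes (> 1 gives heterogeneity; must be >= 1).
#' @param seed integer generation seed.
#' @return object of class `tissue_phantom_spec`.
#' @export
tissue_phantom_spec <- function(grid_shape = c(128, 128, 64),
                                voxel_size_um = c(11.4, 11.4, 20),
                                tumor_fraction = 0.97,
                                expression_correlation_length_um = 50,
                                expression_contrast = 4,
                                seed = 1) {
  if (length(grid_shape) != 3 || any(grid_shape <= 0) ||
      any(grid_shape != round(grid_shape)))
    stop("grid_shape must be three positive integers", call. = FALSE)
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0))
    stop("voxel sizes must be strictly positive", call. = FALSE)
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must be in [0, 1]", call. = FALSE)
  if (expression_correlation_length_um <= 0)
    stop("correlation length must be positive", call. = FALSE)
  if (expression_contrast < 1)
    stop("expression_contrast must be >= 1", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_um = as.numeric(voxel_size_um),
                 tumor_fraction = tumor_fraction,
                 expression_correlation_length_um =
                   expression_correlation_length_um,
                 expression_contrast = expression_contrast,
                 seed = as.integer(seed)),
            class = "tissue_phantom_spec")
}

# stationary gaussian random field with squared-exponential covariance,
# spectral (FFT) synthesis on a periodic grid; returns a standardized array
gaussian_random_field <- function(dim, spacing, corr_len) {
  freqs <- function(n, h) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]
    k / (n * h)
  }
  fs <- lapply(seq_along(dim), function(ax) freqs(dim[ax], spacing[ax])^2)
  f2 <- if (length(dim) == 2) outer(fs[[1]], fs[[2]], `+`) else
    outer(outer(fs[[1]], fs[[2]], `+`), fs[[3]], `+`)
  amp <- exp(-pi^2 * corr_len^2 * f2)   # sqrt of SE spectral density
  w <- array(rnorm(prod(dim)), dim = dim)
  g <- Re(fft(fft(w) * amp, inverse = TRUE)) / prod(dim)
  (g - mean(g)) / sd(g)
}

#' Generate a synthetic tissue phantom
#'
#' Builds a labeled voxel grid (background / healthy / tumor) with a
#' spatially correlated, strictly positive expression-intensity field.
#' Tissue occupies a centered ellipsoid; tumor voxels are the top
#' `tumor_fraction` quantile of a second, independent correlated field,
#' so the generated tumor fraction matches the requested value within one voxel of
#' rounding. The expression field is an exponentiated gaussian random
#' field with squared-exponential covariance: log-intensity sd is
#' `log(contrast)/4`, so +/-2 sd of the field spans a factor `contrast`.
#' Bit-reproducible for a fixed seed.
#'
#' @param spec a `tissue_phantom_spec`.
#' @return a `voxel_grid` with `labels` and `expression`.
#' @export
generate_tissue <- function(spec) {
  stopifnot(inherits(spec, "tissue_phantom_spec"))
  d <- spec$grid_shape; h <- spec$voxel_size_um
  withr::with_seed(spec$seed, {
    g_expr <- gaussian_random_field(d, h, spec$expression_correlation_length_um)
    g_lab <- gaussian_random_field(d, h, spec$expression_correlation_length_um)
    # centered ellipsoid tissue region (fraction of half-extent 0.95)
    ctr <- (d + 1) / 2
    axs <- lapply(1:3, function(ax) ((seq_len(d[ax]) - ctr[ax]) /
                                       (0.95 * d[ax] / 2))^2)
    r2 <- outer(outer(axs[[1]], axs[[2]], `+`), axs[[3]], `+`)
    tissue <- r2 <= 1
    labels <- array(0L, dim = d)
    n_tissue <- sum(tissue)
    n_tumor <- round(spec$tumor_fraction * n_tissue)
    if (n_tumor > 0) {
      vals <- g_lab[tissue]
      thr <- sort(vals, decreasing = TRUE)[n_tumor]
      lab_t <- ifelse(vals >= thr, 2L, 1L)
      # exact count under ties
      if (sum(lab_t == 2L) > n_tumor) {
        extra <- which(lab_t == 2L & vals == thr)
        lab_t[extra[seq_len(sum(lab_t == 2L) - n_tumor)]] <- 1L
      }
      labels[tissue] <- lab_t
    } else {
      labels[tissue] <- 1L
    }
    sdl <- log(spec$expression_contrast) / 4
    expr <- array(0, dim = d)
    expr[tissue] <- exp(sdl * g_expr[tissue])
    voxel_grid(d, h, labels = labels, expression = expr)
  })
}

#' Generate an activity map from a tissue phantom
#'
#' Distributes a total activity over the phantom: a fraction
#' `specificity` binds to tumor voxels proportionally to their expression
#' intensity; the remainder spreads uniformly over all tissue voxels.
#' The map sums to `total_activity_Bq` exactly (floating tolerance).
#'
#' @param grid a `voxel_grid` with labels and expression.
#' @param total_activity_Bq total activity, Bq (>= 0).
#' @param specificity bound fraction in `[0, 1]`.
#' @return an `activity_map`.
#' @export
generate_activity_map <- function(grid, total_activity_Bq,
                                  specificity = 0.9) {
  stopifnot(inherits(grid, "voxel_grid"),
            !is.null(grid$labels), !is.null(grid$expression))
  if (total_activity_Bq < 0) stop("activity must be >= 0", call. = FALSE)
  if (specificity < 0 || specificity > 1)
    stop("specificity must be in [0, 1]", call. = FALSE)
  tumor <- grid$labels == 2L
  tissue <- grid$labels > 0L
  vals <- array(0, dim = grid$dim)
  if (specificity > 0) {
    if (!any(tumor)) stop("no tumor voxels to bind activity to", call. = FALSE)
    w <- grid$expression * tumor
    vals <- vals + total_activity_Bq * specificity * w / sum(w)
  }
  if (specificity < 1) {
    vals[tissue] <- vals[tissue] +
      total_activity_Bq * (1 - specificity) / sum(tissue)
  }
  activity_map(vals, grid$spacing)
}

#' Simulation ground truth
#'
#' Bundles the true parameter values behind the synthetic data so
#' downstream fits can be checked closed-loop: dose-rate kinetics,
#' radiobiology (repair half-life 60 h, doubling time 14.5 d,
#' alpha 0.14 Gy^-1 at alpha/beta 100 Gy by default), the DSB yield per
#' cell per mGy (default 0.0223), the initial foci level, and
#' piecewise-exponential growth rates chosen so the regrowth doubling
#' time equals the radiobiology `T_D_d`.
#'
#' @param kinetics a `kinetic_params`; default R0 = 48 mGy/h with a 10%
#'   plateau and 48 h effective half-life (giving ~1.7 Gy over the first
#'   2 days, matching the observed per-section dose scale).
#' @param radiobiology a `radiobiology_params`.
#' @param dsb_yield DSB per cell per mGy (>= 0).
#' @param foci0 initial gammaH2AX foci per cell for the repair series.
#' @param growth list with `V0` (mm^3), rates `k0`, `k1`, `k2` (1/d) and
#'   onsets `T0_d`, `T1_d` (days).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(kinetics = kinetic_params(R0 = 48, P = 4.8,
                                                   lambda_e = log(2) / 48),
                         radiobiology = radiobiology_params(
                           alpha = 0.14, alpha_beta = 100,
                           T_mu_h = 60, T_D_d = 14.5),
                         dsb_yield = 0.0223,
                         foci0 = 25,
                         growth = NULL) {
  if (dsb_yield < 0) stop("dsb_yield must be >= 0", call. = FALSE)
  if (is.null(growth)) {
    # pick k2 so that ln2/(k0 - k1 + k2) equals the radiobiology T_D
    k0 <- 0.25; k1 <- 0.35
    k2 <- log(2) / radiobiology$T_D_d - k0 + k1
    growth <- list(V0 = 200, k0 = k0, k1 = k1, k2 = k2, T0_d = 3, T1_d = 7)
  }
  stopifnot(all(c("V0", "k0", "k1", "k2", "T0_d", "T1_d") %in% names(growth)))
  if (growth$T0_d >= growth$T1_d) stop("need T0 < T1", call. = FALSE)
  structure(list(kinetics = kinetics, radiobiology = radiobiology,
                 dsb_yield = dsb_yield, foci0 = foci0, growth = growth),
            class = "ground_truth")
}

# mean-one multiplicative lognormal noise
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a biodistribution (time-activity) series
#'
#' Bound-activity values following the biexponential dose-rate shape of
#' the ground-truth kinetics, with mean-one multiplicative lognormal
#' noise of the stated coefficient of variation.
#'
#' @param truth a `ground_truth`.
#' @param times_h sampling times, hours (nonempty).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return data.frame with `t_h` and `value` (mGy/h scale of the truth
#'   kinetics).
#' @export
generate_biodistribution <- function(truth, times_h, noise_cv = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(times_h) == 0) stop("empty time vector", call. = FALSE)
  mu <- dose_rate(truth$kinetics, times_h)
  noise <- withr::with_seed(seed, lognormal_noise(length(times_h), noise_cv))
  data.frame(t_h = times_h, value = mu * noise)
}

#' Generate a gammaH2AX foci decay series
#'
#' Mean foci per cell decay mono-exponentially with the ground-truth
#' repair half-life; the observed value at each time point is the mean of
#' `n_cells` Poisson counts. `n_cells = Inf` returns the noiseless curve.
#'
#' @param truth a `ground_truth`.
#' @param times_h sampling times, hours.
#' @param n_cells cells scored per time point (> 0; `Inf` = noiseless).
#' @param seed integer seed.
#' @return data.frame with `t_h` and `foci_per_cell`.
#' @export
generate_foci_series <- function(truth, times_h, n_cells = 500, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(times_h) == 0) stop("empty time vector", call. = FALSE)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  m <- truth$foci0 * exp(-truth$radiobiology$mu * times_h)
  y <- if (is.infinite(n_cells)) m else
    withr::with_seed(seed, rpois(length(m), n_cells * m) / n_cells)
  data.frame(t_h = times_h, foci_per_cell = y)
}

#' Generate a tumor-volume curve
#'
#' Volumes follow the piecewise-exponential growth model
#' ([growth_model()]) of the ground truth, with mean-one multiplicative
#' lognormal noise.
#'
#' @param truth a `ground_truth`.
#' @param times_d sampling times, days.
#' @param noise_cv coefficient of variation of the noise.
#' @param seed integer seed.
#' @return data.frame with `t_d` and `volume_mm3`.
#' @export
generate_volume_curve <- function(truth, times_d, noise_cv = 0, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(times_d) == 0) stop("empty time vector", call. = FALSE)
  g <- truth$growth
  v <- growth_model(times_d, g$V0, g$k0, g$k1, g$k2, g$T0_d, g$T1_d)
  noise <- withr::with_seed(seed, lognormal_noise(length(v), noise_cv))
  data.frame(t_d = times_d, volume_mm3 = v * noise)
}

#' Generate a costained high-resolution section
#'
#' Emulates a small costained tissue section: a 2-D correlated
#' expression image at the dose map's resolution, plus `n_cells` cells at
#' uniform random pixel positions whose DSB counts are Poisson with mean
#' `dsb_yield x local absorbed dose` (mGy). The section metadata records
#' the true mean dose over the section.
#'
#' @param truth a `ground_truth`.
#' @param dose_map_2d numeric matrix of absorbed dose, mGy.
#' @param n_cells number of scored cells (> 0).
#' @param seed integer seed.
#' @param dim expected image dimensions; defaults to `dim(dose_map_2d)`
#'   and errors on mismatch.
#' @param corr_len_px correlation length of the expression image, pixels.
#' @param contrast expression contrast (high/low intensity ratio).
#' @param tiff_path optional path; writes the expression image as 16-bit
#'   TIFF.
#' @return list of class `costained_section`: `image`, `cells`
#'   (data.frame x, y, dose_mGy, dsb), `mean_dose_mGy`, `mean_dsb`,
#'   `n_cells`.
#' @export
generate_costained_section <- function(truth, dose_map_2d, n_cells = 2000,
                                       seed = 1, dim = NULL,
                                       corr_len_px = 40, contrast = 4,
                                       tiff_path = NULL) {
  stopifnot(inherits(truth, "ground_truth"), is.matrix(dose_map_2d))
  if (!is.null(dim) && !identical(as.integer(dim), base::dim(dose_map_2d)))
    stop("dose map shape mismatch", call. = FALSE)
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (any(dose_map_2d < 0)) stop("doses must be >= 0", call. = FALSE)
  d <- base::dim(dose_map_2d)
  out <- withr::with_seed(seed, {
    g <- gaussian_random_field(d, c(1, 1), corr_len_px)
    img <- exp(log(contrast) / 4 * g)
    ix <- sample.int(d[1], n_cells, replace = TRUE)
    iy <- sample.int(d[2], n_cells, replace = TRUE)
    dose <- dose_map_2d[cbind(ix, iy)]
    dsb <- rpois(n_cells, truth$dsb_yield * dose)
    list(img = img, cells = data.frame(x = ix, y = iy, dose_mGy = dose,
                                       dsb = dsb))
  })
  if (!is.null(tiff_path)) {
    norm <- out$img / max(out$img)
    tiff::writeTIFF(norm, tiff_path, bits.per.sample = 16)
  }
  structure(list(image = out$img, cells = out$cells,
                 mean_dose_mGy = mean(dose_map_2d),
                 mean_dsb = mean(out$cells$dsb),
                 n_cells = n_cells),
            class = "costained_section")
}
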