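test_that("phantom spec validates its inputs", {
  expect_error(tissue_phantom_spec(grid_shape = c(0, 10, 10)), "positive")
  expect_error(tissue_phantom_spec(voxel_size_um = c(5, -1, 5)), "positive")
  expect_error(tissue_phantom_spec(tumor_fraction = 1.2), "tumor_fraction")
  expect_error(tissue_phantom_spec(expression_correlation_length_um = 0),
               "correlation length")
})

test_that("tissue generation honors labels, tumor fraction and seed", {
  spec <- tissue_phantom_spec(grid_shape = c(32, 32, 16),
                              tumor_fraction = 1.0, seed = 11)
  g <- generate_tissue(spec)
  # boundary case: every tissue voxel is tumor
  expect_true(all(g$labels[g$labels > 0L] == 2L))
  expect_equal(tumor_fraction(g), 1.0)

  for (tf in c(0.94, 0.97)) {
    spec2 <- tissue_phantom_spec(grid_shape = c(32, 32, 16),
                                 tumor_fraction = tf, seed = 3)
    g2 <- generate_tissue(spec2)
    n_tissue <- sum(g2$labels > 0L)
    # label fractions match within one voxel of rounding
    expect_lte(abs(sum(g2$labels == 2L) - tf * n_tissue), 1)
    # expression positive inside tissue, zero outside
    expect_true(all(g2$expression[g2$labels > 0L] > 0))
    expect_true(all(g2$expression[g2$labels == 0L] == 0))
  }

  # bit-reproducible for a fixed seed, different for another
  ga <- generate_tissue(spec)
  expect_identical(ga$expression, g$expression)
  expect_identical(ga$labels, g$labels)
  gb <- generate_tissue(tissue_phantom_spec(grid_shape = c(32, 32, 16),
                                            tumor_fraction = 1.0, seed = 12))
  expect_false(identical(gb$expression, g$expression))
})

test_that("expression field has the requested correlation length", {
  # radially averaged autocorrelation of the generated field crosses
  # exp(-1/2) near the squared-exponential correlation length
  spec <- tissue_phantom_spec(grid_shape = c(128, 128, 128),
                              voxel_size_um = c(11.4, 11.4, 11.4),
                              tumor_fraction = 1,
                              expression_correlation_length_um = 50,
                              seed = 5)
  g <- generate_tissue(spec)
  f <- log(g$expression)
  f[g$labels == 0L] <- 0          # analyze the log-field on the full grid
  f <- f - mean(f)
  Fhat <- fft(f)
  ac <- Re(fft(Fhat * Conj(Fhat), inverse = TRUE)) / length(f)
  ac <- ac / ac[1, 1, 1]
  # autocorrelation along the first axis (radial average over 3 axes)
  prof <- (ac[1:20, 1, 1] + ac[1, 1:20, 1] + ac[1, 1, 1:20]) / 3
  r_um <- (0:19) * 11.4
  cross <- approx(prof, r_um, xout = exp(-0.5))$y
  expect_lt(abs(cross - 50) / 50, 0.25)
})

test_that("activity maps conserve activity and respect specificity", {
  spec <- tissue_phantom_spec(grid_shape = c(24, 24, 12),
                              tumor_fraction = 0.9, seed = 2)
  g <- generate_tissue(spec)

  a1 <- generate_activity_map(g, 1e6, specificity = 1)
  expect_equal(a1$total, 1e6, tolerance = 1e-9)
  expect_true(all(a1$values[g$labels != 2L] == 0))

  # specificity 0: uniform over all tissue voxels (direct summation)
  a0 <- generate_activity_map(g, 5e5, specificity = 0)
  tissue_vals <- a0$values[g$labels > 0L]
  expect_equal(sum(tissue_vals), 5e5, tolerance = 1e-9)
  expect_lt(diff(range(tissue_vals)), 1e-12 * max(tissue_vals))
  expect_true(all(a0$values[g$labels == 0L] == 0))

  # uniform expression -> uniform activity over tumor voxels
  gu <- g
  gu$expression[gu$labels > 0L] <- 2.5
  au <- generate_activity_map(gu, 1e4, specificity = 1)
  tv <- au$values[gu$labels == 2L]
  expect_lt(diff(range(tv)), 1e-12 * max(tv))

  expect_error(generate_activity_map(g, -1), ">= 0")
})

test_that("biodistribution series follow the kinetics with stated noise", {
  tr <- default_truth
  tt <- c(0, 2, 6, 12, 24, 48, 96, 168)
  noiseless <- generate_biodistribution(tr, tt, noise_cv = 0)
  expect_equal(noiseless$value, dose_rate(tr$kinetics, tt))
  expect_equal(noiseless$value[1], tr$kinetics$R0)  # t = 0 amplitude
  expect_error(generate_biodistribution(tr, numeric(0)), "empty")

  # closed loop: refit recovers lambda_e within 15% at CV 10%, n = 8
  noisy <- generate_biodistribution(tr, tt, noise_cv = 0.1, seed = 42)
  fit <- fit_biexponential(noisy)
  expect_lt(abs(fit$params$lambda_e - tr$kinetics$lambda_e) /
              tr$kinetics$lambda_e, 0.15)
})

test_that("foci series decay with the truth half-life", {
  tr <- default_truth
  tmu <- tr$radiobiology$T_mu_h
  noiseless <- generate_foci_series(tr, c(0, tmu), n_cells = Inf)
  expect_equal(noiseless$foci_per_cell[2], noiseless$foci_per_cell[1] / 2)
  expect_error(generate_foci_series(tr, c(0, 10), n_cells = 0), "positive")
  s1 <- generate_foci_series(tr, 0:5 * 24, n_cells = 300, seed = 9)
  s2 <- generate_foci_series(tr, 0:5 * 24, n_cells = 300, seed = 9)
  expect_identical(s1, s2)
})

test_that("volume curves follow the piecewise growth model", {
  tr0 <- ground_truth(growth = list(V0 = 150, k0 = 0.2, k1 = 0, k2 = 0,
                                    T0_d = 3, T1_d = 7))
  tt <- seq(0, 14, by = 2)
  v <- generate_volume_curve(tr0, tt)
  # k1 = k2 = 0: pure exponential growth
  expect_equal(v$volume_mm3, 150 * exp(0.2 * tt))

  # noiseless closed loop: rates recovered to 4 significant digits
  tr <- default_truth
  vc <- generate_volume_curve(tr, seq(0, 21, by = 1.5))
  fit <- fit_growth(vc, T0_d = tr$growth$T0_d)
  expect_equal(fit$k0, tr$growth$k0, tolerance = 1e-4)
  expect_equal(fit$k1, tr$growth$k1, tolerance = 1e-4)
  expect_equal(fit$k2, tr$growth$k2, tolerance = 1e-4)
})

test_that("costained sections draw Poisson DSB counts from the dose", {
  tr <- default_truth
  dm <- matrix(1700, 48, 48)

  zero <- ground_truth(dsb_yield = 0)
  s0 <- generate_costained_section(zero, dm, n_cells = 200, seed = 1)
  expect_true(all(s0$cells$dsb == 0))

  # Poisson law: sample mean -> yield * dose within 3 SE at n = 1e4
  s <- generate_costained_section(tr, dm, n_cells = 1e4, seed = 4)
  mu <- tr$dsb_yield * 1700
  se <- sqrt(mu / 1e4)
  expect_lt(abs(s$mean_dsb - mu), 3 * se)
  expect_equal(s$mean_dose_mGy, 1700)

  s2 <- generate_costained_section(tr, dm, n_cells = 1e4, seed = 4)
  expect_identical(s$cells, s2$cells)

  expect_error(generate_costained_section(tr, dm, dim = c(32, 32)),
               "shape mismatch")
})
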