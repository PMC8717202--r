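test_that("Lea-Catcheside factor has the correct limits", {
  p <- ref_kinetics
  # no-repair limit: G -> 1
  expect_equal(lea_catcheside_G(p, mu = 1e-12, t_h = 1e6), 1,
               tolerance = 1e-6)
  # P = 0, t -> Inf: G = lambda_e / (lambda_e + mu)
  p0 <- kinetic_params(10, 0, 0.03)
  for (mu in c(0.005, 0.0116, 0.2)) {
    expect_equal(lea_catcheside_G(p0, mu, Inf), 0.03 / (0.03 + mu),
                 tolerance = 1e-12)
  }
  # quadrature cross-check of the P = 0 reduction at large t
  expect_equal(lea_catcheside_G_quad(p0, 0.0116, 4000),
               0.03 / (0.03 + 0.0116), tolerance = 1e-5)
  expect_error(lea_catcheside_G(p, mu = 0, t_h = 10), "mu")
  expect_error(lea_catcheside_G(p, mu = 0.01, t_h = 0), "t_h")
})

test_that("closed-form G agrees with the double-integral quadrature", {
  # the printed closed form is validated against the generic definition
  p <- kinetic_params(R0 = 10, P = 1, lambda_e = 0.03,
                      lambda_p = 0.00434)
  g_cf <- lea_catcheside_G(p, mu = 0.01155, t_h = 120)
  g_q <- lea_catcheside_G_quad(p, mu = 0.01155, t_h = 120)
  expect_equal(g_cf, g_q, tolerance = 1e-6)

  # random parameter sweep away from rate degeneracies
  set.seed(41)
  for (i in 1:30) {
    le <- runif(1, 0.008, 0.1)
    mu <- runif(1, 0.005, 0.05)
    if (min(abs(mu - le), abs(mu - log(2) / 159.528)) < 1e-4) next
    pp <- kinetic_params(runif(1, 5, 60), runif(1, 0, 4), le)
    tt <- runif(1, 24, 500)
    expect_equal(lea_catcheside_G(pp, mu, tt),
                 lea_catcheside_G_quad(pp, mu, tt), tolerance = 1e-6)
  }

  # G monotone nonincreasing in mu; G in (0, 1]
  mus <- c(0.001, 0.005, 0.02, 0.08)
  gs <- vapply(mus, function(m) lea_catcheside_G(p, m, 120), numeric(1))
  expect_true(all(diff(gs) < 0))
  expect_true(all(gs > 0 & gs <= 1))

  # near-degenerate rates fall back to quadrature without error
  pd <- kinetic_params(10, 1, 0.02)
  expect_equal(lea_catcheside_G(pd, mu = 0.02 + 1e-8, t_h = 100),
               lea_catcheside_G_quad(pd, mu = 0.02 + 1e-8, t_h = 100),
               tolerance = 1e-9)
})

test_that("LQ survival evaluates and respects monotonicity", {
  rb <- radiobiology_params(0.14, 100, T_mu_h = 60, T_D_d = 14.5)
  # D = 0 -> pure repopulation
  expect_equal(survival_lq(rb, 0, 1, 240), exp(rb$gamma * 240))
  # gamma = 0, beta = 0 (alpha/beta -> Inf), D = 1/alpha -> 1/e
  rb0 <- radiobiology_params(0.5, 1e12, T_mu_h = 60)
  expect_equal(survival_lq(rb0, 1 / 0.5, 1, 100), exp(-1), tolerance = 1e-9)
  # direct re-evaluation
  rb1 <- radiobiology_params(0.14, 100, T_mu_h = 60, T_D_d = 14.5)
  gt <- 0.1 / rb1$gamma
  expect_equal(survival_lq(rb1, 3, 0.5, gt),
               exp(0.1) * exp(-0.14 * 3 - 0.5 * 0.0014 * 9))
  # monotone nonincreasing in D and in alpha
  ds <- seq(0, 10, by = 0.5)
  es <- survival_lq(rb1, ds, 0.7, 0)
  expect_true(all(diff(es) < 0))
  e_lo <- survival_lq(radiobiology_params(0.1, 100, 60), 5, 0.7, 0)
  e_hi <- survival_lq(radiobiology_params(0.3, 100, 60), 5, 0.7, 0)
  expect_lt(e_hi, e_lo)
  expect_error(survival_lq(rb1, -1, 1, 0), ">= 0")
  expect_error(survival_lq(rb1, 1, 0, 0), "G")
})

test_that("survival_map equals the scalar pipeline on uniform maps", {
  rb <- radiobiology_params(0.14, 100, T_mu_h = 60, T_D_d = 14.5)
  tmpl <- default_truth$kinetics
  r0 <- array(35, dim = c(6, 6, 3))
  sm <- survival_map(r0, tmpl, rb, t_h = 48)
  avg <- survival_map(r0, tmpl, rb, t_h = 48, average_approach = TRUE)
  expect_true(all(sm$E == sm$E[1]))
  expect_equal(sm$E, avg$E)
  # scalar pipeline
  unit <- kinetic_params(1, tmpl$P / tmpl$R0, tmpl$lambda_e, tmpl$lambda_p)
  D <- 35 * cumulative_dose(unit, 48)
  G <- lea_catcheside_G(unit, rb$mu, 48)
  expect_equal(sm$E[1], survival_lq(rb, D / 1000, G, 48))

  # zero activity -> pure repopulation everywhere
  sz <- survival_map(array(0, dim = c(4, 4, 2)), tmpl, rb, t_h = 48)
  expect_true(all(sz$E == exp(rb$gamma * 48)))

  # heterogeneous map: mean log-survival <= log of average-approach
  # survival (Jensen on the concave -G beta D^2 exponent)
  set.seed(7)
  rh <- array(rexp(96, 1 / 35), dim = c(8, 4, 3))
  sh <- survival_map(rh, tmpl, rb, t_h = 48)
  sa <- survival_map(rh, tmpl, rb, t_h = 48, average_approach = TRUE)
  expect_lte(mean(log(sh$E)), log(sa$E[1]) + 1e-12)
})

test_that("interval chaining composes survival distributions", {
  rb <- radiobiology_params(0.14, 100, T_mu_h = 60, T_D_d = 14.5)
  tmpl <- default_truth$kinetics
  set.seed(11)
  r0 <- array(rexp(60, 1 / 30), dim = c(5, 4, 3))
  s1 <- survival_map(r0, tmpl, rb, t_h = 48)

  # a single interval reproduces the survival_map distribution
  ch1 <- chain_intervals(list(s1), n_samples = 2e4, seed = 5)
  expect_equal(mean(ch1$samples), s1$summary[["mean"]], tolerance = 0.02)

  # all-zero doses over a 14 d schedule: point mass at exp(gamma * 14 d)
  z <- survival_map(array(0, dim = c(4, 4, 1)), tmpl, rb, t_h = 14 * 24)
  chz <- chain_intervals(list(z), n_samples = 100, seed = 1)
  expect_true(all(chz$samples == exp(rb$gamma * 14 * 24)))

  # two uniform intervals: exact product of scalar LQ factors
  u1 <- survival_map(array(20, dim = c(3, 3, 1)), tmpl, rb, t_h = 48)
  u2 <- survival_map(array(10, dim = c(3, 3, 1)), tmpl, rb, t_h = 72)
  ch2 <- chain_intervals(list(u1, u2), n_samples = 50, seed = 2)
  expect_true(all(ch2$samples == u1$E[1] * u2$E[1]))

  expect_error(chain_intervals(list()), "empty")

  # reproducibility and gaussian option
  cha <- chain_intervals(list(s1), n_samples = 1000, seed = 9)
  chb <- chain_intervals(list(s1), n_samples = 1000, seed = 9)
  expect_identical(cha$samples, chb$samples)
  chg <- chain_intervals(list(s1), n_samples = 2e4, seed = 9,
                         gaussian = TRUE)
  expect_equal(mean(chg$samples), s1$summary[["mean"]], tolerance = 0.02)
})

test_that("gaussian alpha heterogeneity widens the survival distribution", {
  tmpl <- default_truth$kinetics
  D_Gy <- 2.5
  alphas <- sample_alpha(radiobiology_params(0.14, 100, 60, 14.5,
                                             alpha_sd = 0.03), 5000, seed = 3)
  expect_lt(abs(mean(alphas) - 0.14), 3 * 0.03 / sqrt(5000))
  expect_true(all(alphas > 0))
  e_fixed <- exp(-0.14 * D_Gy)
  e_spread <- exp(-alphas * D_Gy)
  expect_gt(sd(e_spread), 0)
  expect_equal(mean(e_spread) > 0, TRUE)
  # same draws for the same seed
  expect_identical(alphas,
                   sample_alpha(radiobiology_params(0.14, 100, 60, 14.5,
                                                    alpha_sd = 0.03),
                                5000, seed = 3))
})

test_that("growth fitting recovers rates and flags undefined T_D", {
  # k1 = k2 = 0 noiseless: T_D = ln2/k0 exactly
  tr0 <- ground_truth(growth = list(V0 = 100, k0 = 0.1, k1 = 0, k2 = 0,
                                    T0_d = 3, T1_d = 7))
  v0 <- generate_volume_curve(tr0, seq(0, 21, by = 1.5))
  f0 <- fit_growth(v0)
  expect_equal(f0$T_D_d, log(2) / 0.1, tolerance = 1e-6)

  # full model, noiseless: 4 significant digits; doubling time at the
  # simulated truth of 14.5 d
  tr <- default_truth
  v <- generate_volume_curve(tr, seq(0, 21, by = 1.5))
  f <- fit_growth(v, T0_d = 3)
  expect_equal(f$T_D_d, 14.5, tolerance = 1e-4)
  expect_equal(f$T1_d, tr$growth$T1_d, tolerance = 1e-3)
  expect_equal(f$V0, tr$growth$V0, tolerance = 1e-3)

  # net shrinkage: T_D undefined and flagged
  trs <- ground_truth(growth = list(V0 = 100, k0 = 0.05, k1 = 0.3, k2 = 0.01,
                                    T0_d = 3, T1_d = 7))
  vs <- generate_volume_curve(trs, seq(0, 21, by = 1.5))
  fs <- fit_growth(vs)
  expect_false(fs$T_D_defined)
  expect_true(is.na(fs$T_D_d))

  expect_error(fit_growth(v[1:4, ]), "6 time points")
})

test_that("repair fitting recovers the half-life and flags flat series", {
  tr <- default_truth
  tt <- c(0, 24, 48, 72, 120, 150)
  # noiseless: exact
  f0 <- fit_repair(generate_foci_series(tr, tt, n_cells = Inf))
  expect_equal(f0$T_mu_h, 60, tolerance = 1e-6)

  # Poisson counts at n_cells = 500: within 10%
  fn <- fit_repair(generate_foci_series(tr, tt, n_cells = 500, seed = 21))
  expect_lt(abs(fn$T_mu_h - 60) / 60, 0.10)

  # flat series: near-zero rate, flagged, not an error
  flat <- data.frame(t_h = tt, foci_per_cell = rep(5, length(tt)))
  ff <- fit_repair(flat)
  expect_false(ff$decaying)
  expect_lt(ff$mu_per_h, 1e-4)

  # increasing series: fit failure
  up <- data.frame(t_h = tt, foci_per_cell = exp(0.01 * tt))
  expect_error(fit_repair(up), "does not decay")
  expect_error(fit_repair(flat[1:3, ]), "4 time points")
})

test_that("minimal effective dose rate balances kill and repopulation", {
  # beta = 0 limit: R* = gamma / alpha
  rb_lin <- radiobiology_params(0.2, 1e9, T_mu_h = 60, T_D_d = 10)
  expect_equal(minimal_effective_dose_rate(rb_lin),
               rb_lin$gamma / 0.2 * 1000, tolerance = 1e-6)

  # the root satisfies the defining balance equation
  rb <- radiobiology_params(0.14, 100, T_mu_h = 60, T_D_d = 14.5)
  R <- minimal_effective_dose_rate(rb) / 1000
  expect_equal(rb$alpha * R + 2 * rb$beta / rb$mu * R^2, rb$gamma,
               tolerance = 1e-10)

  # solver is the bisection of a monotone function: unique positive root
  expect_gt(R, 0)
  expect_error(minimal_effective_dose_rate(
    radiobiology_params(0.14, 100, 60)), "gamma")
})

test_that("RBE is the alpha ratio", {
  expect_equal(rbe(0.264, 0.264), 1)
  expect_equal(round(rbe(0.1, 0.264), 1), 0.4)
  expect_error(rbe(0.1, 0), "positive")
})
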