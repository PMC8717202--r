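# prrtdosim

Voxel dosimetry and radiobiologic modeling of ¹⁷⁷Lu-DOTATATE peptide
receptor radionuclide therapy (PRRT), for radiation physicists and
radiobiologists studying how heterogeneous, receptor-driven uptake shapes
absorbed dose, DNA double-strand-break (DSB) induction and in vivo
tumor-cell survival in preclinical models.

## What it computes

The package implements the full chain from activity distribution to
biological effect:

* **Dose engine** — per-decay 3-D absorbed dose maps by FFT convolution
  with a packaged ¹⁷⁷Lu electron dose-point kernel (condensed-history
  CSDA transport with Highland multiple scattering, all beta/conversion/
  Auger components; see `data-raw/make_lu177_dpk.R`), region S values
  (Gy/decay), and a uniform water-sphere reference phantom.
* **Kinetics** — the biexponential dose-rate model
  `Ṙ(t) = (R₀ − P)·e^(−λₑt) + P·e^(−λₚt)` (mGy/h), its closed-form
  integral, and multistart least-squares fitting with AICc selection
  against a mono-exponential alternative (λₚ fixed to the ¹⁷⁷Lu constant,
  half-life 6.647 d).
* **Survival model** — linear-quadratic in vivo survival with dose-rate
  protraction and repopulation,
  `E(t) = e^(γt)·exp(−αD(t) − G(t)·βD(t)²)`, where `G(t)` is the
  Lea–Catcheside factor in closed form for biexponential kinetics,
  validated against an adaptive-quadrature oracle; per-voxel survival
  maps and an "average approach" on the regional mean dose rate; Monte
  Carlo chaining of treatment intervals (0–2, 2–5, 5–11, 11–14 d);
  piecewise-exponential tumor-growth fits (`T_D = ln2/(k₀−k₁+k₂)`),
  γH2AX repair fits (`T_μ = ln2/μ`), minimal effective dose rates, and
  RBE as the ratio of fitted α values.
* **Dose metrics** — DVH/cDVH, generalized equivalent uniform dose
  (power mean of order `a`, negative for tumors), S-value comparisons
  with paired tests, Shapiro–Wilk/Q–Q normality diagnostics.
* **DSB analysis** — per-tumor and pooled dose–DSB regressions with 95%
  CI, and χ² template matching of expression patterns with
  similarity–dose overlap reports.
* **Synthetic data** — every input the original study took from mice and
  microscopy is emulated with controlled ground truth (correlated
  expression fields, activity maps, time–activity series, foci decay,
  volume curves, costained sections with Poisson DSB counts), so the
  whole pipeline is testable offline.

## Worked example

Dose–DSB correlation on a synthetic eight-section study (this is
`analysis/05_dsb_correlation.R`, trimmed):

```r
library(prrtdosim)

truth <- ground_truth()           # DSB yield 0.0223 per cell per mGy
doses <- seq(1600, 1800, length.out = 8)
records <- do.call(rbind, lapply(seq_along(doses), function(j) {
  s <- generate_costained_section(truth, matrix(doses[j], 32, 32),
                                  n_cells = 2000, seed = 600 + j)
  data.frame(tumor = ceiling(j / 2), dose_mGy = s$mean_dose_mGy,
             dsb_per_cell = s$mean_dsb)
}))
fit_dose_dsb(records)
#> dose_dsb_fit: pooled slope 0.02294 DSB/cell/mGy (95% CI 0.02134..0.02454), R^2 0.995
#>   4 tumors, mean slope 0.02315, Shapiro-Wilk p = 0.786
```

The pooled slope recovers the generating yield (0.0223 DSB per cell per
mGy) inside its own 95% confidence interval; the per-tumor slopes pass
the normality check.

Minimal effective dose rates for cell kill — the constant dose rate at
which LQ killing under steady-state protraction balances repopulation —
at α/β = 100 Gy, repair half-life 60 h, doubling time 14.5 d:

```r
minimal_effective_dose_rate(radiobiology_params(0.14, 100, 60, 14.5))
#> [1] 13.893    # mGy/h
minimal_effective_dose_rate(radiobiology_params(0.264, 100, 60, 14.5))
#> [1] 7.448652
rbe(0.1, 0.264)  # internal vs external-beam alpha
#> [1] 0.3787879  # rounds to 0.4
```

The analysis drivers `analysis/01_phantom_and_dosimetry.R` …
`05_dsb_correlation.R` run the stages end to end on synthetic phantoms
and write their tables under `results/`. The methods vignette
(`vignettes/prrt-dosimetry-methods.Rmd`) documents the models,
parameters, numerical choices and limitations.

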