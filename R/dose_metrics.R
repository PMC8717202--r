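#' Dose-volume histogram
#'
#' Frequency and cumulative dose-volume histograms over a region.
#' Frequencies are normalized to 1; the cumulative curve gives the volume
#' fraction receiving at least each bin-edge dose and is the reversed
#' cumulative sum of the frequencies (monotone nonincreasing from 1 to 0).
#' The volume fraction receiving at least the mean dose is computed from
#' the raw voxel sample, not from the binned histogram.
#'
#' @param dose_map a `dose_map` or bare numeric array.
#' @param mask optional logical array selecting the region.
#' @param n_bins number of equal-width dose bins.
#' @return object of class `dvh`: `breaks`, `frequency`, `cumulative`
#'   (at `breaks`), `mean_dose`, `frac_ge_mean_pct`.
#' @export
dvh <- function(dose_map, mask = NULL, n_bins = 256) {
  x <- if (inherits(dose_map, "dose_map")) dose_map$values else dose_map
  d <- if (is.null(mask)) as.numeric(x) else as.numeric(x[mask])
  if (length(d) == 0) stop("empty region mask", call. = FALSE)
  rng <- range(d)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1) * 1e-6
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(pmin(findInterval(d, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  freq <- counts / length(d)
  cumulative <- c(1, 1 - cumsum(freq))
  m <- mean(d)
  structure(list(breaks = breaks, frequency = freq, cumulative = cumulative,
                 mean_dose = m,
                 frac_ge_mean_pct = 100 * mean(d >= m)),
            class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf(
    "dvh: %d bins over [%.4g, %.4g]; mean dose %.4g; %.2f%% of volume >= mean\n",
    length(x$frequency), min(x$breaks), max(x$breaks), x$mean_dose,
    x$frac_ge_mean_pct))
  invisible(x)
}

#' Generalized equivalent uniform dose
#'
#' Power mean of order `a` of the voxel doses,
#' \deqn{gEUD = \left(\frac{1}{N}\sum_i d_i^a\right)^{1/a}.}
#' Negative `a` (the tumor convention) penalizes cold spots; `a = 1` is
#' the arithmetic mean. With `a < 0` a zero-dose voxel makes the power
#' mean diverge to 0; zero-dose voxels are excluded with a warning and
#' their count reported in the `n_zero_excluded` attribute (an all-zero
#' sample returns 0).
#'
#' @param doses numeric vector/array of voxel doses (Gy, >= 0).
#' @param a power-mean exponent, nonzero.
#' @return gEUD in the units of `doses`.
#' @export
geud <- function(doses, a) {
  d <- as.numeric(doses)
  if (length(a) != 1 || a == 0) stop("`a` must be a nonzero scalar", call. = FALSE)
  if (any(d < 0)) stop("doses must be >= 0", call. = FALSE)
  n_zero <- 0L
  if (a < 0 && any(d == 0)) {
    n_zero <- sum(d == 0)
    d <- d[d > 0]
    warning(sprintf("excluded %d zero-dose voxel(s) from gEUD with a < 0",
                    n_zero))
    if (length(d) == 0) return(structure(0, n_zero_excluded = n_zero))
  }
  # scale so the power terms stay bounded: by min(d) for a < 0 (ratios
  # >= 1, powers <= 1), by max(d) for a > 0
  m <- if (a < 0) min(d) else max(d)
  if (m == 0) return(structure(0, n_zero_excluded = n_zero))
  out <- m * mean((d / m)^a)^(1 / a)
  structure(out, n_zero_excluded = n_zero)
}

#' Compare heterogeneous S values against a homogeneous reference
#'
#' Percent differences `(S_het - S_hom) / S_hom`, their spread, and a
#' two-sided paired t-test of the heterogeneous values against the
#' reference (a scalar reference is paired as a constant).
#'
#' @param het numeric vector of heterogeneous S values, or list of
#'   `svalue_result`.
#' @param hom homogeneous reference: scalar, or vector paired with `het`.
#' @return list: `percent_diff`, `max_spread_pct` (max - min), `t_test`
#'   (p-value, or NA for fewer than 2 values), `significant` (P < 0.05).
#' @export
compare_s_values <- function(het, hom) {
  if (is.list(het)) het <- vapply(het, function(x) x$S, numeric(1))
  if (inherits(hom, "svalue_result")) hom <- hom$S
  if (length(hom) != 1 && length(hom) != length(het))
    stop("paired comparison needs matching lengths", call. = FALSE)
  ref <- if (length(hom) == 1) rep(hom, length(het)) else hom
  pct <- (het - ref) / ref * 100
  p <- if (length(het) >= 2 && sd(het - ref) > 0)
    t.test(het, ref, paired = TRUE)$p.value else NA_real_
  list(percent_diff = pct,
       max_spread_pct = max(pct) - min(pct),
       t_test_p = p,
       significant = isTRUE(p < 0.05))
}

#' Normality diagnostics
#'
#' Shapiro-Wilk test plus a Q-Q summary (squared correlation of the sorted
#' sample with standard-normal quantiles). Constant samples are flagged as
#' degenerate rather than tested.
#'
#' @param x numeric sample, n >= 3 (Shapiro-Wilk caps at n = 5000; larger
#'   samples are tested on a deterministic thinning).
#' @return list: `shapiro_p`, `qq_r_squared`, `degenerate`, `n`.
#' @export
normality_report <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0)
    return(list(shapiro_p = NA_real_, qq_r_squared = NA_real_,
                degenerate = TRUE, n = n))
  xs <- if (n > 5000) sort(x)[round(seq(1, n, length.out = 5000))] else x
  sw <- shapiro.test(xs)
  qq <- cor(sort(x), qnorm(ppoints(n)))^2
  list(shapiro_p = sw$p.value, qq_r_squared = qq, degenerate = FALSE, n = n)
}
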