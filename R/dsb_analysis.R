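#' Dose-DSB correlation fit
#'
#' Per-tumor simple linear regressions of DSB per cell on mean absorbed
#' dose, a Shapiro-Wilk normality check on the per-tumor slopes, and a
#' pooled ordinary least-squares fit with intercept over all sections,
#' reporting the slope with its 95% confidence interval (t-distribution on
#' the OLS standard error) and R^2.
#'
#' @param records data.frame with columns `tumor` (id), `dose_mGy` (mean
#'   absorbed dose to cancer cells) and `dsb_per_cell`; one row per
#'   section.
#' @return object of class `dose_dsb_fit`: `per_tumor` (data.frame of
#'   slopes), `slope_mean`, `shapiro_p`, `pooled_slope`, `pooled_ci`
#'   (95%), `pooled_r_squared`, `pooled_intercept`, `n_sections`.
#' @export
fit_dose_dsb <- function(records) {
  need <- c("tumor", "dose_mGy", "dsb_per_cell")
  if (!all(need %in% names(records)))
    stop("`records` needs columns tumor, dose_mGy, dsb_per_cell",
         call. = FALSE)
  if (any(records$dose_mGy < 0) || any(records$dsb_per_cell < 0))
    stop("doses and DSB counts must be >= 0", call. = FALSE)
  if (nrow(records) < 3)
    stop("need at least 3 pooled sections", call. = FALSE)

  slopes <- do.call(rbind, lapply(split(records, records$tumor), function(d) {
    if (nrow(d) < 2 || sd(d$dose_mGy) == 0) return(NULL)
    data.frame(tumor = d$tumor[1],
               slope = coef(lm(dsb_per_cell ~ dose_mGy, data = d))[[2]],
               n = nrow(d))
  }))
  shapiro_p <- if (!is.null(slopes) && nrow(slopes) >= 3 &&
                   sd(slopes$slope) > 0)
    shapiro.test(slopes$slope)$p.value else NA_real_

  pooled <- lm(dsb_per_cell ~ dose_mGy, data = records)
  # exact synthetic data triggers summary.lm's perfect-fit warning
  ci <- suppressWarnings(confint(pooled, "dose_mGy", level = 0.95))
  r2 <- suppressWarnings(summary(pooled)$r.squared)
  structure(list(per_tumor = slopes,
                 slope_mean = if (!is.null(slopes)) mean(slopes$slope)
                              else NA_real_,
                 shapiro_p = shapiro_p,
                 pooled_slope = coef(pooled)[["dose_mGy"]],
                 pooled_ci = as.numeric(ci),
                 pooled_r_squared = r2,
                 pooled_intercept = coef(pooled)[[1]],
                 n_sections = nrow(records)),
            class = "dose_dsb_fit")
}

#' @export
print.dose_dsb_fit <- function(x, ...) {
  cat(sprintf(
    "dose_dsb_fit: pooled slope %.4g DSB/cell/mGy (95%% CI %.4g..%.4g), R^2 %.3f\n",
    x$pooled_slope, x$pooled_ci[1], x$pooled_ci[2], x$pooled_r_squared))
  if (!is.null(x$per_tumor))
    cat(sprintf("  %d tumors, mean slope %.4g, Shapiro-Wilk p = %.3g\n",
                nrow(x$per_tumor), x$slope_mean, x$shapiro_p))
  invisible(x)
}

#' Threshold an expression image into low/high classes
#'
#' Otsu two-class threshold (via EBImage) on a single-channel image; the
#' low/high masks partition the image.
#'
#' @param image numeric matrix.
#' @return list: `threshold` (original intensity units), `low`, `high`
#'   (logical matrices).
#' @export
threshold_expression <- function(image) {
  if (!is.matrix(image)) stop("image must be a 2-D matrix", call. = FALSE)
  rng <- range(image)
  if (diff(rng) == 0)
    stop("constant image: threshold is degenerate", call. = FALSE)
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(norm, range = c(0, 1), levels = 256)
  thr <- rng[1] + th * diff(rng)
  list(threshold = thr, low = image <= thr, high = image > thr)
}

# min-max normalize a patch; constant patches map to all zeros
norm01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(x * 0)
  (x - rng[1]) / diff(rng)
}

# chi-square distance between two histograms
chisq_hist <- function(h1, h2) {
  s <- h1 + h2
  ok <- s > 0
  sum((h1[ok] - h2[ok])^2 / s[ok])
}

#' Template matching by chi-square histogram distance
#'
#' Slides the template over the test image and scores each window by the
#' chi-square distance
#' \deqn{\chi^2 = \sum_b \frac{(h_w(b) - h_T(b))^2}{h_w(b) + h_T(b)}}
#' between the intensity histograms (default 32 bins on min-max
#' normalized patches; normalization makes the score robust to staining
#' intensity scale). A pixelwise variant (chi-square on normalized pixel
#' values) is available behind `method`.
#'
#' @param test_image numeric matrix, strictly larger than the template.
#' @param template numeric matrix.
#' @param stride window step in pixels; default a quarter of the template
#'   size per axis.
#' @param n_bins histogram bins.
#' @param method "histogram" (default) or "pixel".
#' @return object of class `template_match_map`: `distance` (matrix over
#'   window positions), `rows`, `cols` (window top-left indices),
#'   `window` (template dim), `stride`, `best` (top-left index of the
#'   global minimum).
#' @export
template_match <- function(test_image, template, stride = NULL, n_bins = 32,
                           method = c("histogram", "pixel")) {
  method <- match.arg(method)
  if (!is.matrix(test_image) || !is.matrix(template))
    stop("images must be 2-D matrices", call. = FALSE)
  tw <- dim(template)
  if (any(tw >= dim(test_image)))
    stop("template must be strictly smaller than the test image",
         call. = FALSE)
  if (is.null(stride)) stride <- pmax(1L, floor(tw / 4))
  stride <- rep(as.integer(stride), length.out = 2)

  rows <- seq(1L, nrow(test_image) - tw[1] + 1L, by = stride[1])
  cols <- seq(1L, ncol(test_image) - tw[2] + 1L, by = stride[2])
  breaks <- seq(0, 1, length.out = n_bins + 1)
  tmpl_n <- norm01(template)
  h_t <- if (method == "histogram")
    tabulate(pmin(findInterval(tmpl_n, breaks, rightmost.closed = TRUE),
                  n_bins), nbins = n_bins) / length(tmpl_n)

  dist <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) {
    for (j in seq_along(cols)) {
      w <- test_image[rows[i]:(rows[i] + tw[1] - 1L),
                      cols[j]:(cols[j] + tw[2] - 1L)]
      wn <- norm01(w)
      dist[i, j] <- if (method == "histogram") {
        h_w <- tabulate(pmin(findInterval(wn, breaks,
                                          rightmost.closed = TRUE),
                             n_bins), nbins = n_bins) / length(wn)
        chisq_hist(h_w, h_t)
      } else {
        s <- wn + tmpl_n
        ok <- s > 0
        if (!any(ok)) 0 else sum((wn[ok] - tmpl_n[ok])^2 / s[ok]) / sum(ok)
      }
    }
  }
  bi <- arrayInd(which.min(dist), dim(dist))
  structure(list(distance = dist, rows = rows, cols = cols,
                 window = tw, stride = stride,
                 best = c(row = rows[bi[1]], col = cols[bi[2]])),
            class = "template_match_map")
}

#' @export
print.template_match_map <- function(x, ...) {
  cat(sprintf(
    "template_match_map: %d x %d windows (stride %d x %d), best at (%d, %d), min chi^2 %.4g\n",
    nrow(x$distance), ncol(x$distance), x$stride[1], x$stride[2],
    x$best[1], x$best[2], min(x$distance)))
  invisible(x)
}

#' Relate template-match similarity to local absorbed dose
#'
#' For each window of a template-match map, computes the local mean dose
#' from a co-registered 2-D dose map, then reports the Spearman rank
#' correlation between similarity (negated chi-square distance) and local
#' dose, the fraction of top-decile-similarity windows that are also
#' top-decile in dose, and optionally a permutation null band for the
#' correlation.
#'
#' @param match_map a `template_match_map`.
#' @param dose_map_2d numeric matrix co-registered with the test image.
#' @param n_perm permutation draws for the null band (0 to skip).
#' @param seed seed for the permutation draws.
#' @return list: `rank_correlation`, `top_decile_overlap`, `window_dose`,
#'   `similarity`, and when `n_perm > 0` the two-sided 95% null band
#'   `perm_band`.
#' @export
flag_high_dsb_regions <- function(match_map, dose_map_2d, n_perm = 0,
                                  seed = 1) {
  stopifnot(inherits(match_map, "template_match_map"))
  tw <- match_map$window
  if (any(dim(dose_map_2d) < c(max(match_map$rows) + tw[1] - 1L,
                               max(match_map$cols) + tw[2] - 1L)))
    stop("dose map smaller than the matched image area", call. = FALSE)
  wd <- matrix(NA_real_, length(match_map$rows), length(match_map$cols))
  for (i in seq_along(match_map$rows)) {
    for (j in seq_along(match_map$cols)) {
      r <- match_map$rows[i]; cc <- match_map$cols[j]
      wd[i, j] <- mean(dose_map_2d[r:(r + tw[1] - 1L),
                                   cc:(cc + tw[2] - 1L)])
    }
  }
  sim <- -as.numeric(match_map$distance)
  dose <- as.numeric(wd)
  rho <- if (sd(sim) > 0 && sd(dose) > 0)
    cor(sim, dose, method = "spearman") else NA_real_
  q_s <- quantile(sim, 0.9); q_d <- quantile(dose, 0.9)
  top_s <- sim >= q_s
  overlap <- if (any(top_s)) mean(dose[top_s] >= q_d) else NA_real_
  out <- list(rank_correlation = rho, top_decile_overlap = overlap,
              window_dose = wd, similarity = matrix(sim, nrow(wd), ncol(wd)))
  if (n_perm > 0) {
    perms <- withr::with_seed(seed, replicate(n_perm, {
      cor(sim, sample(dose), method = "spearman")
    }))
    out$perm_band <- quantile(perms, c(0.025, 0.975))
  }
  out
}
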