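## Image-quality scores with circular handling for axial angle maps,
## the local azimuth-dispersion map csd(phi), and the rank-sum test used
## to compare per-image score samples between denoising methods.

as_roi <- function(roi, x) {
  if (is.null(roi)) return(array(TRUE, dim(x)))
  stopifnot(identical(dim(roi), dim(x)))
  roi <- roi & !is.na(roi)
  if (!any(roi)) stop("empty ROI")
  roi
}

#' Root-mean-squared error over a region of interest
#'
#' Linear RMSE, or axial (circular) RMSE for orientation maps on
#' \[0, 180) degrees: differences are wrapped into (-90, 90] before
#' squaring, so 179 vs 1 degrees counts as a 2-degree error.
#'
#' @param x,y numeric matrices of equal size (degrees if `circular`).
#' @param roi logical matrix or `NULL` for the whole frame.
#' @param circular treat inputs as axial angles modulo 180 degrees.
#' @return scalar RMSE (same units as the input).
#' @export
rmse <- function(x, y, roi = NULL, circular = FALSE) {
  stopifnot(identical(dim(x), dim(y)))
  roi <- as_roi(roi, x)
  d <- if (circular) axial_diff(x[roi], y[roi]) else x[roi] - y[roi]
  sqrt(mean(d^2))
}

#' Normalised peak signal-to-noise ratio in decibels
#'
#' `20 log10(range / rmse)` where the peak is the dynamic range of the
#' reference within the ROI (axial quantities use the fixed 180-degree
#' range). Normalising by the reference range makes the score comparable
#' across quantities with different units.
#'
#' @inheritParams rmse
#' @param ref reference image.
#' @return scalar in dB; `Inf` when `x == ref` exactly.
#' @export
npsnr <- function(x, ref, roi = NULL, circular = FALSE) {
  roi <- as_roi(roi, x)
  rng <- if (circular) 180 else diff(range(ref[roi]))
  if (rng <= 0) stop("reference has zero dynamic range within the ROI")
  e <- rmse(x, ref, roi, circular)
  if (e == 0) return(Inf)
  20 * log10(rng / e)
}

#' Structural similarity index (mean SSIM, percent)
#'
#' Windowed SSIM with a Gaussian window, averaged over the ROI and
#' reported in percent. Local means/variances are computed with replicate
#' padding so border pixels inside the ROI contribute.
#'
#' @inheritParams npsnr
#' @param window odd window size in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @param k1,k2 SSIM stabilising constants.
#' @param dynamic_range value range L of the quantity; default is the
#'   reference range within the ROI.
#' @return mean SSIM in percent (100 = identical).
#' @export
ssim <- function(x, ref, roi = NULL, window = 7, sigma = 1.5,
                 k1 = 0.01, k2 = 0.03, dynamic_range = NULL) {
  stopifnot(identical(dim(x), dim(ref)), window %% 2 == 1)
  roi <- as_roi(roi, x)
  if (window > min(dim(x))) stop("SSIM window larger than the image extent")
  L <- if (is.null(dynamic_range)) diff(range(ref[roi])) else dynamic_range
  if (L <= 0) L <- 1
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  k <- gaussian_kernel(window, sigma)
  mu_x <- conv2same(x, k); mu_r <- conv2same(ref, k)
  sxx <- conv2same(x * x, k) - mu_x^2
  srr <- conv2same(ref * ref, k) - mu_r^2
  sxr <- conv2same(x * ref, k) - mu_x * mu_r
  smap <- ((2 * mu_x * mu_r + C1) * (2 * sxr + C2)) /
          ((mu_x^2 + mu_r^2 + C1) * (sxx + srr + C2))
  100 * mean(smap[roi])
}

#' Local circular standard deviation of an axial orientation map
#'
#' For each pixel, the azimuths in the surrounding `window x window`
#' neighbourhood are doubled (axial to circular), the mean resultant
#' length `Rbar` of the unit vectors at `2 phi` is computed over valid
#' neighbours, and the circular standard deviation
#' `csd = 1/2 sqrt(-2 ln Rbar)` is reported in degrees. Low values mean
#' coherent fibre orientation, high values directional disruption.
#'
#' @param phi H x W azimuth map in degrees on \[0, 180).
#' @param valid logical mask of pixels whose azimuth is meaningful;
#'   invalid neighbours are excluded from each window.
#' @param window odd neighbourhood size (default 5).
#' @param cap upper cap in degrees replacing the infinite csd at zero
#'   resultant length.
#' @param min_neighbours windows with fewer valid pixels yield `NA`.
#' @return H x W matrix of csd values in degrees (`NA` where undefined).
#' @export
csd_map <- function(phi, valid = NULL, window = 5, cap = 1e3,
                    min_neighbours = 3) {
  stopifnot(window %% 2 == 1)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(phi), ncol(phi))
  v <- valid & is.finite(phi)
  a2 <- 2 * phi * pi / 180
  cs <- ifelse(v, cos(a2), 0)
  sn <- ifelse(v, sin(a2), 0)
  n <- boxsum(v * 1, window)
  C <- boxsum(cs, window)
  S <- boxsum(sn, window)
  rbar <- sqrt(C^2 + S^2) / pmax(n, 1)
  rbar <- pmin(rbar, 1)
  rbar[rbar > 1 - 1e-12] <- 1   # snap: constant windows give exactly 0
  rbar[rbar < 1e-12] <- 0       # snap: antipodal cancellation hits the cap
  out <- 0.5 * sqrt(-2 * log(rbar)) * 180 / pi
  out[rbar == 0] <- cap
  out <- pmin(out, cap)
  out[n < min_neighbours] <- NA_real_
  out
}

## Exact two-sided rank-sum tail by dynamic programming over doubled
## midranks (integers even with ties): f[k+1, s+1] = number of size-k
## subsets of the pooled doubled ranks with sum s.
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  r2 <- as.integer(round(2 * rank(pooled)))     # doubled midranks
  m <- length(a); N <- length(pooled)
  w2 <- sum(r2[seq_len(m)])
  smax <- sum(sort(r2, decreasing = TRUE)[seq_len(m)])
  f <- matrix(0, m + 1L, smax + 1L)
  f[1L, 1L] <- 1
  for (x in r2) {
    for (k in rev(seq_len(m))) {
      src <- seq_len(smax + 1L - x)
      f[k + 1L, src + x] <- f[k + 1L, src + x] + f[k, src]
    }
  }
  counts <- f[m + 1L, ]
  total <- sum(counts)
  sums <- seq_along(counts) - 1L
  p_le <- sum(counts[sums <= w2]) / total
  p_ge <- sum(counts[sums >= w2]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Two-sided Wilcoxon rank-sum test between two score samples
#'
#' Compares independent per-image score samples of two methods. For a
#' combined sample size of at most 20 the p-value is exact (enumeration of
#' the rank-sum distribution, correct under ties); larger samples use the
#' normal approximation with tie correction.
#'
#' @param a,b numeric vectors of per-image scores, each of length >= 3.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact mode;
#'   default chooses by combined sample size.
#' @return two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b, exact = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) stop("need at least 3 scores per sample")
  if (is.null(exact)) exact <- (length(a) + length(b)) <= 20
  if (exact) return(ranksum_exact_p(a, b))
  stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
}

#' Summarise per-image scores into a quartile report
#'
#' Builds the quartile table (q1 / median / q3 per quantity and method)
#' and marks methods whose score distribution differs significantly from a
#' designated reference method (two-sided rank-sum test). Quartiles use
#' linear interpolation between order statistics.
#'
#' @param scores data frame with columns `method`, `quantity`, `score`
#'   (one row per image x method x quantity).
#' @param reference method name the pairwise tests compare against.
#' @param alpha significance level for the star column.
#' @return an object of class `metric_report`: list with the quartile
#'   `table` (data frame), the `reference` method and `alpha`.
#' @export
summarize_scores <- function(scores, reference = "PDDN", alpha = 0.05) {
  stopifnot(all(c("method", "quantity", "score") %in% names(scores)))
  rows <- list()
  for (q in unique(scores$quantity)) {
    sq <- scores[scores$quantity == q, ]
    ref_scores <- sq$score[sq$method == reference]
    for (m in unique(sq$method)) {
      v <- sq$score[sq$method == m]
      qs <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      p <- NA_real_
      if (m != reference && length(ref_scores) >= 3 && length(v) >= 3) {
        p <- wilcoxon_ranksum(v, ref_scores)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, method = m, q1 = qs[1], median = qs[2], q3 = qs[3],
        n = length(v), p_value = p,
        significant = !is.na(p) & p < alpha)
    }
  }
  structure(list(table = do.call(rbind, rows), reference = reference,
                 alpha = alpha,
                 quartile_rule = "linear interpolation (type 7)"),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report (q1/median/q3; * = p <", x$alpha,
      "vs", x$reference, ")\n")
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-6s %-6s %8.3g/%8.3g/%8.3g %s\n", tb$quantity[i],
                tb$method[i], tb$q1[i], tb$median[i], tb$q3[i],
                if (isTRUE(tb$significant[i])) "*" else ""))
  }
  invisible(x)
}
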