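# Image-fidelity metrics: morphology-based torso segmentation, the Residual
# Structure Index (RSI), heatmap overlays, display-window normalisation for
# IQA, SSIM, and the Mann-Whitney rank-sum test.

#' Segment the torso (body) region of a CT image
#'
#' Threshold at `threshold_hu`, binary closing with a disc brush, keep the
#' largest connected component, fill holes. Intended to exclude the air
#' background so ratio metrics are computed over anatomy only.
#'
#' @param x A [ct_image()] (or HU matrix).
#' @param threshold_hu Threshold separating body from air (default -300 HU).
#' @param closing_radius_px Disc radius of the morphological closing.
#' @return A [region_mask()] with role `torso`.
#' @export
segment_torso <- function(x, threshold_hu = -300, closing_radius_px = 3) {
  px <- as_pixel_matrix(x)
  bw <- px > threshold_hu
  if (!any(bw))
    ctaudit_error("torso segmentation failed: no pixels above threshold",
                  "ctaudit_error_segmentation")
  brush <- EBImage::makeBrush(2 * closing_radius_px + 1, shape = "disc")
  closed <- EBImage::closing(bw * 1, brush)
  lab <- EBImage::bwlabel(closed > 0)
  counts <- tabulate(lab[lab > 0])
  if (length(counts) == 0)
    ctaudit_error("torso segmentation failed: empty mask",
                  "ctaudit_error_segmentation")
  keep <- which.max(counts)
  filled <- EBImage::fillHull(lab == keep)
  m <- matrix(as.logical(filled > 0), nrow(px), ncol(px))
  if (!any(m))
    ctaudit_error("torso segmentation failed: empty mask",
                  "ctaudit_error_segmentation")
  region_mask(m, role = "torso")
}

#' Residual Structure Index
#'
#' The RSI is the mean absolute predicted structural component divided by
#' the mean absolute residual noise, both over the same mask. It lies in
#' `[0, 1]`: a ratio above 1 is clipped (and flagged), preserving the
#' index's stated range while recording the anomaly. High values flag
#' structure leaking into the residual noise, i.e. potential hallucination
#' or structure removal by a denoiser.
#'
#' @param s_hat Predicted [structure_component()] (or matrix).
#' @param n_hat Residual [noise_image()] (or matrix).
#' @param mask A [region_mask()] — torso role for whole-slice RSI, circle
#'   set for ROI protocols. Must be non-empty.
#' @return An object of class `rsi_result`: fields `rsi`, `numerator`,
#'   `denominator` (HU), `mask_pixels`, `clipped`.
#' @export
compute_rsi <- function(s_hat, n_hat, mask) {
  sm <- as_pixel_matrix(s_hat)
  nm <- as_pixel_matrix(n_hat)
  mm <- as_mask_matrix(mask)
  check_same_shape(sm, nm, "`s_hat` and `n_hat`")
  check_same_shape(sm, mm, "inputs and mask")
  if (!any(mm))
    ctaudit_error("RSI mask is empty", "ctaudit_error_empty_mask")
  num <- mean(abs(sm[mm]))
  den <- mean(abs(nm[mm]))
  if (den <= 0)
    ctaudit_error("RSI denominator is zero (residual noise vanishes on mask)",
                  "ctaudit_error_zero_denominator")
  ratio <- num / den
  structure(
    list(rsi = min(1, ratio), numerator = num, denominator = den,
         mask_pixels = sum(mm), clipped = ratio > 1),
    class = "rsi_result")
}

#' @export
print.rsi_result <- function(x, ...) {
  cat(sprintf("RSI = %.4f (|s|: %.3f HU / |n|: %.3f HU over %d px%s)\n",
              x$rsi, x$numerator, x$denominator, x$mask_pixels,
              if (x$clipped) ", clipped" else ""))
  invisible(x)
}

#' Render a structure-prediction heatmap overlay
#'
#' The base image is rendered in a display window (default the abdominal
#' `[-160, 240]` HU window) and the absolute predicted structure is overlaid
#' through a perceptual colormap with opacity proportional to its magnitude;
#' values below `alpha_floor_hu` stay fully transparent, keeping backgrounds
#' clean.
#'
#' @param s_hat Predicted [structure_component()] (or matrix).
#' @param base A [ct_image()] (or matrix) to render under the overlay.
#' @param display_window Two HU values (low, high).
#' @param alpha_floor_hu Magnitude below which nothing is drawn.
#' @param alpha_scale_hu Magnitude at which the overlay saturates.
#' @param palette A `grDevices::hcl.colors` palette name.
#' @return Numeric array `H x W x 3` with values in `[0, 1]`.
#' @export
make_heatmap <- function(s_hat, base, display_window = c(-160, 240),
                         alpha_floor_hu = 2, alpha_scale_hu = 40,
                         palette = "Inferno") {
  sm <- abs(as_pixel_matrix(s_hat))
  bm <- as_pixel_matrix(base)
  check_same_shape(sm, bm, "`s_hat` and `base`")
  lo <- display_window[1]; hi <- display_window[2]
  gray <- (pmin(pmax(bm, lo), hi) - lo) / (hi - lo)
  alpha <- pmin(1, pmax(0, (sm - alpha_floor_hu) / alpha_scale_hu))
  alpha[sm < alpha_floor_hu] <- 0
  cols <- hcl.colors(256, palette)
  rgb <- col2rgb(cols) / 255
  idx <- 1 + pmin(255, floor(255 * pmin(1, sm / alpha_scale_hu)))
  out <- array(0, c(nrow(bm), ncol(bm), 3))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * gray + alpha * matrix(rgb[ch, idx],
                                                       nrow(bm), ncol(bm))
  out
}

#' Write a heatmap overlay to PNG
#' @param heatmap Array from [make_heatmap()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(heatmap, path) {
  png::writePNG(heatmap, path)
  invisible(path)
}

#' Normalise a CT image for IQA metrics
#'
#' Linear map of the abdominal reference window -160 HU -> 0 and
#' 240 HU -> 255, clipping outside the window and rounding half-up.
#'
#' @param img A [ct_image()] or HU matrix.
#' @return Integer matrix with values in 0..255.
#' @export
normalize_for_iqa <- function(img) {
  px <- as_pixel_matrix(img)
  v <- (px + 160) / 400 * 255
  v <- pmin(pmax(v, 0), 255)
  matrix(as.integer(floor(v + 0.5)), nrow(px), ncol(px))
}

ssim_kernel <- function(sigma, radius) {
  k <- exp(-0.5 * (seq(-radius, radius))^2 / sigma^2)
  k / sum(k)
}

#' Structural similarity index (SSIM)
#'
#' Standard single-scale SSIM with an 11x11 Gaussian window (sigma 1.5),
#' `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 255`, population
#' covariances, averaged over the map after cropping the half-window
#' border (so boundary handling cannot influence the score).
#'
#' @param a,b Numeric matrices of identical shape (8-bit scale).
#' @param L Dynamic range (default 255).
#' @param K1,K2 Stability constants.
#' @param sigma,win_size Gaussian window parameters.
#' @return SSIM in `[-1, 1]`.
#' @export
compute_ssim <- function(a, b, L = 255, K1 = 0.01, K2 = 0.03,
                         sigma = 1.5, win_size = 11) {
  a <- as_pixel_matrix(a) * 1.0
  b <- as_pixel_matrix(b) * 1.0
  check_same_shape(a, b, "`a` and `b`")
  r <- (win_size - 1) / 2
  if (min(dim(a)) < win_size)
    stop("images smaller than the SSIM window", call. = FALSE)
  k <- ssim_kernel(sigma, r)
  ux <- cpp_sep_filter(a, k)
  uy <- cpp_sep_filter(b, k)
  uxx <- cpp_sep_filter(a * a, k)
  uyy <- cpp_sep_filter(b * b, k)
  uxy <- cpp_sep_filter(a * b, k)
  vx <- uxx - ux^2
  vy <- uyy - uy^2
  cxy <- uxy - ux * uy
  C1 <- (K1 * L)^2
  C2 <- (K2 * L)^2
  S <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  core <- S[(r + 1):(nrow(S) - r), (r + 1):(ncol(S) - r)]
  mean(core)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact distribution when both groups have at most 8 observations and no
#' ties are present; tie-corrected normal approximation with continuity
#' correction otherwise. Degenerate all-equal data returns p = 1.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return The two-sided p-value, with the U statistic attached as
#'   attribute `"statistic"`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both groups must be non-empty", call. = FALSE)
  if (!is.numeric(group_a) || !is.numeric(group_b))
    stop("groups must be numeric", call. = FALSE)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1)
    return(structure(1, statistic =
                       length(group_a) * length(group_b) / 2))
  ties <- anyDuplicated(pooled) > 0
  exact <- !ties && length(group_a) <= 8 && length(group_b) <= 8
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  structure(min(1, p), statistic = unname(wt$statistic))
}
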