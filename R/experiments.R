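# End-to-end experiment drivers: ROI verification of the structure
# predictor, the degradation-sensitivity comparison of RSI against SSIM,
# and the denoiser-auditing pipeline with pluggable denoisers.

#' Specify a synthetic "imperfect denoiser" degradation
#'
#' @param noise_reduction_fraction Fraction of the noise removed (default
#'   0.30, i.e. 30\% less noise than the low-dose image).
#' @param blur_sigma_mm Gaussian blur sigma in millimetres (default 0.75).
#' @param mixing_rate Fraction of the blurred image mixed in, in `[0, 1]`.
#' @return An object of class `degradation_spec`.
#' @export
degradation_spec <- function(noise_reduction_fraction = 0.30,
                             blur_sigma_mm = 0.75, mixing_rate = 1) {
  if (noise_reduction_fraction < 0 || noise_reduction_fraction > 1)
    stop("`noise_reduction_fraction` must lie in [0, 1]", call. = FALSE)
  if (blur_sigma_mm <= 0)
    stop("`blur_sigma_mm` must be positive", call. = FALSE)
  if (mixing_rate < 0 || mixing_rate > 1)
    stop("`mixing_rate` must lie in [0, 1]", call. = FALSE)
  structure(list(noise_reduction_fraction = noise_reduction_fraction,
                 blur_sigma_mm = blur_sigma_mm, mixing_rate = mixing_rate),
            class = "degradation_spec")
}

#' Apply a synthetic degradation to mimic an imperfect denoiser
#'
#' Builds `d0 = x + (1 - noise_reduction_fraction) * n` (partial noise
#' removal), blurs it with the physical sigma, and returns the linear mix
#' `(1 - r) * d0 + r * blur(d0)`.
#'
#' @param x Reference (standard-dose) [ct_image()].
#' @param n Pure [noise_image()] of its low-dose counterpart.
#' @param spec A [degradation_spec()].
#' @return A degraded-denoised [ct_image()].
#' @export
apply_degradation <- function(x, n, spec) {
  if (!inherits(spec, "degradation_spec"))
    stop("`spec` must be a degradation_spec", call. = FALSE)
  check_same_shape(x, n, "`x` and `n`")
  d0 <- x$pixels + (1 - spec$noise_reduction_fraction) * n$pixels
  b <- cpp_gauss_blur(d0, spec$blur_sigma_mm / x$spacing_mm)
  out <- (1 - spec$mixing_rate) * d0 + spec$mixing_rate * b
  ct_image(clamp_hu(out), x$spacing_mm,
           dose_fraction = n$dose_fraction, id = x$id)
}

rsi_or_na <- function(s_hat, n_hat, mask) {
  tryCatch(compute_rsi(s_hat, n_hat, mask),
           ctaudit_error_zero_denominator = function(e) NULL)
}

#' ROI verification of the structure predictor
#'
#' For each held-out case and dose: simulate pure noise, embed ground-truth
#' structure discs, predict the structure from the embedded image, and
#' compute per-disc RSI both over the ground-truth structure discs and over
#' an equal number of rejection-sampled discs with zero overlap with the
#' structure areas. Groups are compared per dose with the two-sided
#' Mann-Whitney rank-sum test.
#'
#' @param model A trained `structure_predictor`.
#' @param cohort_val List of held-out standard-dose [ct_image()] objects.
#' @param doses Dose fractions to evaluate.
#' @param n_rois Discs per class per case (default 5).
#' @param diameter_mm Disc diameter (default 30 mm).
#' @param config A [noise_sim_config()].
#' @param seed Master seed.
#' @param predict_fn Optional override of the predictor: a
#'   `function(z_noise_image, s_truth_matrix)` returning a prediction
#'   matrix (used for oracle checks).
#' @param return_images Also return the per-(case, dose) images, masks and
#'   predictions, so every reported RSI can be recomputed externally.
#' @return Object of class `roi_rsi_result`: `rois` (per-disc tibble with
#'   disc centres), `summary` (per dose x class), `p_values` (per dose),
#'   and optionally `images`.
#' @export
roi_rsi_experiment <- function(model, cohort_val,
                               doses = c(0.25, 0.5, 0.75), n_rois = 5,
                               diameter_mm = 30,
                               config = noise_sim_config(), seed = 1,
                               predict_fn = NULL, return_images = FALSE) {
  if (length(cohort_val) == 0)
    stop("`cohort_val` must be non-empty", call. = FALSE)
  if (is.null(predict_fn))
    predict_fn <- function(z, s_truth) predict_structure(model, z)$pixels
  rows <- list()
  images <- list()
  for (ci in seq_along(cohort_val)) {
    x <- cohort_val[[ci]]
    torso <- segment_torso(x)
    p <- attenuation_sinogram(x, config)
    for (d in doses) {
      y <- simulate_low_dose_from_sinogram(
        x, p, d, config, derive_seed(seed, ci, round(d * 100), 1))
      n <- extract_pure_noise(y, x)
      s <- make_structure_component(x, torso,
                                    seed = derive_seed(seed, ci,
                                                       round(d * 100), 2),
                                    n_masks = n_rois,
                                    diameter_mm = diameter_mm)
      z <- embed_structure(n, s)
      zi <- noise_image(z$pixels, d, x$id)
      s_hat <- predict_fn(zi, s$pixels)
      empty <- sample_circular_masks(
        torso, n_masks = n_rois, diameter_mm = diameter_mm,
        spacing_mm = x$spacing_mm,
        seed = derive_seed(seed, ci, round(d * 100), 3),
        avoid = s$mask)
      dims <- dim(x$pixels)
      add_rows <- function(centers, radius_px, cls) {
        for (k in seq_len(nrow(centers))) {
          dm <- disc_mask(dims, centers[k, ], radius_px) & torso$pixels
          r <- rsi_or_na(s_hat, z$pixels, dm)
          rows[[length(rows) + 1]] <<- tibble(
            case = x$id, dose = d, roi_class = cls, roi = k,
            center_row = centers[k, 1], center_col = centers[k, 2],
            radius_px = radius_px,
            rsi = if (is.null(r)) NA_real_ else r$rsi,
            numerator = if (is.null(r)) NA_real_ else r$numerator,
            denominator = if (is.null(r)) NA_real_ else r$denominator,
            mask_pixels = sum(dm),
            clipped = if (is.null(r)) NA else r$clipped)
        }
      }
      add_rows(s$mask$centers, s$mask$radius_px, "structure")
      add_rows(empty$centers, empty$radius_px, "no_structure")
      if (return_images)
        images[[sprintf("%s_dose%03d", x$id, round(d * 100))]] <-
          list(case = x$id, dose = d, z = z$pixels, s = s$pixels,
               s_hat = s_hat, torso = torso$pixels)
    }
  }
  rois <- do.call(rbind, rows)
  agg <- function(sub) tibble(mean_rsi = mean(sub$rsi, na.rm = TRUE),
                              sd_rsi = sd(sub$rsi, na.rm = TRUE),
                              n = sum(!is.na(sub$rsi)))
  key <- unique(rois[, c("dose", "roi_class")])
  summary <- do.call(rbind, lapply(seq_len(nrow(key)), function(i) {
    sub <- rois[rois$dose == key$dose[i] & rois$roi_class == key$roi_class[i], ]
    cbind(key[i, ], agg(sub))
  }))
  p_values <- do.call(rbind, lapply(sort(unique(rois$dose)), function(d) {
    a <- rois$rsi[rois$dose == d & rois$roi_class == "structure"]
    b <- rois$rsi[rois$dose == d & rois$roi_class == "no_structure"]
    tibble(dose = d,
           p_value = as.numeric(rank_sum_test(a[!is.na(a)], b[!is.na(b)])))
  }))
  structure(list(rois = rois, summary = summary, p_values = p_values,
                 images = if (return_images) images else NULL),
            class = "roi_rsi_result")
}

#' @export
print.roi_rsi_result <- function(x, ...) {
  cat("ROI RSI verification\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  print(as.data.frame(x$p_values), row.names = FALSE)
  invisible(x)
}

#' Degradation sensitivity: RSI versus SSIM
#'
#' Builds, per held-out case, a reference image, its 50\%-dose simulation,
#' and degraded-denoised images across the mixing-rate grid; reports SSIM
#' between reference and degraded images (on display-window-normalised
#' grids) and the RSI of the predicted structure in the residual
#' (low-dose minus degraded) under the torso mask. A vanishing residual
#' yields an `NA` RSI (zero-denominator policy), never 0 or 1.
#'
#' @param cohort_val Held-out standard-dose images.
#' @param model A trained `structure_predictor`.
#' @param mixing_rates Blur mixing rates (default 25/50/75/100\%).
#' @param noise_reduction_fraction,blur_sigma_mm See [degradation_spec()].
#' @param dose_fraction Dose of the low-dose set (default 0.5).
#' @param config A [noise_sim_config()].
#' @param seed Master seed.
#' @return Object of class `degradation_result` with `per_case` and
#'   `summary` tibbles.
#' @export
degradation_experiment <- function(cohort_val, model,
                                   mixing_rates = c(0.25, 0.5, 0.75, 1),
                                   noise_reduction_fraction = 0.30,
                                   blur_sigma_mm = 0.75,
                                   dose_fraction = 0.5,
                                   config = noise_sim_config(), seed = 1) {
  if (length(cohort_val) == 0)
    stop("`cohort_val` must be non-empty", call. = FALSE)
  rows <- list()
  for (ci in seq_along(cohort_val)) {
    x <- cohort_val[[ci]]
    torso <- segment_torso(x)
    y <- simulate_low_dose(x, dose_fraction, config,
                           seed = derive_seed(seed, ci, 50))
    n <- extract_pure_noise(y, x)
    ref8 <- normalize_for_iqa(x)
    for (r in mixing_rates) {
      spec <- degradation_spec(noise_reduction_fraction, blur_sigma_mm, r)
      deg <- apply_degradation(x, n, spec)
      ssim <- compute_ssim(ref8, normalize_for_iqa(deg))
      resid <- y$pixels - deg$pixels
      rsi <- NA_real_
      if (any(resid != 0)) {
        s_hat <- predict_structure(model, resid)
        rr <- rsi_or_na(s_hat, resid, torso)
        if (!is.null(rr)) rsi <- rr$rsi
      }
      rows[[length(rows) + 1]] <- tibble(case = x$id, mixing_rate = r,
                                         ssim = ssim, rsi = rsi)
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(sort(unique(per_case$mixing_rate)),
                                   function(r) {
    sub <- per_case[per_case$mixing_rate == r, ]
    tibble(mixing_rate = r,
           mean_ssim = mean(sub$ssim), sd_ssim = sd(sub$ssim),
           mean_rsi = mean(sub$rsi, na.rm = TRUE),
           sd_rsi = sd(sub$rsi, na.rm = TRUE))
  }))
  structure(list(per_case = per_case, summary = summary),
            class = "degradation_result")
}

#' @export
print.degradation_result <- function(x, ...) {
  cat("Degradation sensitivity (SSIM vs RSI)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

# ---- pluggable denoisers ---------------------------------------------------

#' Define a denoiser under audit
#'
#' A denoiser is a named callable taking a [ct_image()] and returning a
#' [ct_image()] of identical shape and spacing with finite values.
#'
#' @param name Display name.
#' @param fn Function `ct_image -> ct_image`.
#' @return An object of class `ct_denoiser`.
#' @export
denoiser <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  structure(list(name = name, fn = fn), class = "ct_denoiser")
}

#' Reference toy denoisers
#'
#' `denoiser_identity()` returns its input unchanged (residual is zero);
#' `denoiser_gaussian()` blurs with a physical sigma — the blur removes
#' noise but leaks anatomy into the residual, more so at larger sigma;
#' `denoiser_oracle()` subtracts the known simulated noise exactly, keyed
#' by image id, leaving a structure-free residual.
#'
#' @param sigma_mm Blur sigma in millimetres.
#' @param name Optional display name.
#' @param noise_map Named list of [noise_image()] objects keyed by image id.
#' @return A [denoiser()].
#' @export
denoiser_identity <- function(name = "identity")
  denoiser(name, function(img) img)

#' @rdname denoiser_identity
#' @export
denoiser_gaussian <- function(sigma_mm = 1.0,
                              name = sprintf("gaussian_%.2gmm", sigma_mm)) {
  denoiser(name, function(img) {
    ct_image(clamp_hu(cpp_gauss_blur(img$pixels, sigma_mm / img$spacing_mm)),
             img$spacing_mm, img$dose_fraction, img$id)
  })
}

#' @rdname denoiser_identity
#' @export
denoiser_oracle <- function(noise_map, name = "oracle") {
  denoiser(name, function(img) {
    n <- noise_map[[img$id]]
    if (is.null(n))
      stop("oracle denoiser has no noise image for '", img$id, "'",
           call. = FALSE)
    ct_image(clamp_hu(img$pixels - n$pixels), img$spacing_mm,
             dose_fraction = 1, id = img$id)
  })
}

apply_denoiser <- function(dn, img) {
  out <- dn$fn(img)
  if (!inherits(out, "ct_image") ||
      !identical(dim(out$pixels), dim(img$pixels)) ||
      !all(is.finite(out$pixels)))
    stop("denoiser '", dn$name,
         "' violated its contract (shape/finite output)", call. = FALSE)
  out
}

#' Audit a set of denoisers from their residual noise
#'
#' For every denoiser and low-dose image: the residual (low-dose minus
#' denoised) is passed through the structure predictor, the RSI is computed
#' under the torso mask, and an optional heatmap is written. When reference
#' images are given, SSIM against the reference is added. Denoisers are
#' ranked by mean RSI ascending (lower = purer residual noise).
#'
#' @param denoisers List of [denoiser()] objects.
#' @param low_dose_images List of low-dose [ct_image()] objects.
#' @param model A trained `structure_predictor`.
#' @param reference_images Optional list of standard-dose images, parallel
#'   to `low_dose_images`.
#' @param heatmap_dir Optional directory for PNG heatmaps.
#' @return Object of class `audit_report` with `per_slice` and `summary`
#'   tibbles (summary statistics are recomputable from the per-slice rows).
#' @export
audit_denoiser <- function(denoisers, low_dose_images, model,
                           reference_images = NULL, heatmap_dir = NULL) {
  if (inherits(denoisers, "ct_denoiser")) denoisers <- list(denoisers)
  if (length(low_dose_images) == 0)
    stop("`low_dose_images` must be non-empty", call. = FALSE)
  if (!is.null(heatmap_dir))
    dir.create(heatmap_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (dn in denoisers) {
    for (ii in seq_along(low_dose_images)) {
      y <- low_dose_images[[ii]]
      torso <- segment_torso(y)
      den <- apply_denoiser(dn, y)
      resid <- y$pixels - den$pixels
      rsi <- NA_real_; clipped <- NA
      heatmap_path <- NA_character_
      if (any(resid != 0)) {
        s_hat <- predict_structure(model, resid)
        rr <- rsi_or_na(s_hat, resid, torso)
        if (!is.null(rr)) { rsi <- rr$rsi; clipped <- rr$clipped }
        if (!is.null(heatmap_dir)) {
          heatmap_path <- file.path(
            heatmap_dir, sprintf("%s_%s.png", dn$name, y$id))
          write_heatmap_png(make_heatmap(s_hat, den), heatmap_path)
        }
      }
      ssim <- NA_real_
      if (!is.null(reference_images))
        ssim <- compute_ssim(normalize_for_iqa(reference_images[[ii]]),
                             normalize_for_iqa(den))
      rows[[length(rows) + 1]] <- tibble(
        denoiser = dn$name, case = y$id, rsi = rsi, clipped = clipped,
        ssim_vs_reference = ssim, heatmap = heatmap_path)
    }
  }
  per_slice <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(unique(per_slice$denoiser), function(nm) {
    sub <- per_slice[per_slice$denoiser == nm, ]
    tibble(denoiser = nm,
           mean_rsi = mean(sub$rsi, na.rm = TRUE),
           sd_rsi = sd(sub$rsi, na.rm = TRUE),
           n = sum(!is.na(sub$rsi)),
           mean_ssim = mean(sub$ssim_vs_reference, na.rm = TRUE))
  }))
  summary <- summary[order(summary$mean_rsi, na.last = TRUE), ]
  structure(list(per_slice = per_slice, summary = summary),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("Denoiser audit (ranked by mean RSI, ascending)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
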