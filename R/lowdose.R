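# Low-dose CT noise simulation in the sinogram domain.
#
# The standard-dose image is converted from HU to linear attenuation,
# forward-projected (parallel beam), and zero-mean Gaussian noise with
# variance (1/alpha - 1) * exp(p) / i0 is injected per detector sample
# (alpha = dose fraction, p = line integral). The noise-only sinogram is
# reconstructed by Ram-Lak filtered back projection and added to the image
# in HU. This reproduces the three properties the downstream method relies
# on: dose-scaled magnitude, attenuation dependence, and streak-correlated
# texture. Electronic detector noise is omitted by default (the quantum term
# dominates at the dose fractions studied) but a constant floor is exposed.

#' Configure the low-dose noise simulator
#'
#' @param i0 Reference photon fluence (unitless scale). Calibrated so that
#'   torso noise sd at 50\% dose is roughly 15-25 HU on the default phantom.
#' @param mu_water_per_mm Linear attenuation coefficient of water used for
#'   the HU-to-attenuation conversion (per mm).
#' @param n_angles Number of projection angles over 180 degrees (>= 90).
#' @param fbp_filter Reconstruction filter: `"ram-lak"` or `"hann"`.
#' @param electronic_noise_sd Optional constant detector noise floor (sd in
#'   line-integral units); `0` disables it.
#' @param seed Master seed used when no per-call seed is given.
#' @return An object of class `noise_sim_config`.
#' @export
noise_sim_config <- function(i0 = 2.5e5, mu_water_per_mm = 0.0205,
                             n_angles = 360, fbp_filter = c("ram-lak", "hann"),
                             electronic_noise_sd = 0, seed = 1) {
  fbp_filter <- match.arg(fbp_filter)
  if (!is.numeric(i0) || i0 <= 0)
    stop("`i0` must be positive", call. = FALSE)
  if (!is.numeric(n_angles) || n_angles < 90)
    stop("`n_angles` must be at least 90", call. = FALSE)
  if (!is.numeric(mu_water_per_mm) || mu_water_per_mm <= 0)
    stop("`mu_water_per_mm` must be positive", call. = FALSE)
  structure(
    list(i0 = as.numeric(i0), mu_water_per_mm = as.numeric(mu_water_per_mm),
         n_angles = as.integer(n_angles), fbp_filter = fbp_filter,
         electronic_noise_sd = as.numeric(electronic_noise_sd),
         seed = as.integer(seed)),
    class = "noise_sim_config")
}

n_detectors <- function(n) 2L * as.integer(ceiling(sqrt(2) * n / 2)) + 1L

#' Forward-project a CT image to attenuation line integrals
#'
#' HU are mapped to linear attenuation `mu = (HU/1000 + 1) * mu_water` and
#' integrated along parallel rays; line integrals are dimensionless.
#'
#' @param x A [ct_image()].
#' @param config A [noise_sim_config()].
#' @return Matrix `n_det x n_angles` of line integrals.
#' @export
attenuation_sinogram <- function(x, config = noise_sim_config()) {
  px <- as_pixel_matrix(x)
  mu <- (px / 1000 + 1) * config$mu_water_per_mm
  mu[mu < 0] <- 0
  cpp_radon(mu, config$n_angles, n_detectors(max(dim(px)))) * x$spacing_mm
}

#' Draw the injected sinogram noise for a dose fraction
#'
#' Exposes the quantum-noise model directly: per detector sample the noise is
#' `N(0, (1/alpha - 1) * exp(p) / i0)`, optionally plus a constant
#' electronic floor. Used internally by [simulate_low_dose()] and available
#' for calibration and model diagnostics.
#'
#' @param p Attenuation sinogram from [attenuation_sinogram()].
#' @param dose_fraction Dose fraction alpha in (0, 1].
#' @param config A [noise_sim_config()].
#' @param seed Integer seed for the draw.
#' @return Matrix of sinogram-domain noise, same shape as `p`.
#' @export
draw_noise_sinogram <- function(p, dose_fraction, config = noise_sim_config(),
                                seed = config$seed) {
  if (dose_fraction <= 0 || dose_fraction > 1)
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  v <- (1 / dose_fraction - 1) * exp(pmin(p, 30)) / config$i0 +
    config$electronic_noise_sd^2
  with_seed(seed, matrix(rnorm(length(p), sd = sqrt(as.vector(v))),
                         nrow(p), ncol(p)))
}

# Discrete ramp-filter transfer function (Ram-Lak spatial kernel of Kak &
# Slaney), optionally Hann-windowed, for projections padded to length m.
ramp_transfer <- function(m, filter = "ram-lak") {
  h <- numeric(m)
  h[1] <- 0.25
  nn <- seq(1, m / 2)
  odd <- nn[nn %% 2 == 1]
  h[1 + odd] <- -1 / (pi^2 * odd^2)
  h[m + 1 - odd] <- -1 / (pi^2 * odd^2)
  H <- Re(fft(h))
  if (filter == "hann") {
    f <- seq(0, m - 1)
    f <- pmin(f, m - f) / (m / 2)
    H <- H * 0.5 * (1 + cos(pi * f))
  }
  H
}

fbp_reconstruct <- function(sino, n, spacing_mm, filter = "ram-lak") {
  n_det <- nrow(sino)
  m <- 2^ceiling(log2(2 * n_det))
  H <- ramp_transfer(m, filter)
  padded <- rbind(sino, matrix(0, m - n_det, ncol(sino)))
  filtered <- Re(mvfft(mvfft(padded) * H, inverse = TRUE)) / m
  filtered <- filtered[seq_len(n_det), , drop = FALSE]
  cpp_backproject(filtered, n, n) / spacing_mm
}

#' Simulate a reduced-dose CT image
#'
#' Adds sinogram-domain quantum noise (scaled by the dose fraction and the
#' attenuation path) reconstructed with filtered back projection to the
#' standard-dose image. `dose_fraction = 1` returns the input unchanged.
#' Deterministic given `seed`; by default the seed is derived from the config
#' master seed, the image id and the dose, so each (case, dose) pair has its
#' own stream.
#'
#' @param x Standard-dose [ct_image()] (`dose_fraction == 1`).
#' @param dose_fraction Target dose fraction in (0, 1].
#' @param config A [noise_sim_config()].
#' @param seed Optional integer seed overriding the derived stream.
#' @return A [ct_image()] with the requested `dose_fraction`.
#' @export
simulate_low_dose <- function(x, dose_fraction, config = noise_sim_config(),
                              seed = NULL) {
  if (!inherits(x, "ct_image"))
    stop("`x` must be a ct_image", call. = FALSE)
  if (!is.numeric(dose_fraction) || length(dose_fraction) != 1 ||
      dose_fraction <= 0 || dose_fraction > 1)
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  if (x$dose_fraction != 1)
    stop("`x` must be a standard-dose image (dose_fraction == 1)",
         call. = FALSE)
  if (dose_fraction == 1) {
    y <- x
    return(y)
  }
  if (is.null(seed))
    seed <- derive_seed(config$seed, sum(utf8ToInt(x$id)),
                        round(dose_fraction * 100))
  p <- attenuation_sinogram(x, config)
  simulate_low_dose_from_sinogram(x, p, dose_fraction, config, seed)
}

# Internal fast path: reuse a precomputed attenuation sinogram (the forward
# projection depends only on x, so cohort builders compute it once per case).
simulate_low_dose_from_sinogram <- function(x, p, dose_fraction, config,
                                            seed) {
  noise_sino <- draw_noise_sinogram(p, dose_fraction, config, seed)
  n_hu <- fbp_reconstruct(noise_sino, nrow(x$pixels), x$spacing_mm,
                          config$fbp_filter) /
    config$mu_water_per_mm * 1000
  y <- clamp_hu(x$pixels + n_hu)
  ct_image(y, x$spacing_mm, dose_fraction = dose_fraction, id = x$id)
}

#' Extract the pure noise image
#'
#' The additive decomposition of a simulated low-dose image: the low-dose
#' image equals the standard-dose image plus noise, so the noise is the
#' elementwise difference, exact to the bit.
#'
#' @param y Low-dose [ct_image()].
#' @param x Standard-dose [ct_image()] of the same case.
#' @return A [noise_image()].
#' @export
extract_pure_noise <- function(y, x) {
  if (!inherits(y, "ct_image") || !inherits(x, "ct_image"))
    stop("`y` and `x` must be ct_image objects", call. = FALSE)
  check_same_shape(y, x, "`y` and `x`")
  if (y$spacing_mm != x$spacing_mm)
    stop("`y` and `x` must share pixel spacing", call. = FALSE)
  if (y$id != x$id)
    stop("`y` and `x` must come from the same source image", call. = FALSE)
  noise_image(y$pixels - x$pixels, dose_fraction = y$dose_fraction,
              source_id = x$id)
}

#' Noise standard deviation within a region
#'
#' @param n A [noise_image()].
#' @param mask A [region_mask()] (non-empty).
#' @return Sample standard deviation in HU.
#' @export
noise_std_in_region <- function(n, mask) {
  m <- as_mask_matrix(mask)
  check_same_shape(n, m, "`n` and `mask`")
  if (!any(m))
    ctaudit_error("mask is empty", "ctaudit_error_empty_mask")
  sd(as_pixel_matrix(n)[m])
}
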