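# Spurious-structure synthesis: band-pass anatomy under random circular
# masks, embedded into pure noise to form supervised training pairs.

#' Difference-of-Gaussians band-pass filter
#'
#' `G(sigma) * x - G(k * sigma) * x` with a fixed outer/inner sigma ratio
#' (default 1.6, the standard Laplacian-of-Gaussian approximation). Linear
#' and shift-equivariant; Gaussian filtering uses reflect boundaries to
#' avoid edge halos.
#'
#' @param x A [ct_image()] or numeric matrix.
#' @param sigma_px Inner Gaussian sigma in pixels (> 0).
#' @param k_ratio Outer/inner sigma ratio (> 1).
#' @return A numeric matrix, same shape as the input.
#' @export
dog_filter <- function(x, sigma_px, k_ratio = 1.6) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px <= 0)
    stop("`sigma_px` must be positive", call. = FALSE)
  if (!is.numeric(k_ratio) || k_ratio <= 1)
    stop("`k_ratio` must exceed 1", call. = FALSE)
  m <- as_pixel_matrix(x)
  cpp_gauss_blur(m, sigma_px) - cpp_gauss_blur(m, k_ratio * sigma_px)
}

disc_mask <- function(dims, center, radius_px) {
  ii <- matrix(seq_len(dims[1]), dims[1], dims[2])
  jj <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  (ii - center[1])^2 + (jj - center[2])^2 <= radius_px^2
}

#' Sample random circular masks inside the torso
#'
#' Draws `n_masks` disc centres uniformly from torso pixels whose full disc
#' lies inside the image, and returns the union as a `circle_set` mask.
#' Discs may overlap each other unless an `avoid` mask is given, in which
#' case each disc is rejection-sampled to have zero overlap with `avoid`.
#'
#' @param torso A [region_mask()] with role `torso` (non-empty).
#' @param n_masks Number of discs (default 5).
#' @param diameter_mm Physical disc diameter (default 30 mm).
#' @param spacing_mm Pixel size used to convert the diameter to pixels.
#' @param seed Integer seed; the draw is deterministic given it.
#' @param avoid Optional mask (or `region_mask`) the discs must not touch.
#' @param max_tries Rejection-sampling budget per disc.
#' @return A [region_mask()] with role `circle_set`, carrying `centers`,
#'   `diameter_mm` and `radius_px`.
#' @export
sample_circular_masks <- function(torso, n_masks = 5, diameter_mm = 30,
                                  spacing_mm, seed = 1, avoid = NULL,
                                  max_tries = 1000) {
  tm <- as_mask_matrix(torso)
  if (!any(tm))
    ctaudit_error("torso mask is empty", "ctaudit_error_empty_mask")
  if (n_masks < 0) stop("`n_masks` must be non-negative", call. = FALSE)
  radius_px <- diameter_mm / 2 / spacing_mm
  if (radius_px < 3)
    stop("disc radius below 3 px at this spacing", call. = FALSE)
  dims <- dim(tm)
  r_ceil <- ceiling(radius_px)
  ii <- matrix(seq_len(dims[1]), dims[1], dims[2])
  jj <- matrix(seq_len(dims[2]), dims[1], dims[2], byrow = TRUE)
  ok <- tm & ii > r_ceil & ii <= dims[1] - r_ceil &
    jj > r_ceil & jj <= dims[2] - r_ceil
  cand <- which(ok)
  if (n_masks > 0 && length(cand) == 0)
    ctaudit_error("no valid disc centre exists", "ctaudit_error_placement")
  avoid_m <- if (is.null(avoid)) NULL else as_mask_matrix(avoid)

  out <- matrix(FALSE, dims[1], dims[2])
  centers <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  with_seed(seed, {
    for (k in seq_len(n_masks)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        idx <- cand[sample.int(length(cand), 1)]
        ctr <- c((idx - 1) %% dims[1] + 1, (idx - 1) %/% dims[1] + 1)
        d <- disc_mask(dims, ctr, radius_px)
        if (!is.null(avoid_m) && any(d & avoid_m)) next
        out <- out | d
        centers <- rbind(centers, ctr)
        placed <- TRUE
        break
      }
      if (!placed)
        ctaudit_error("could not place a non-overlapping disc",
                      "ctaudit_error_placement")
    }
  })
  region_mask(out, role = "circle_set", centers = centers,
              diameter_mm = diameter_mm, radius_px = radius_px)
}

#' Synthesise a spurious structural component
#'
#' Band-pass filters the standard-dose image with a randomly drawn sigma
#' (uniform on 0.5-1.5 px unless given) and multiplies elementwise by the
#' union of random circular masks, so the component is exactly zero outside
#' the discs.
#'
#' @param x Standard-dose [ct_image()].
#' @param torso Torso [region_mask()] used to place the discs.
#' @param seed Integer seed controlling sigma and disc placement.
#' @param sigma_px Optional fixed sigma in `[0.5, 1.5]` px.
#' @param n_masks,diameter_mm Disc parameters (defaults 5 discs of 30 mm).
#' @param k_ratio Outer/inner sigma ratio of the band-pass filter.
#' @return A [structure_component()].
#' @export
make_structure_component <- function(x, torso, seed = 1, sigma_px = NULL,
                                     n_masks = 5, diameter_mm = 30,
                                     k_ratio = 1.6) {
  if (!inherits(x, "ct_image"))
    stop("`x` must be a ct_image", call. = FALSE)
  if (is.null(sigma_px))
    sigma_px <- with_seed(derive_seed(seed, 1), runif(1, 0.5, 1.5))
  if (sigma_px < 0.5 || sigma_px > 1.5)
    stop("`sigma_px` must lie in [0.5, 1.5]", call. = FALSE)
  mask <- sample_circular_masks(torso, n_masks = n_masks,
                                diameter_mm = diameter_mm,
                                spacing_mm = x$spacing_mm,
                                seed = derive_seed(seed, 2))
  s <- dog_filter(x, sigma_px, k_ratio)
  s[!mask$pixels] <- 0
  structure_component(s, sigma_px = sigma_px, mask = mask, source_id = x$id)
}

#' Embed a structural component into pure noise
#'
#' The structure-embedded noise image is the exact elementwise sum of the
#' pure noise and the structural component.
#'
#' @param n A [noise_image()].
#' @param s A [structure_component()] of the same shape.
#' @return An object of class `structure_embedded_noise` with fields
#'   `pixels` (the sum), `noise_ref` and `structure_ref`.
#' @export
embed_structure <- function(n, s) {
  if (!inherits(n, "noise_image"))
    stop("`n` must be a noise_image", call. = FALSE)
  if (!inherits(s, "structure_component"))
    stop("`s` must be a structure_component", call. = FALSE)
  check_same_shape(n, s, "`n` and `s`")
  structure(
    list(pixels = n$pixels + s$pixels, noise_ref = n$source_id,
         structure_ref = s$source_id, dose_fraction = n$dose_fraction),
    class = "structure_embedded_noise")
}

#' @export
print.structure_embedded_noise <- function(x, ...) {
  cat(sprintf("<structure_embedded_noise from '%s'> %d x %d px\n",
              x$noise_ref, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

#' Build a supervised training set of (z, s) pairs
#'
#' For every case x dose x sample: a fresh noise realisation, a fresh sigma
#' and disc draw, and the paired structure-embedded input `z = n + s` with
#' ground truth `s`. All sub-seeds derive from `seed`, so regeneration with
#' the same arguments reproduces the manifest exactly. The train/validation
#' split follows the cohort's per-case split (never by sample).
#'
#' @param cohort A non-empty list of standard-dose [ct_image()] objects,
#'   typically from [generate_cohort()].
#' @param dose_fractions Dose fractions to simulate (default 25/50/75\%).
#' @param per_case_samples Pairs per case per dose.
#' @param config A [noise_sim_config()].
#' @param seed Master seed.
#' @return An object of class `training_set`: list with `pairs` (each a
#'   list `z`, `s`, `meta`) and a `manifest` tibble.
#' @export
build_training_set <- function(cohort, dose_fractions = c(0.25, 0.5, 0.75),
                               per_case_samples = 1,
                               config = noise_sim_config(), seed = 1) {
  if (length(cohort) == 0)
    stop("`cohort` must be non-empty", call. = FALSE)
  if (any(dose_fractions <= 0 | dose_fractions > 1))
    stop("dose fractions must lie in (0, 1]", call. = FALSE)
  split <- attr(cohort, "split")
  if (is.null(split))
    split <- vapply(cohort, function(x) attr(x, "split") %||% "train", "")
  pairs <- list()
  rows <- list()
  for (i in seq_along(cohort)) {
    x <- cohort[[i]]
    torso <- segment_torso(x)
    p <- attenuation_sinogram(x, config)
    for (d in dose_fractions) {
      for (k in seq_len(per_case_samples)) {
        seed_noise <- derive_seed(seed, i, round(d * 100), k, 1)
        seed_struct <- derive_seed(seed, i, round(d * 100), k, 2)
        y <- simulate_low_dose_from_sinogram(x, p, d, config, seed_noise)
        n <- extract_pure_noise(y, x)
        s <- make_structure_component(x, torso, seed = seed_struct)
        z <- embed_structure(n, s)
        pairs[[length(pairs) + 1]] <- list(
          z = z$pixels, s = s$pixels,
          meta = list(case = x$id, dose = d, sample = k,
                      sigma_px = s$sigma_px, split = split[i],
                      seed_noise = seed_noise, seed_struct = seed_struct))
        rows[[length(rows) + 1]] <- tibble(
          case = x$id, dose = d, sample = k, sigma_px = s$sigma_px,
          split = split[i], seed_noise = seed_noise,
          seed_struct = seed_struct)
      }
    }
  }
  structure(list(pairs = pairs, manifest = do.call(rbind, rows)),
            class = "training_set")
}

#' @export
print.training_set <- function(x, ...) {
  cat(sprintf("<training_set> %d pairs (%d train / %d val cases)\n",
              length(x$pairs),
              length(unique(x$manifest$case[x$manifest$split == "train"])),
              length(unique(x$manifest$case[x$manifest$split == "val"]))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
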