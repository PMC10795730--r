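# Synthetic torso phantoms: a seeded stand-in cohort for patient CT slices.
# Each phantom is an elliptical soft-tissue body on an air background, with
# contrast "organ" ellipses, an optional bone shell + spine, a smooth
# large-scale field and fine-grained internal texture. The texture carries
# the high-frequency content that band-pass (DoG) filtering later extracts
# as spurious structure, so its amplitude is a first-class parameter.

PHANTOM_HU <- list(
  air = -1000,          # background
  soft_tissue = 45,     # body baseline (contrast-enhanced abdomen scale)
  organ_delta = 70,     # max |offset| of organ ellipses from baseline
  bone_shell = 950,     # rib-like cortical shell
  bone_spine = 850      # posterior spine ellipse
)

#' Specify a synthetic torso phantom
#'
#' @param image_size Pixels per side (square grid), at least 64.
#' @param spacing_mm Isotropic pixel size in millimetres.
#' @param n_organs Number of internal contrast ellipses.
#' @param texture_amplitude_hu Standard deviation (HU) of the internal
#'   texture added inside soft tissue; `0` gives a piecewise-constant
#'   interior.
#' @param bone Add a rib-like high-attenuation shell and spine.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256, spacing_mm = 0.8, n_organs = 6,
                         texture_amplitude_hu = 35, bone = TRUE, seed = 7) {
  if (!is.numeric(image_size) || image_size < 64)
    stop("`image_size` must be at least 64", call. = FALSE)
  if (!is.numeric(spacing_mm) || spacing_mm <= 0)
    stop("`spacing_mm` must be positive", call. = FALSE)
  if (!is.numeric(n_organs) || n_organs < 0)
    stop("`n_organs` must be non-negative", call. = FALSE)
  if (!is.numeric(texture_amplitude_hu) || texture_amplitude_hu < 0)
    stop("`texture_amplitude_hu` must be non-negative", call. = FALSE)
  structure(
    list(image_size = as.integer(image_size),
         spacing_mm = as.numeric(spacing_mm),
         n_organs = as.integer(n_organs),
         texture_amplitude_hu = as.numeric(texture_amplitude_hu),
         bone = isTRUE(bone), seed = as.integer(seed)),
    class = "phantom_spec")
}

ellipse_mask <- function(n, cy, cx, ry, rx, theta = 0) {
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  dy <- ii - cy; dx <- jj - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Generate a synthetic standard-dose torso phantom
#'
#' Deterministic given `spec$seed`. The returned image carries two
#' attributes used by downstream code and tests: `"base"`, the texture-free
#' piecewise image, and `"body"`, the logical body mask. Texture is
#' normalised so that its sample standard deviation over the soft-tissue
#' region equals `texture_amplitude_hu` exactly (before HU clamping).
#'
#' @param spec A [phantom_spec()].
#' @return A [ct_image()] with `dose_fraction = 1`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    stop("`spec` must be a phantom_spec", call. = FALSE)
  n <- spec$image_size
  with_seed(spec$seed, {
    cy <- (n + 1) / 2
    cx <- (n + 1) / 2
    rx <- 0.42 * n * runif(1, 0.96, 1.04)
    ry <- 0.32 * n * runif(1, 0.96, 1.04)
    body <- ellipse_mask(n, cy, cx, ry, rx)
    base <- matrix(PHANTOM_HU$air, n, n)
    base[body] <- PHANTOM_HU$soft_tissue

    # internal organ ellipses with distinct mean HU
    for (k in seq_len(spec$n_organs)) {
      oc <- c(cy + runif(1, -0.55, 0.55) * ry,
              cx + runif(1, -0.55, 0.55) * rx)
      ax <- runif(2, 0.05, 0.16) * n
      th <- runif(1, 0, pi)
      delta <- runif(1, -1, 1) * PHANTOM_HU$organ_delta
      om <- ellipse_mask(n, oc[1], oc[2], ax[1], ax[2], th) & body
      base[om] <- PHANTOM_HU$soft_tissue + delta
    }

    bone_mask <- matrix(FALSE, n, n)
    if (spec$bone) {
      shell <- ellipse_mask(n, cy, cx, 0.97 * ry, 0.97 * rx) &
        !ellipse_mask(n, cy, cx, 0.92 * ry, 0.92 * rx)
      spine <- ellipse_mask(n, cy + 0.62 * ry, cx, 0.10 * n, 0.06 * n)
      base[shell] <- PHANTOM_HU$bone_shell
      base[spine & body] <- PHANTOM_HU$bone_spine
      bone_mask <- shell | (spine & body)
    }

    # internal texture: a slow organ-scale drift, a smooth field with
    # correlation length ~2-4 px, and fine grain, jointly normalised to the
    # requested sd over soft tissue
    soft <- body & !bone_mask
    px <- base
    if (spec$texture_amplitude_hu > 0) {
      t_drift <- cpp_gauss_blur(matrix(rnorm(n * n), n, n), n / 24)
      t_smooth <- cpp_gauss_blur(matrix(rnorm(n * n), n, n), 1.2)
      t_fine <- matrix(rnorm(n * n), n, n)
      tex <- 0.35 * t_drift / sd(t_drift[soft]) +
        0.75 * t_smooth / sd(t_smooth[soft]) +
        0.45 * t_fine / sd(t_fine[soft])
      tex <- tex / sd(tex[soft]) * spec$texture_amplitude_hu
      px[soft] <- px[soft] + tex[soft]
    }
    px <- clamp_hu(px)
    out <- ct_image(px, spec$spacing_mm, dose_fraction = 1,
                    id = sprintf("phantom_seed%d", spec$seed))
    attr(out, "base") <- base
    attr(out, "body") <- body
    out
  })
}

#' Generate a phantom cohort with per-case layout jitter
#'
#' Cases draw disjoint sub-seeds from `seed`, so the cohort is reproducible
#' and all cases differ in organ layout and texture realisation. The first
#' 75\% of cases (at least one) are tagged `train`, the rest `val`; the
#' split is by case, never by sample.
#'
#' @param n_cases Number of phantoms (>= 1).
#' @param base_spec A [phantom_spec()] supplying all non-seed parameters.
#' @param seed Master seed for the cohort.
#' @return A list of [ct_image()] objects; each carries a `"split"`
#'   attribute, and the list itself a `"split"` character vector.
#' @export
generate_cohort <- function(n_cases, base_spec = phantom_spec(), seed = 1) {
  if (!is.numeric(n_cases) || n_cases < 1)
    stop("`n_cases` must be at least 1", call. = FALSE)
  n_cases <- as.integer(n_cases)
  n_train <- max(1L, as.integer(floor(0.75 * n_cases)))
  split <- rep(c("train", "val"), c(n_train, n_cases - n_train))
  cohort <- lapply(seq_len(n_cases), function(i) {
    sp <- base_spec
    sp$seed <- derive_seed(seed, i)
    img <- generate_phantom(sp)
    img$id <- sprintf("case_%03d", i)
    attr(img, "split") <- split[i]
    img
  })
  attr(cohort, "split") <- split
  attr(cohort, "seed") <- as.integer(seed)
  cohort
}
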