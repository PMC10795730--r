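# Core containers: CT images, noise images, structural components, masks.
# All pixel grids are numeric matrices in Hounsfield units (HU); air = -1000,
# water = 0. Grids are indexed [row, column].

HU_MIN <- -1024
HU_MAX <- 3071

#' Construct a CT image
#'
#' A `ct_image` is a 2D grid of Hounsfield units with isotropic pixel spacing
#' and a dose fraction relative to the standard-dose acquisition.
#'
#' @param pixels Numeric matrix of HU values, all finite and within
#'   `[-1024, 3071]`.
#' @param spacing_mm Physical size of one pixel in millimetres (> 0).
#' @param dose_fraction Dose relative to standard dose, in `(0, 1]`.
#' @param id Opaque label used for provenance tracking.
#' @return An object of class `ct_image`.
#' @export
ct_image <- function(pixels, spacing_mm, dose_fraction = 1, id = "ct") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("all pixel values must be finite", call. = FALSE)
  if (any(pixels < HU_MIN) || any(pixels > HU_MAX))
    stop("pixel values must lie within [-1024, 3071] HU", call. = FALSE)
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 1 || spacing_mm <= 0)
    stop("`spacing_mm` must be a positive scalar", call. = FALSE)
  if (!is.numeric(dose_fraction) || length(dose_fraction) != 1 ||
      dose_fraction <= 0 || dose_fraction > 1)
    stop("`dose_fraction` must lie in (0, 1]", call. = FALSE)
  structure(
    list(pixels = pixels, spacing_mm = as.numeric(spacing_mm),
         dose_fraction = as.numeric(dose_fraction), id = as.character(id)),
    class = "ct_image")
}

#' @export
print.ct_image <- function(x, ...) {
  cat(sprintf("<ct_image '%s'> %d x %d px, %.3g mm/px, dose %.0f%%\n",
              x$id, nrow(x$pixels), ncol(x$pixels), x$spacing_mm,
              100 * x$dose_fraction))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Construct a noise image
#'
#' A signed HU-difference grid: either pure noise (low-dose minus
#' standard-dose) or residual noise (low-dose minus denoised).
#'
#' @param pixels Numeric matrix of signed HU differences (finite).
#' @param dose_fraction Dose fraction of the low-dose image it derives from.
#' @param source_id Id of the parent `ct_image`.
#' @return An object of class `noise_image`.
#' @export
noise_image <- function(pixels, dose_fraction, source_id = "ct") {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    stop("`pixels` must be a finite numeric matrix", call. = FALSE)
  structure(
    list(pixels = pixels, dose_fraction = as.numeric(dose_fraction),
         source_id = as.character(source_id)),
    class = "noise_image")
}

#' @export
print.noise_image <- function(x, ...) {
  cat(sprintf("<noise_image from '%s'> %d x %d px, dose %.0f%%, sd %.2f HU\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels),
              100 * x$dose_fraction, sd(x$pixels)))
  invisible(x)
}

#' Construct a region mask
#'
#' Boolean grid marking either the torso (body) region or a set of circular
#' regions of interest.
#'
#' @param pixels Logical matrix.
#' @param role `"torso"` or `"circle_set"`.
#' @param centers Optional matrix of disc centres (`row`, `col`), for
#'   `role = "circle_set"`.
#' @param diameter_mm Optional physical disc diameter.
#' @param radius_px Optional disc radius in pixels.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(pixels, role = c("torso", "circle_set"),
                        centers = NULL, diameter_mm = NULL,
                        radius_px = NULL) {
  role <- match.arg(role)
  if (!is.matrix(pixels) || !is.logical(pixels))
    stop("`pixels` must be a logical matrix", call. = FALSE)
  structure(
    list(pixels = pixels, role = role, centers = centers,
         diameter_mm = diameter_mm, radius_px = radius_px),
    class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask role '%s'> %d x %d px, %d true pixels\n",
              x$role, nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Construct a structural component
#'
#' Signed HU-difference grid holding band-pass structure, either synthesised
#' under circular masks or predicted by the structure-predictor network.
#'
#' @param pixels Numeric matrix of signed HU differences.
#' @param sigma_px Inner Gaussian sigma used by the band-pass filter
#'   (`NA` for predictions).
#' @param mask Optional `region_mask` (role `circle_set`) outside which the
#'   component is exactly zero.
#' @param source_id Id of the image it derives from.
#' @param predicted Logical; `TRUE` marks a network prediction (no
#'   generating mask).
#' @return An object of class `structure_component`.
#' @export
structure_component <- function(pixels, sigma_px = NA_real_, mask = NULL,
                                source_id = "ct", predicted = FALSE) {
  if (!is.matrix(pixels) || !all(is.finite(pixels)))
    stop("`pixels` must be a finite numeric matrix", call. = FALSE)
  if (!predicted) {
    if (!is.finite(sigma_px) || sigma_px < 0.5 || sigma_px > 1.5)
      stop("`sigma_px` must lie in [0.5, 1.5]", call. = FALSE)
    if (!is.null(mask) && any(pixels[!mask$pixels] != 0))
      stop("component must be exactly zero outside its mask", call. = FALSE)
  }
  structure(
    list(pixels = pixels, sigma_px = sigma_px, mask = mask,
         source_id = as.character(source_id), predicted = predicted),
    class = "structure_component")
}

#' @export
print.structure_component <- function(x, ...) {
  kind <- if (x$predicted) "predicted" else
    sprintf("synthesised (sigma %.2f px)", x$sigma_px)
  cat(sprintf("<structure_component %s> %d x %d px, mean |s| %.2f HU\n",
              kind, nrow(x$pixels), ncol(x$pixels), mean(abs(x$pixels))))
  invisible(x)
}

# ---- internal helpers ------------------------------------------------------

as_pixel_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, c("ct_image", "noise_image", "structure_component")))
    return(x$pixels)
  if (inherits(x, "region_mask")) return(x$pixels)
  stop("cannot extract a pixel grid from an object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

as_mask_matrix <- function(x) {
  m <- if (inherits(x, "region_mask")) x$pixels else x
  if (!is.matrix(m) || !is.logical(m))
    stop("mask must be a logical matrix or region_mask", call. = FALSE)
  m
}

check_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(as_pixel_matrix(a)), dim(as_pixel_matrix(b))))
    stop(what, " must have identical dimensions", call. = FALSE)
  invisible(TRUE)
}

clamp_hu <- function(m) pmin(pmax(m, HU_MIN), HU_MAX)

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulations compose deterministically.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation: mixes a master seed with integer tags
# (case index, dose in percent, draw index, ...) into a 31-bit seed.
derive_seed <- function(master, ...) {
  parts <- c(as.numeric(master), vapply(list(...), as.numeric, numeric(1)))
  h <- 0
  for (p in parts) h <- (h * 69069 + abs(p) * 1000003 + 12345) %% 2147483629
  as.integer(h)
}

# Reflect-pad a matrix by (bottom, right) pixels (half-sample reflection).
pad_reflect <- function(m, bottom = 0, right = 0) {
  if (bottom > 0) {
    n <- nrow(m)
    m <- rbind(m, m[n:(n - bottom + 1), , drop = FALSE])
  }
  if (right > 0) {
    n <- ncol(m)
    m <- cbind(m, m[, n:(n - right + 1), drop = FALSE])
  }
  m
}

pad_reflect_all <- function(m, r) {
  n1 <- nrow(m); n2 <- ncol(m)
  m <- rbind(m[r:1, , drop = FALSE], m, m[n1:(n1 - r + 1), , drop = FALSE])
  cbind(m[, r:1, drop = FALSE], m, m[, n2:(n2 - r + 1), drop = FALSE])
}

ctaudit_error <- function(msg, class) {
  stop(structure(class = c(class, "ctaudit_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
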