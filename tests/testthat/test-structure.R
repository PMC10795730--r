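test_that("DoG kills constants, is linear, and matches the closed-form kernel", {
  const <- matrix(123.4, 40, 40)
  expect_lt(max(abs(dog_filter(const, 1.0))), 1e-9 * 123.4)

  set.seed(5)
  a <- matrix(rnorm(1600), 40, 40)
  b <- matrix(rnorm(1600), 40, 40)
  expect_equal(dog_filter(a + b, 0.8), dog_filter(a, 0.8) + dog_filter(b, 0.8),
               tolerance = 1e-12)

  # impulse response equals the difference of the two sampled, normalised
  # Gaussian kernels (recomputed here from first principles)
  n <- 41
  imp <- matrix(0, n, n); imp[21, 21] <- 1
  sigma <- 1.2; k_ratio <- 1.6
  kern2d <- function(s) {
    r <- max(1, ceiling(4 * s))
    k1 <- exp(-0.5 * (-r:r)^2 / s^2); k1 <- k1 / sum(k1)
    k2d <- outer(k1, k1)
    full <- matrix(0, n, n)
    full[(21 - r):(21 + r), (21 - r):(21 + r)] <- k2d
    full
  }
  expected <- kern2d(sigma) - kern2d(k_ratio * sigma)
  expect_equal(dog_filter(imp, sigma, k_ratio), expected, tolerance = 1e-12)
  expect_error(dog_filter(imp, -1), "positive")
})

test_that("DoG concentrates energy in its band", {
  n <- 96
  ii <- matrix(seq_len(n), n, n)
  sigma <- 1.0
  ramp <- ii / n                         # low-frequency content
  sine <- sin(2 * pi * ii / (2 * pi * sigma))  # period matched to the band
  ramp_resp <- max(abs(dog_filter(ramp, sigma)[20:76, 20:76]))
  sine_resp <- max(abs(dog_filter(sine, sigma)[20:76, 20:76]))
  expect_lt(ramp_resp, 0.01 * sine_resp)
})

test_that("circular masks have the right area, stay in bounds, and are reproducible", {
  ph <- small_phantom()
  torso <- segment_torso(ph)
  m <- sample_circular_masks(torso, n_masks = 5, diameter_mm = 30,
                             spacing_mm = 1, seed = 8)
  expect_identical(m$role, "circle_set")
  expect_equal(nrow(m$centers), 5)
  # each disc contains ~ pi * 15^2 pixels (checked on a fresh single disc)
  one <- sample_circular_masks(torso, n_masks = 1, diameter_mm = 30,
                               spacing_mm = 1, seed = 9)
  expect_equal(sum(one$pixels), pi * 15^2, tolerance = 0.03)
  m2 <- sample_circular_masks(torso, n_masks = 5, diameter_mm = 30,
                              spacing_mm = 1, seed = 8)
  expect_identical(m$pixels, m2$pixels)
  empty <- sample_circular_masks(torso, n_masks = 0, diameter_mm = 30,
                                 spacing_mm = 1, seed = 8)
  expect_false(any(empty$pixels))
  # all centres lie on torso pixels
  for (k in seq_len(nrow(m$centers)))
    expect_true(torso$pixels[m$centers[k, 1], m$centers[k, 2]])
})

test_that("mask placement honours exclusion zones or fails loudly", {
  ph <- small_phantom()
  torso <- segment_torso(ph)
  first <- sample_circular_masks(torso, 3, 30, 1, seed = 2)
  second <- sample_circular_masks(torso, 3, 30, 1, seed = 3, avoid = first)
  expect_false(any(first$pixels & second$pixels))
  everything <- region_mask(matrix(TRUE, 96, 96), "torso")
  expect_error(
    sample_circular_masks(torso, 1, 30, 1, seed = 4, avoid = everything,
                          max_tries = 20),
    class = "ctaudit_error_placement")
})

test_that("structure components are band-pass content under the discs only", {
  ph <- small_phantom()
  torso <- segment_torso(ph)
  s <- make_structure_component(ph, torso, seed = 10)
  expect_true(all(s$pixels[!s$mask$pixels] == 0))
  expect_gte(s$sigma_px, 0.5)
  expect_lte(s$sigma_px, 1.5)
  expect_gt(mean(abs(s$pixels[s$mask$pixels])), 0)
  # recompute mask * DoG directly
  expected <- dog_filter(ph, s$sigma_px)
  expected[!s$mask$pixels] <- 0
  expect_equal(s$pixels, expected, tolerance = 1e-12)
  # different sigma on the same image and discs gives a different component
  s075 <- make_structure_component(ph, torso, seed = 10, sigma_px = 0.75)
  s100 <- make_structure_component(ph, torso, seed = 10, sigma_px = 1.0)
  expect_identical(s075$mask$centers, s100$mask$centers)
  expect_false(identical(s075$pixels, s100$pixels))
  expect_error(make_structure_component(ph, torso, sigma_px = 2), "0.5")
})

test_that("a textureless phantom yields a vanishing structure component", {
  ph <- flat_phantom_big()
  inner <- inner_torso_mask(ph, scale = 0.35)  # discs clear of the body edge
  s <- make_structure_component(ph, inner, seed = 4)
  expect_lt(max(abs(s$pixels)), 1e-8)
})

test_that("embedding structure into noise is the exact elementwise sum", {
  ph <- small_phantom()
  y <- simulate_low_dose(ph, 0.5, test_sim_config(), seed = 3)
  n <- extract_pure_noise(y, ph)
  s <- make_structure_component(ph, segment_torso(ph), seed = 5)
  z <- embed_structure(n, s)
  expect_identical(z$pixels, n$pixels + s$pixels)
  expect_equal(mean(z$pixels), mean(n$pixels) + mean(s$pixels),
               tolerance = 1e-12)
  s0 <- make_structure_component(ph, segment_torso(ph), seed = 5)
  s0$pixels[] <- 0
  expect_identical(embed_structure(n, s0)$pixels, n$pixels)
  bad <- noise_image(matrix(0, 10, 10), 0.5)
  expect_error(embed_structure(bad, s), "dimensions")
})

test_that("training sets have the declared size, split and manifest determinism", {
  spec <- phantom_spec(image_size = 96, spacing_mm = 1, seed = 2)
  cohort <- generate_cohort(3, spec, seed = 55)
  cfg <- test_sim_config()
  ts <- build_training_set(cohort, dose_fractions = c(0.25, 0.5),
                           per_case_samples = 2, config = cfg, seed = 66)
  expect_length(ts$pairs, 3 * 2 * 2)
  expect_identical(nrow(ts$manifest), 12L)
  # split is attached per case, never per sample
  by_case <- split(ts$manifest$split, ts$manifest$case)
  for (sp in by_case) expect_length(unique(sp), 1)
  # pair invariant and manifest reproducibility
  ts2 <- build_training_set(cohort, dose_fractions = c(0.25, 0.5),
                            per_case_samples = 2, config = cfg, seed = 66)
  expect_identical(ts$manifest, ts2$manifest)
  expect_identical(ts$pairs[[5]]$z, ts2$pairs[[5]]$z)
  one <- build_training_set(cohort[1], dose_fractions = 0.5,
                            per_case_samples = 1, config = cfg, seed = 1)
  expect_length(one$pairs, 1)
  expect_error(build_training_set(list(), seed = 1), "non-empty")
})
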