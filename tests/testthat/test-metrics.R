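test_that("torso segmentation recovers the body ellipse and excludes air", {
  ph <- small_phantom()
  body <- attr(ph, "body")
  torso <- segment_torso(ph)
  expect_identical(torso$role, "torso")
  expect_equal(sum(torso$pixels), sum(body), tolerance = 0.05)
  # zero false positives in background air
  expect_false(any(torso$pixels & ph$pixels == -1000))
  # idempotence: re-segmenting an image filled from the mask reproduces it
  filled <- matrix(-1000, 96, 96)
  filled[torso$pixels] <- 45
  torso2 <- segment_torso(ct_image(filled, 1))
  expect_identical(torso2$pixels, torso$pixels)
})

test_that("segmentation of pure air fails with a segmentation error", {
  air <- ct_image(matrix(-1000, 64, 64), 1)
  expect_error(segment_torso(air), class = "ctaudit_error_segmentation")
})

test_that("RSI reproduces exact ratios and clips above one", {
  set.seed(3)
  n_hat <- matrix(rnorm(400, sd = 10), 20, 20)
  mask <- region_mask(matrix(runif(400) < 0.6, 20, 20), "torso")
  same <- compute_rsi(n_hat, n_hat, mask)
  expect_identical(same$rsi, 1)
  expect_false(same$clipped)
  expect_identical(compute_rsi(n_hat * 0, n_hat, mask)$rsi, 0)
  half <- compute_rsi(n_hat * 0.5, n_hat, mask)
  expect_equal(half$rsi, 0.5, tolerance = 1e-12)
  over <- compute_rsi(n_hat * 2, n_hat, mask)
  expect_identical(over$rsi, 1)
  expect_true(over$clipped)
})

test_that("RSI equals a brute-force per-pixel loop and is scale invariant", {
  set.seed(11)
  for (i in 1:25) {
    nr <- sample(8:24, 1); nc <- sample(8:24, 1)
    s_hat <- matrix(rnorm(nr * nc), nr, nc)
    n_hat <- matrix(rnorm(nr * nc) + 0.5, nr, nc)
    mask <- matrix(runif(nr * nc) < 0.5, nr, nc)
    if (!any(mask)) mask[1, 1] <- TRUE
    res <- compute_rsi(s_hat, n_hat, region_mask(mask, "circle_set"))
    num <- 0; den <- 0; cnt <- 0L
    for (r in seq_len(nr)) for (cc in seq_len(nc)) if (mask[r, cc]) {
      num <- num + abs(s_hat[r, cc]); den <- den + abs(n_hat[r, cc])
      cnt <- cnt + 1L
    }
    expect_equal(res$rsi, min(1, (num / cnt) / (den / cnt)),
                 tolerance = 1e-12)
    expect_identical(res$mask_pixels, cnt)
    scaled <- compute_rsi(s_hat * 3.7, n_hat * 3.7,
                          region_mask(mask, "circle_set"))
    expect_equal(scaled$rsi, res$rsi, tolerance = 1e-12)
  }
})

test_that("RSI grows with the embedded structure magnitude", {
  set.seed(4)
  n <- matrix(rnorm(900, sd = 10), 30, 30)
  s <- matrix(rnorm(900, sd = 5), 30, 30)
  mask <- region_mask(matrix(TRUE, 30, 30), "torso")
  rsis <- vapply(seq(0, 2, by = 0.25), function(beta)
    compute_rsi(beta * s, n + beta * s, mask)$rsi, 0)
  expect_true(all(diff(rsis) >= -1e-12))
})

test_that("degenerate RSI inputs raise classed errors", {
  m <- matrix(1, 4, 4)
  expect_error(compute_rsi(m, m, region_mask(matrix(FALSE, 4, 4), "torso")),
               class = "ctaudit_error_empty_mask")
  expect_error(compute_rsi(m, m * 0, region_mask(matrix(TRUE, 4, 4), "torso")),
               class = "ctaudit_error_zero_denominator")
  expect_error(compute_rsi(m, matrix(1, 5, 5),
                           region_mask(matrix(TRUE, 4, 4), "torso")),
               "dimensions")
})

test_that("heatmaps overlay colour only where structure exceeds the floor", {
  base <- matrix(seq(-200, 300, length.out = 48 * 48), 48, 48)
  zero <- make_heatmap(matrix(0, 48, 48), base)
  gray <- (pmin(pmax(base, -160), 240) + 160) / 400
  expect_identical(dim(zero), c(48L, 48L, 3L))
  for (ch in 1:3) expect_equal(zero[, , ch], gray, tolerance = 1e-12)
  s_hat <- matrix(0, 48, 48)
  disc <- ctaudit:::disc_mask(c(48, 48), c(24, 24), 6)
  s_hat[disc] <- 30
  hm <- make_heatmap(s_hat, base)
  differs <- apply(abs(hm - zero) > 1e-12, c(1, 2), any)
  expect_true(all(differs[disc]))
  expect_false(any(differs[!disc]))
  # below the alpha floor nothing is drawn
  s_low <- matrix(1, 48, 48)
  expect_equal(make_heatmap(s_low, base), zero, tolerance = 1e-12)
})

test_that("display-window normalisation maps the abdominal window to 8 bits", {
  img <- matrix(c(-160, 240, 40, -1000, 3000, 0), 2, 3)
  out <- normalize_for_iqa(img)
  expect_identical(out[1, 1], 0L)
  expect_identical(out[2, 1], 255L)
  expect_identical(out[1, 2], 128L)   # window centre rounds half-up
  expect_identical(out[2, 2], 0L)     # clipped below
  expect_identical(out[1, 3], 255L)   # clipped above
  expect_identical(out[2, 3], 102L)
  expect_true(is.integer(out))
})

test_that("SSIM is 1 at identity, symmetric, and negative for inverted images", {
  set.seed(8)
  a <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  b <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_equal(compute_ssim(a, a), 1, tolerance = 1e-12)
  expect_equal(compute_ssim(a, b), compute_ssim(b, a), tolerance = 1e-12)
  expect_lt(compute_ssim(a, 255 - a), 0)
  expect_error(compute_ssim(a, matrix(0, 8, 8)), "dimensions")
})

test_that("SSIM matches scikit-image to 1e-6", {
  set.seed(19)
  dir <- tempfile(); dir.create(dir)
  ours <- numeric(3)
  for (i in 1:3) {
    a <- matrix(sample(0:255, 60 * 72, TRUE), 60, 72)
    noise <- matrix(round(rnorm(60 * 72, sd = 15 * i)), 60, 72)
    b <- matrix(pmin(pmax(a + noise, 0), 255), 60, 72)
    write.table(a, file.path(dir, sprintf("a%d.csv", i)), sep = ",",
                row.names = FALSE, col.names = FALSE)
    write.table(b, file.path(dir, sprintf("b%d.csv", i)), sep = ",",
                row.names = FALSE, col.names = FALSE)
    ours[i] <- compute_ssim(a, b)
  }
  out <- run_python(sprintf("
import numpy as np
from skimage.metrics import structural_similarity
for i in (1, 2, 3):
    a = np.loadtxt(r'%s/a%%d.csv' %% i, delimiter=',')
    b = np.loadtxt(r'%s/b%%d.csv' %% i, delimiter=',')
    print('%%.12f' %% structural_similarity(a, b, gaussian_weights=True,
          sigma=1.5, use_sample_covariance=False, data_range=255))
", dir, dir))
  theirs <- as.numeric(out)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("rank-sum test matches enumeration and reference implementations", {
  # all 20 assignments of {1..6} into two groups of three: only the two
  # extreme orderings reach |U - 4.5| >= 4.5, so two-sided p = 2/20 = 0.1
  p <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  vals <- combn(6, 3)
  u_obs <- 0  # U statistic of group {1,2,3}
  u_all <- apply(vals, 2, function(g) sum(outer(g, setdiff(1:6, g), ">")))
  p_enum <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5))
  expect_equal(as.numeric(p), p_enum, tolerance = 1e-12)
  expect_equal(p_enum, 0.1, tolerance = 1e-12)

  expect_identical(as.numeric(rank_sum_test(c(1, 2, 3), c(1, 2, 3))), 1)
  expect_identical(as.numeric(rank_sum_test(c(2, 2), c(2, 2, 2))), 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")

  set.seed(23)
  a <- round(rnorm(7), 6); b <- round(rnorm(6) + 0.8, 6)
  dir <- tempfile(); dir.create(dir)
  writeLines(c(paste(a, collapse = ","), paste(b, collapse = ",")),
             file.path(dir, "groups.csv"))
  out <- run_python(sprintf("
import numpy as np
from scipy.stats import mannwhitneyu
lines = open(r'%s/groups.csv').read().splitlines()
a = [float(x) for x in lines[0].split(',')]
b = [float(x) for x in lines[1].split(',')]
print('%%.12f' %% mannwhitneyu(a, b, alternative='two-sided',
                               method='exact').pvalue)
", dir))
  expect_equal(as.numeric(rank_sum_test(a, b)), as.numeric(out),
               tolerance = 1e-9)
})
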