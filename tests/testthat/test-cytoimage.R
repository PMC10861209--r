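stripes <- function(size = 64, period = 8, angle = 0) {
  xg <- matrix(rep(seq_len(size), each = size), size)
  yg <- matrix(rep(seq_len(size), times = size), size)
  # coordinate along the normal of the stripe direction
  s <- -sin(angle) * xg + cos(angle) * yg
  100 + 50 * sin(2 * pi * s / period)
}

axial_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

test_that("masked mean intensity is background subtracted and normalized", {
  img <- matrix(100, 40, 40)
  mask <- matrix(0, 40, 40); mask[10:30, 10:30] <- 1
  r <- quantify_intensity(img, mask, background = 20)
  expect_equal(r$mean, 80)
  # group normalization: reference {80, 120} -> {0.8, 1.2}
  refs <- c(80, 120)
  norm <- vapply(refs, function(v)
    quantify_intensity(matrix(v + 20, 40, 40), mask, background = 20,
                       reference = refs)$normalized, numeric(1))
  expect_equal(norm, c(0.8, 1.2))
  expect_equal(mean(norm), 1)
  # degenerate: background above the masked mean floors at 0
  expect_warning(r0 <- quantify_intensity(img, mask, background = 150),
                 "floored")
  expect_equal(r0$mean, 0)
  expect_error(quantify_intensity(img, 0 * mask), "empty")
})

test_that("structure tensor recovers stripe orientation and its rotation", {
  f0 <- orientation_field(stripes(angle = 0), tensor_sigma = 3)
  ok <- f0$valid & f0$coherence > 0.9
  expect_gt(mean(ok), 0.25)
  expect_lt(stats::median(axial_diff(f0$theta[ok], 0)), 0.05)

  th <- 30 * pi / 180
  f30 <- orientation_field(stripes(size = 96, angle = th), tensor_sigma = 3)
  ok <- f30$valid & f30$coherence > 0.9
  expect_lt(stats::median(axial_diff(f30$theta[ok], th)), 0.05)
})

test_that("white noise yields low coherence", {
  set.seed(17)
  img <- matrix(rnorm(96^2), 96)
  f <- orientation_field(img)
  expect_lt(mean(f$coherence[f$valid]), 0.2)
})

test_that("deviation is 0 for parallel fibers, ~1 for isotropic tiles", {
  f <- orientation_field(stripes(size = 96), tensor_sigma = 3)
  d <- actin_deviation(f, tile = 16)
  expect_lt(d$mean, 0.05)

  # Monte-Carlo circular-statistics oracle: uniform axial angles in a
  # tile of m pixels give E[1 - R] = 1 - sqrt(pi)/2 * m^(-1/2) + O(1/m)
  m <- 16 * 16
  set.seed(9)
  oracle <- mean(replicate(400, 1 - Mod(mean(exp(2i * runif(m, 0, pi))))))
  fake <- structure(list(
    theta = matrix(runif(96^2, 0, pi), 96),
    coherence = matrix(1, 96, 96),
    energy = matrix(1, 96, 96),
    valid = matrix(TRUE, 96, 96)), class = "orientation_field")
  d1 <- actin_deviation(fake, tile = 16)
  expect_equal(d1$mean, oracle, tolerance = 0.02)
  expect_gt(d1$mean, 0.85)
})

test_that("deviation is rotation and intensity invariant", {
  p <- tiny_profile("old")
  cfg <- tiny_config()
  set.seed(23)
  ren <- render_actin_image(p, cfg, size = 128)
  dev0 <- actin_deviation(orientation_field(ren$image))$mean
  rot90 <- t(ren$image)[ncol(ren$image):1, ]
  dev90 <- actin_deviation(orientation_field(rot90))$mean
  expect_lt(abs(dev90 - dev0) / dev0, 0.02)
  dev_scaled <- actin_deviation(orientation_field(2 * ren$image))$mean
  expect_lt(abs(dev_scaled - dev0) / dev0, 1e-6)
})

test_that("rendered masked mean scales with the intensity parameter", {
  p <- tiny_profile(); p$actin_intensity_sd <- 0
  cfg <- tiny_config(); cfg$image_noise_sd <- 0
  set.seed(31)
  r1 <- render_actin_image(p, cfg, size = 128, background = 0)
  p2 <- p; p2$actin_intensity_mean <- 2 * p$actin_intensity_mean
  set.seed(31)
  r2 <- render_actin_image(p2, cfg, size = 128, background = 0)
  m1 <- mean(r1$image[r1$mask > 0]); m2 <- mean(r2$image[r2$mask > 0])
  expect_equal(m2 / m1, 2, tolerance = 1e-6)
  expect_equal(m1, p$actin_intensity_mean, tolerance = 1e-6)
})

test_that("deviation decreases with orientation concentration kappa", {
  cfg <- tiny_config()
  devs <- vapply(c(0.5, 2, 8), function(kap) {
    p <- tiny_profile(); p$orientation_kappa <- kap
    mean(vapply(1:10, function(s) {
      set.seed(100 * kap + s)
      ren <- render_actin_image(p, cfg, size = 128)
      actin_deviation(orientation_field(ren$image))$mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
})

test_that("intensity ratio between cohorts matches the generator scales", {
  cfg <- tiny_config()
  run <- function(p, seeds) vapply(seeds, function(s) {
    set.seed(s)
    ren <- render_actin_image(p, cfg, size = 128)
    quantify_intensity(ren$image, ren$mask)$mean
  }, numeric(1))
  p1 <- tiny_profile(); p1$actin_intensity_sd <- 5
  p2 <- p1; p2$actin_intensity_mean <- p1$actin_intensity_mean / 2
  v1 <- run(p1, 1:8); v2 <- run(p2, 101:108)
  expect_equal(mean(v1) / mean(v2), 2, tolerance = 0.1)
})
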