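dt <- 0.5

test_that("velocity is the central difference of |u|", {
  t <- seq(0, 54.5, by = dt)
  expect_equal(pillar_velocity(3 * t, dt)[2:109], rep(3, 108))
  expect_equal(pillar_velocity(rep(2, 110), dt), rep(0, 110))
  # analytic derivative of a slow sine; the central difference attenuates
  # by sinc(2 pi f dt), ~2% at a tenth of the Nyquist frequency
  f <- 0.1                                   # cycles/min
  x <- sin(2 * pi * f * t)
  v <- pillar_velocity(x + 2, dt)            # offset keeps |u| = x + 2
  v_true <- 2 * pi * f * cos(2 * pi * f * t)
  i <- 10:100
  expect_lt(max(abs(v[i] - v_true[i])) / max(abs(v_true)), 0.02)
  expect_error(pillar_velocity(1:10, dt), "16")
})

test_that("a single tone yields one dominant IMF", {
  t <- seq(0, 54.5, by = dt)
  x <- sin(2 * pi * 0.3 * t)                 # 5 mHz
  dec <- emd_decompose(x)
  i <- 12:98                                 # away from 10% edges
  expect_gt(stats::cor(dec$imfs[i, 1], x[i]), 0.99)
})

test_that("two well-separated tones map to IMF1 and IMF2", {
  t <- seq(0, 99.5, by = dt)
  hi <- sin(2 * pi * 0.30 * t)               # 5 mHz
  lo <- sin(2 * pi * 0.06 * t + 1)           # 1 mHz
  dec <- emd_decompose(hi + lo)
  expect_gte(dec$n_imfs, 2)
  i <- 21:180
  expect_gt(stats::cor(dec$imfs[i, 1], hi[i]), 0.95)
  expect_gt(stats::cor(dec$imfs[i, 2], lo[i]), 0.95)
})

test_that("EMD is complete and IMFs satisfy the mode conditions", {
  count_crossings <- function(z) sum(abs(diff(sign(z))) > 0)
  count_extrema <- function(z) sum(diff(sign(diff(z))) != 0)
  for (s in 1:10) {
    set.seed(s)
    x <- as.numeric(stats::filter(rnorm(150), rep(1 / 3, 3), sides = 2))
    x[is.na(x)] <- 0
    dec <- emd_decompose(x)
    rec <- rowSums(cbind(dec$imfs, dec$residue))
    expect_lt(max(abs(rec - x)) / max(abs(x)), 1e-8)
    for (m in seq_len(dec$n_imfs))
      expect_lte(abs(count_crossings(dec$imfs[, m]) -
                       count_extrema(dec$imfs[, m])), 1)
  }
})

test_that("monotone input returns zero IMFs with the input as residue", {
  dec <- emd_decompose(seq(0, 1, length.out = 50))
  expect_equal(dec$n_imfs, 0L)
  expect_equal(dec$residue, seq(0, 1, length.out = 50))
})

test_that("orthogonality index is small for band-limited input", {
  set.seed(40)
  t <- seq(0, 99.5, by = dt)
  x <- sin(2 * pi * 0.3 * t) + 0.7 * sin(2 * pi * 0.06 * t + 0.5)
  expect_lt(orthogonality_index(emd_decompose(x)), 0.1)
})

test_that("Hilbert spectrum of a tone recovers amplitude and frequency", {
  t <- seq(0, 54.5, by = dt)
  x <- sin(2 * pi * 0.18 * t)                # 3 mHz, unit amplitude
  sp <- hilbert_instantaneous(x, dt, imf_index = 1L)
  i <- sp$interior
  expect_equal(stats::median(sp$amplitude[i]), 1, tolerance = 0.02)
  expect_equal(stats::median(sp$frequency_mHz[i], na.rm = TRUE), 3,
               tolerance = 0.02)
  # linearity: doubling the input doubles A, leaves F unchanged
  sp2 <- hilbert_instantaneous(2 * x, dt, imf_index = 1L)
  expect_equal(sp2$amplitude, 2 * sp$amplitude, tolerance = 1e-9)
  expect_equal(sp2$frequency_mHz, sp$frequency_mHz, tolerance = 1e-9)
})

test_that("a linear chirp is tracked within 5% in the interior", {
  t <- seq(0, 109.5, by = dt)
  Tn <- max(t)
  f0 <- 0.06; f1 <- 0.30                     # 1 -> 5 mHz in cycles/min
  phase <- 2 * pi * (f0 * t + (f1 - f0) * t^2 / (2 * Tn))
  sp <- hilbert_instantaneous(sin(phase), dt, imf_index = 1L)
  f_true <- (f0 + (f1 - f0) * t / Tn) / 0.06
  i <- which(sp$interior & !is.na(sp$frequency_mHz))
  expect_lt(stats::median(abs(sp$frequency_mHz[i] - f_true[i]) /
                            f_true[i]), 0.05)
})

test_that("requesting an absent IMF names the available modes", {
  dec <- emd_decompose(sin(seq(0, 20, length.out = 60)))
  expect_error(hilbert_instantaneous(dec, dt, imf_index = 5L),
               "available|has")
})

test_that("recovered IMF2 frequency rises with the generator band center", {
  # single-pillar velocity built like the generator: slow band + fast
  # flicker filling IMF1
  n <- 110
  recovered <- vapply(c(2, 3, 4), function(fc_mHz) {
    fs <- numeric(8)
    for (s in 1:8) {
      set.seed(1000 * fc_mHz + s)
      fc <- fc_mHz * 0.06; ff <- 14 * 0.06
      d <- band_limited_noise(n, dt, fc, 0.4 * fc) *
        0.12 / (sqrt(pi / 2) * 2 * pi * fc) +
        band_limited_noise(n, dt, ff, 0.4 * ff) *
          0.4 / (sqrt(pi / 2) * 2 * pi * ff)
      v <- pillar_velocity(d + rnorm(n, 0, 0.004) + 1, dt)
      sp <- hilbert_instantaneous(emd_decompose(v), dt, 2L)
      fs[s] <- mean(sp$frequency_mHz[sp$interior], na.rm = TRUE)
    }
    mean(fs)
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
})

test_that("identical cells give zero SEM in the cohort spectrum", {
  p <- tiny_profile()
  set.seed(33)
  sim <- simulate_cell_force(p, tiny_lattice(p), tiny_config())
  sp <- cell_spectrum(force_maps_from_sim(sim), max_pillars = 6)
  co <- cohort_spectrum(list(sp, sp, sp))
  expect_equal(max(co$A_sem), 0)
  expect_equal(co$A_mean, sp$A_t)
})
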