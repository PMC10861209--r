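test_that("deflection to force is the linear spring law", {
  rest <- cbind(c(0, 4), c(0, 0))
  tab <- do.call(rbind, lapply(1:3, function(fr)
    data.frame(frame = fr, pillar_id = 1:2,
               x_um = c(0, 4.5), y_um = c(0, 0))))
  tr <- tracks_from_table(tab)
  fm <- deflection_to_force(tr, rest, k = 10, engaged = c(FALSE, TRUE))
  expect_equal(fm$Tx[1, 1], 0)
  expect_equal(fm$Tx[2, 1], 5)            # u = (0.5, 0), k = 10
  expect_equal(fm$Ty[2, 1], 0)
})

test_that("short gaps are interpolated, long gaps exclude the pillar", {
  rest <- cbind(c(0, 4, 8), c(0, 0, 0))
  tab <- expand.grid(frame = 1:8, pillar_id = 1:3)
  tab$x_um <- rest[tab$pillar_id, 1] + 0.1 * tab$frame
  tab$y_um <- 0
  drop2 <- with(tab, pillar_id == 2 & frame %in% 4:5)   # 2-frame gap
  drop3 <- with(tab, pillar_id == 3 & frame %in% 3:5)   # 3-frame gap
  tr <- tracks_from_table(tab[!(drop2 | drop3), ])
  fm <- deflection_to_force(tr, rest, k = 1, engaged = rep(TRUE, 3))
  expect_false(fm$excluded[2])
  expect_true(fm$excluded[3])
  expect_equal(fm$ux[2, 4], 0.4, tolerance = 1e-9)      # linear fill
})

test_that("active/quiescent split matches the scaled-MAD hand computation", {
  # engaged |T| = {2, 3, 4, 5, 100}: median 4, MAD 1 (raw), threshold
  # 4 + 3 * 1.4826 = 8.448 -> active = 100, quiescent = 14
  ux <- matrix(rep(c(2, 3, 4, 5, 100), 8), 5)
  uy <- matrix(0, 5, 8)
  fm <- fake_maps(ux, uy, times = seq(0, 3.5, by = 0.5))
  met <- force_metrics(fm, stim_time = 1)
  expect_equal(met$trace$active_nN[1], 100)
  expect_equal(met$trace$quiescent_nN[1], 14)
  expect_equal(met$trace$total_nN[1], 114)
})

test_that("constant trace reports peak 1 and missing time-to-peak", {
  ux <- matrix(1, 4, 10)
  fm <- fake_maps(ux, 0 * ux, times = seq(0, 4.5, by = 0.5))
  met <- force_metrics(fm, stim_time = 1)
  expect_equal(met$peak_normalized, 1)
  expect_true(is.na(met$time_to_peak_min))
})

test_that("active + quiescent equals total in every frame", {
  set.seed(21)
  ux <- matrix(abs(rnorm(30 * 12, 1, 0.6)), 30)
  uy <- matrix(abs(rnorm(30 * 12, 0.3, 0.2)), 30)
  fm <- fake_maps(ux, uy, times = seq(0, 5.5, by = 0.5), k = 2)
  met <- force_metrics(fm, stim_time = 1)
  expect_equal(met$trace$active_nN + met$trace$quiescent_nN,
               met$trace$total_nN)
})

test_that("normalized metrics are invariant to the spring constant", {
  p <- tiny_profile()
  set.seed(14)
  sim <- simulate_cell_force(p, tiny_lattice(p), tiny_config())
  fm1 <- force_maps_from_sim(sim)
  fm2 <- fm1
  fm2$k <- 5 * fm1$k; fm2$Tx <- 5 * fm1$Tx; fm2$Ty <- 5 * fm1$Ty
  m1 <- force_metrics(fm1, 2.5); m2 <- force_metrics(fm2, 2.5)
  expect_equal(m1$trace$normalized, m2$trace$normalized)
  expect_equal(m1$peak_normalized, m2$peak_normalized)
  expect_equal(m1$time_to_peak_min, m2$time_to_peak_min)
})

test_that("reconstruction from truth tracks equals generated forces", {
  p <- tiny_profile()
  set.seed(15)
  sim <- simulate_cell_force(p, tiny_lattice(p), tiny_config())
  np <- nrow(sim$lattice$rest_positions)
  tab <- do.call(rbind, lapply(seq_along(sim$times), function(fr)
    data.frame(frame = fr, pillar_id = seq_len(np),
               x_um = sim$lattice$rest_positions[, 1] +
                 sim$deflections[, fr, 1],
               y_um = sim$lattice$rest_positions[, 2] +
                 sim$deflections[, fr, 2])))
  fm <- deflection_to_force(tracks_from_table(tab),
                            sim$lattice$rest_positions,
                            k = sim$lattice$k, engaged = sim$engaged)
  Tx_true <- sim$lattice$k * sim$deflections[, , 1]
  rel <- abs(fm$Tx - Tx_true) / max(abs(Tx_true))
  expect_lt(max(rel), 1e-3)            # oracle equivalence, < 0.1%
})

test_that("image-route total force stays within 5% of the programmed trace", {
  # measurement fidelity: default imaging noise, oscillation off so the
  # programmed trace is the exact truth frame by frame
  p <- tiny_profile(area = 450)
  p$osc_amplitude <- 0; p$fast_amplitude <- 0
  cfg <- tiny_config(seed = 31)
  set.seed(cfg$seed)
  sim <- simulate_cell_force(p, tiny_lattice(p), cfg)
  fm <- reconstruct_from_images(sim, cfg)
  met <- force_metrics(fm, config_stim_time(cfg))
  expect_true(all(abs(met$trace$total_nN - sim$force_true) /
                    sim$force_true < 0.05))
})

test_that("with oscillations the time-mean total force still tracks truth", {
  p <- tiny_profile(area = 450)
  cfg <- tiny_config(seed = 37)
  set.seed(cfg$seed)
  sim <- simulate_cell_force(p, tiny_lattice(p), cfg)
  fm <- reconstruct_from_images(sim, cfg)
  met <- force_metrics(fm, config_stim_time(cfg))
  expect_equal(mean(met$trace$total_nN) / mean(sim$force_true), 1,
               tolerance = 0.03)
})

test_that("strain energy matches hand summation and scales quadratically", {
  expect_equal(strain_energy(rbind(c(3, 0), c(0, 4)),
                             rbind(c(0.3, 0), c(0, 0.4))), 1.25)
  expect_equal(strain_energy(matrix(0, 3, 2), matrix(0, 3, 2)), 0)
  set.seed(5)
  ux <- matrix(rnorm(20), 10); uy <- matrix(rnorm(20), 10)
  fm1 <- fake_maps(ux, uy, times = c(0, 0.5), k = 3)
  fm2 <- fake_maps(2 * ux, 2 * uy, times = c(0, 0.5), k = 3)
  e1 <- strain_energy(fm1); e2 <- strain_energy(fm2)
  expect_equal(e2, 4 * e1)
  # cross-check of the two closed forms: E = k/2 * sum |u|^2
  expect_equal(e1, 0.5 * 3 * colSums(ux^2 + uy^2))
  expect_true(all(e1 >= 0))
})
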