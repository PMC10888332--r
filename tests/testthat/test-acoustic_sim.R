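test_that("transmit delay law matches its analytic cases", {
  pr <- probe_config()
  expect_equal(transmit_delays(pr, 0), rep(0, 128))
  # element index n = 64, pitch 0.3 mm, 10 degrees, 1540 m/s -> 2.165 us
  d10 <- transmit_delays(pr, 10)
  expect_equal(d10[65], 64 * 0.3e-3 * sin(10 * pi / 180) / 1540)
  expect_equal(d10[65] * 1e6, 2.165, tolerance = 1e-4)
  # odd symmetry in the steering angle
  expect_equal(transmit_delays(pr, -7.3), -transmit_delays(pr, 7.3))
  expect_error(transmit_delays(pr, 95))
})

test_that("scatterer fields follow the concentration map", {
  g <- small_grid()
  expect_equal(nrow(generate_scatterers(uniform_phantom(esc = 0, grid = g),
                                        1L)$positions_mm), 0L)
  ph <- uniform_phantom(esc = 2, grid = g)
  sf <- generate_scatterers(ph, 5L)
  expect_identical(sf$positions_mm, generate_scatterers(ph, 5L)$positions_mm)
  # Poisson expectation: esc * area / lambda^2
  expected <- 2 * prod(g$roi_mm) / 0.308^2
  expect_lt(abs(nrow(sf$positions_mm) - expected), 3 * sqrt(expected))
  expect_true(all(abs(sf$positions_mm[, 1]) <= g$roi_mm[["width"]] / 2))
  expect_true(all(sf$positions_mm[, 2] >= 0 &
                    sf$positions_mm[, 2] <= g$roi_mm[["depth"]]))
})

single_scatterer_rf <- function(sos, seed = 1L, depth_mm = 16,
                                probe = small_probe()) {
  ph <- uniform_phantom(sos = sos, esc = 0, grid = small_grid())
  sc <- structure(list(positions_mm = cbind(0, depth_mm), amplitudes = 1,
                       esd_um = 85, pixel = 1L, seed = seed),
                  class = "scatterer_field")
  simulate_rf(ph, probe, seed, snr_db = 80, scatterers = sc)
}

test_that("echoes arrive at the two-way time of flight", {
  pr <- small_probe()
  rf <- single_scatterer_rf(1540)
  e_mid <- which.min(abs(pr$elem_x_mm))
  env <- Mod(quantus:::analytic_signal(rf$data[, e_mid, 2, drop = FALSE]))
  t_peak <- which.max(env) / pr$sampling_rate_hz
  expect_lt(abs(t_peak - 2 * 0.016 / 1540), 2.5 / pr$sampling_rate_hz)

  # uniform SoS change rescales the arrival time by the speed ratio,
  # within one sample period
  rf2 <- single_scatterer_rf(1580)
  env2 <- Mod(quantus:::analytic_signal(rf2$data[, e_mid, 2, drop = FALSE]))
  t2 <- which.max(env2) / pr$sampling_rate_hz
  expect_lt(abs(t2 - t_peak * 1540 / 1580), 1 / pr$sampling_rate_hz)
})

test_that("simulation is pure and validates geometry", {
  ph <- uniform_phantom(esc = 1, grid = small_grid())
  pr <- small_probe()
  rf1 <- simulate_rf(ph, pr, 3L)
  rf2 <- simulate_rf(ph, pr, 3L)
  expect_identical(rf1$data, rf2$data)
  expect_equal(dim(rf1$data), c(2300L, 64L, 3L))
  # empty scatterer field -> pure noise at the configured level
  ph0 <- uniform_phantom(esc = 0, grid = small_grid())
  rf0 <- simulate_rf(ph0, pr, 3L, snr_db = 30)
  expect_equal(sd(rf0$data), 10^(-30 / 20), tolerance = 0.01)
  # probe wider than the phantom is a geometry mismatch
  wide <- probe_config(n_elements = 128L, pitch_mm = 0.3)
  expect_error(simulate_rf(ph, wide, 1L), "geometry mismatch")
})

test_that("attenuation strictly dims deep echoes, monotonically in AC", {
  pr <- small_probe()
  g <- small_grid()
  amp_at <- function(ac) {
    ph <- uniform_phantom(ac = ac, esc = 2, grid = g)
    rf <- simulate_rf(ph, pr, 17L, snr_db = 60)
    i_deep <- round(2 * 0.018 / 1540 * pr$sampling_rate_hz) + seq_len(150)
    i_shal <- round(2 * 0.006 / 1540 * pr$sampling_rate_hz) + seq_len(150)
    c(deep = sqrt(mean(rf$data[i_deep, , 2]^2)),
      shallow = sqrt(mean(rf$data[i_shal, , 2]^2)))
  }
  a1 <- amp_at(0.4); a2 <- amp_at(0.8); a3 <- amp_at(1.1)
  expect_gt(a1[["deep"]], a2[["deep"]])
  expect_gt(a2[["deep"]], a3[["deep"]])
  # the deep/shallow ratio falls faster than the shallow amplitude
  expect_gt(a1[["deep"]] / a1[["shallow"]], a2[["deep"]] / a2[["shallow"]])
})

test_that("beamforming focuses a point scatterer at its true position", {
  rf <- single_scatterer_rf(1540)
  bf <- beamform_das(rf, 1540, x_mm = seq(-5, 5, 0.2),
                     z_mm = seq(11, 21, 0.2))
  pk <- which(bf$envelope == max(bf$envelope), arr.ind = TRUE)
  expect_lte(abs(bf$z_mm[pk[1]] - 16), 0.2)
  expect_lte(abs(bf$x_mm[pk[2]] - 0), 0.2)

  # zero input -> zero image
  rf0 <- rf; rf0$data[] <- 0
  expect_equal(max(beamform_das(rf0, 1540, x_mm = seq(-2, 2, 0.5),
                                z_mm = seq(10, 20, 0.5))$envelope), 0)
})

test_that("angular compounding improves the peak-to-sidelobe ratio", {
  pslr <- function(angles) {
    rf <- single_scatterer_rf(1540, probe = small_probe(angles))
    bf <- beamform_das(rf, 1540, x_mm = seq(-6, 6, 0.1),
                       z_mm = seq(15.2, 16.8, 0.1))
    env <- bf$envelope / max(bf$envelope)
    pk <- which(env == 1, arr.ind = TRUE)
    # sidelobe: maximum outside a 1 mm guard around the peak
    guard <- abs(col(env) - pk[2]) <= 10 & abs(row(env) - pk[1]) <= 10
    1 / max(env[!guard])
  }
  expect_gte(pslr(c(-8, 0, 8)) + 1e-9, pslr(0))
})
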