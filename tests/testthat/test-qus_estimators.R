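# reduced-geometry estimator checks; full parameter-recovery statistics
# live in test-acceptance.R

test_that("analysis windows and reference validation behave", {
  expect_error(analysis_windows(overlap = 1), "overlap")
  ref <- small_reference()
  rf_other <- structure(list(data = array(0, c(10, 4, 1)),
                             probe = probe_config(n_elements = 4,
                                                  n_samples = 10)),
                        class = "plane_wave_rf")
  expect_error(estimate_ac(rf_other, small_windows(), ref),
               "reference probe")
})

test_that("spectral estimators are self-consistent on the reference", {
  ref <- small_reference()
  rf <- ref$frames[[1]]
  w <- small_windows()
  ac <- estimate_ac(rf, w, ref)
  expect_s3_class(ac, "qus_image")
  expect_equal(ac$units, "dB/cm/MHz")
  expect_lt(abs(median(ac$values) - ref$ac), 0.1)
  ee <- estimate_esd_esc(rf, w, ref, ac_image = ac)
  expect_lt(abs(median(ee$ESD$values) - ref$esd), 13)
  expect_lt(abs(median(ee$ESC$values) - ref$esc), 1)
})

test_that("attenuation layering is resolved in depth", {
  g <- small_grid()
  ph <- uniform_phantom(grid = g)
  ph$ac_map[g$z_mm < 11, ] <- 0.4
  ph$ac_map[g$z_mm >= 11, ] <- 0.9
  rf <- simulate_rf(ph, small_probe(), 21L)
  ac <- estimate_ac(rf, small_windows(), small_reference())
  shallow <- ac$values[ac$z_mm < 9, ]
  deep <- ac$values[ac$z_mm > 14, ]
  expect_gt(mean(deep), mean(shallow))
  expect_lt(mean(shallow), 0.65)
  expect_gt(mean(deep), 0.6)
})

test_that("scatterer size and concentration separate", {
  ref <- small_reference()
  w <- small_windows()
  est <- function(esd, esc, seed) {
    ph <- uniform_phantom(esd = esd, esc = esc, grid = small_grid())
    rf <- simulate_rf(ph, small_probe(), seed)
    ee <- estimate_esd_esc(rf, w, ref)
    c(esd = median(ee$ESD$values), esc = median(ee$ESC$values))
  }
  lo <- est(75, 2, 31L); hi <- est(100, 2, 32L)
  expect_lt(lo[["esd"]], hi[["esd"]])          # size ordering preserved
  e1 <- est(90, 1.5, 33L); e2 <- est(90, 3, 34L)
  expect_gt(e2[["esc"]], e1[["esc"]])          # concentration responds
  expect_lt(abs(e2[["esd"]] - e1[["esd"]]), 15)  # size stays put
})

test_that("speed of sound is recovered by coherence maximization", {
  ph <- uniform_phantom(sos = 1560, grid = small_grid())
  rf <- simulate_rf(ph, small_probe(), 41L)
  sos <- estimate_sos(rf, seq(1500, 1620, by = 4),
                      patch_x_mm = c(-8, 8), patch_z_mm = c(6, 20))
  expect_equal(sos$values[1, 1], 1560, tolerance = 6)
  expect_false(attr(sos, "clamped"))

  # candidates excluding the truth clamp at the boundary with a warning
  expect_warning(
    clamped <- estimate_sos(rf, seq(1480, 1520, by = 4),
                            patch_x_mm = c(-8, 8), patch_z_mm = c(6, 20)),
    "clamped")
  expect_equal(clamped$values[1, 1], 1520)
  expect_true(attr(clamped, "clamped"))

  one_angle <- simulate_rf(ph, small_probe(angles = 0), 41L)
  expect_error(estimate_sos(one_angle), "multiple steering angles")
})

test_that("estimates are invariant to global RF amplitude scaling", {
  ref <- small_reference()
  w <- small_windows()
  ph <- uniform_phantom(ac = 0.7, sos = 1550, esd = 92, esc = 2.5,
                        grid = small_grid())
  rf <- simulate_rf(ph, small_probe(), 51L)
  rf_scaled <- rf
  rf_scaled$data <- rf$data * 3.7
  ac1 <- estimate_ac(rf, w, ref); ac2 <- estimate_ac(rf_scaled, w, ref)
  expect_equal(ac1$values, ac2$values, tolerance = 0.02)
  s1 <- estimate_sos(rf, seq(1510, 1590, 4), patch_x_mm = c(-8, 8),
                     patch_z_mm = c(6, 20))
  s2 <- estimate_sos(rf_scaled, seq(1510, 1590, 4), patch_x_mm = c(-8, 8),
                     patch_z_mm = c(6, 20))
  expect_equal(s1$values, s2$values, tolerance = 1e-6)
  e1 <- estimate_esd_esc(rf, w, ref, ac_image = ac1)
  e2 <- estimate_esd_esc(rf_scaled, w, ref, ac_image = ac2)
  expect_equal(e1$ESD$values, e2$ESD$values, tolerance = 1)
  # the envelope-moment concentration is a ratio statistic: scale-free
  expect_equal(e1$ESC$values, e2$ESC$values, tolerance = 0.05)
})

test_that("lesion measurements summarize maps over the lesion mask", {
  g <- small_grid()
  les <- lesion_spec("ellipse", c(0, 13), c(4, 3), class_label = "benign",
                     properties = list(ac = 0.5, sos = 1545, esd = 95,
                                       esc = 2))
  ph <- generate_phantom(layers = list(list(class = "gland",
                                            thickness_mm = Inf)),
                         lesion = les, rng_seed = 3L, grid = g)
  fake <- function(p, v) qus_image(matrix(v, 10, 11), p,
                                   seq(-10, 10, 2), seq(4, 22, 2))
  imgs <- list(AC = fake("AC", 0.5), SoS = fake("SoS", 1545),
               ESD = fake("ESD", 95), ESC = fake("ESC", 2))
  imgs$AC$values[imgs$AC$z_mm >= 9 & imgs$AC$z_mm <= 17, ] <- 0.9
  row <- lesion_measurement(imgs, ph, id = "x", label = "benign")
  expect_equal(row$ac, 0.9)                  # mask rows carry the contrast
  expect_equal(row$sos, 1545)
  expect_equal(row$label, "benign")
})
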