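test_that("quartile inversion reproduces published group parameters", {
  # AC benign: median 0.506, IQR 0.402-0.623
  f <- fit_distribution_from_quartiles(0.506, 0.402, 0.623, "log-normal")
  expect_equal(f$mu, log(0.506), tolerance = 1e-10)
  expect_equal(f$sigma, log(0.623 / 0.402) / (2 * qnorm(0.75)),
               tolerance = 1e-10)
  expect_equal(f$mu, -0.6812, tolerance = 1e-4)
  expect_equal(f$sigma, 0.3248, tolerance = 5e-4)
  # degenerate interquartile range: point mass
  expect_equal(fit_distribution_from_quartiles(1, 1, 1, "log-normal")$sigma, 0)
  expect_error(fit_distribution_from_quartiles(-1, -2, 1, "log-normal"),
               "positive")
  expect_error(fit_distribution_from_quartiles(1, 2, 1, "normal"), "q1")
})

test_that("fitted distributions round-trip their quartiles", {
  withr::with_seed(21, {
    f <- fit_distribution_from_quartiles(91.53, 86.46, 97.71, "log-normal")
    qs <- quantile(rlnorm(1e6, f$mu, f$sigma), c(0.25, 0.5, 0.75))
    expect_equal(unname(qs), c(86.46, 91.53, 97.71), tolerance = 0.01)
    g <- fit_distribution_from_quartiles(1542, 1525, 1558.5, "normal")
    qn <- quantile(rnorm(1e6, g$mean, g$sd), c(0.25, 0.5, 0.75))
    expect_equal(unname(qn), c(1525, 1542, 1558.5), tolerance = 0.01)
  })
})

test_that("sample_cohort emulates the clinical group structure", {
  co <- sample_cohort(seed = 4)
  expect_equal(nrow(co), 55L)                 # 32 benign + 23 malignant
  expect_equal(sum(co$label == "benign"), 32L)
  expect_equal(sum(co$label == "malignant"), 23L)
  expect_true(all(c("id", "ac", "sos", "esd", "esc", "label") %in%
                    names(co)))
  expect_true(all(co$ac > 0 & co$esd > 0 & co$esc > 0))
  # determinism and the empty edge case
  expect_identical(sample_cohort(seed = 4), co)
  expect_equal(nrow(sample_cohort(0, 0)), 0L)
})

test_that("large cohorts reproduce the published medians", {
  co <- sample_cohort(1e5, 1e5, seed = 8)
  s <- clinical_group_summaries()
  for (gr in c("benign", "malignant")) for (p in c("ac", "sos", "esd", "esc")) {
    med <- median(co[[p]][co$label == gr])
    pub <- s$median[s$group == gr & s$parameter == p]
    expect_equal(med, pub, tolerance = 0.01,
                 label = paste(gr, p, "median"))
  }
})

test_that("the packaged model separates synthetic groups as published", {
  co <- sample_cohort(1e4, 1e4, seed = 12)
  pr <- probability(log_odds(co))
  expect_gt(median(pr[co$label == "malignant"]),
            median(pr[co$label == "benign"]))

  # at the clinical 32/23 size, AC/SoS/ESD reject at alpha = .05 in most
  # seeds while ESC (overlapping groups) rejects in a minority
  rej <- sapply(1:20, function(s) {
    cs <- sample_cohort(seed = 100 + s)
    vapply(c("ac", "sos", "esd", "esc"), function(p)
      mann_whitney(cs[[p]][cs$label == "benign"],
                   cs[[p]][cs$label == "malignant"])$p < 0.05, logical(1))
  })
  frac <- rowMeans(rej)
  expect_gt(frac[["ac"]], 0.5)
  expect_gt(frac[["sos"]], 0.5)
  expect_gt(frac[["esd"]], 0.5)
  expect_lt(frac[["esc"]], 0.5)
})

test_that("the correlation hook induces rank correlation via the copula", {
  R <- diag(4); R[1, 2] <- R[2, 1] <- 0.8
  co <- sample_cohort(4000, 0, seed = 3, correlation = R)
  expect_gt(cor(co$ac, co$sos, method = "spearman"), 0.6)
  co0 <- sample_cohort(4000, 0, seed = 3)
  expect_lt(abs(cor(co0$ac, co0$sos, method = "spearman")), 0.08)
})
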