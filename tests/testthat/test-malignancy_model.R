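# Frozen oracle values for the nine packaged clinical lesions, computed
# by direct hand evaluation of the published log-odds formula before the
# model code was written.
table5_oracle <- data.frame(
  id = paste0("lesion", 1:9),
  log_odds = c(-4.195481, -3.9179363, -1.832243, -0.8234109,
               -2.887003, 1.60654956, -2.7558915, -4.4810073, -0.4283028),
  probability = c(0.014839953608, 0.019494491981, 0.137971284807,
                  0.305040100569, 0.052799803623, 0.832931786950,
                  0.059754781459, 0.011195250103, 0.394531679996))

test_that("packaged model reproduces the clinical log-odds and probabilities", {
  les <- clinical_lesions()
  expect_equal(nrow(les), 9L)
  lo <- log_odds(les)
  expect_equal(lo, table5_oracle$log_odds, tolerance = 1e-9)
  expect_equal(probability(lo), table5_oracle$probability, tolerance = 1e-9)
  # intercept-only evaluation
  zero <- data.frame(ac = 0, sos = 0, esd = 0, esc = 0)
  expect_equal(log_odds(zero), -31.7558)
  # the two biopsy-confirmed malignant lesions are ranked 1st and 3rd
  # among the nine by predicted probability
  p <- probability(lo)
  expect_true(which.max(p) == 6L)
  expect_true(all(rank(-p)[les$label == "malignant"] <= 3))
})

test_that("sigmoid conversion behaves as a probability", {
  expect_equal(probability(0), 0.5)
  x <- c(-30, -2.5, 0.1, 7, 30)
  expect_equal(probability(x) + probability(-x), rep(1, 5))
  expect_true(all(probability(x) > 0 & probability(x) < 1))
  cl <- classify_lesions(data.frame(ac = 0.8061, sos = 1590, esd = 89.88,
                                    esc = 1.976))
  expect_equal(cl$predicted, "malignant")
  expect_equal(cl$probability, 0.832931786950, tolerance = 1e-9)
})

test_that("odds-ratio table matches the published inference table", {
  m <- default_qus_model()
  tab <- odds_ratio_table(m)
  pub <- clinical_inference_table()
  i <- match(tab$parameter, pub$parameter)
  expect_equal(tab$odds_ratio, pub$odds_ratio[i], tolerance = 0.005)
  # definitional identities
  expect_equal(tab$odds_ratio, exp(tab$coef))
  expect_equal(odds_ratio_table(qus_logistic(0, 0, 0, 0, 0))$odds_ratio,
               rep(1, 4))
})

test_that("log_odds validates its inputs", {
  expect_error(log_odds(data.frame(ac = 0.5, sos = 1540, esd = 90)),
               "esc")
  expect_error(log_odds(data.frame(ac = NA, sos = 1540, esd = 90,
                                   esc = 2)), "non-finite")
})

test_that("fit_logistic recovers a known model and reports inference", {
  set.seed(11)
  n <- 4000
  truth <- qus_logistic(-20, 8, 0.012, -0.08, 0.1)
  co <- data.frame(ac = rlnorm(n, log(0.58), 0.25),
                   sos = rnorm(n, 1552, 25),
                   esd = rlnorm(n, log(88), 0.1),
                   esc = rlnorm(n, log(2.5), 0.3))
  p <- probability(log_odds(co, truth))
  co$label <- ifelse(runif(n) < p, "malignant", "benign")
  fit <- fit_logistic(co)
  expect_false(attr(fit, "separation"))
  # signs and rough magnitudes of all four coefficients
  cf <- fit$coefficients[c("ac", "sos", "esd", "esc")]
  expect_equal(unname(sign(cf)), c(1, 1, -1, 1))
  expect_equal(unname(cf[["ac"]]), 8, tolerance = 0.25)
  # inference identities
  inf <- fit$inference
  expect_equal(inf$odds_ratio, exp(inf$coef))
  expect_equal(inf$se_or, inf$odds_ratio * inf$se)
  expect_equal(inf$ci_low, exp(inf$coef - qnorm(0.975) * inf$se))
})

test_that("fit_logistic flags degenerate cohorts", {
  withr::with_seed(2, {
    co <- data.frame(ac = c(rep(0.3, 12), rep(1.0, 12)),
                     sos = rnorm(24, 1540, 10), esd = rnorm(24, 90, 5),
                     esc = rlnorm(24, log(2), 0.2),
                     label = rep(c("benign", "malignant"), each = 12))
  })
  expect_warning(fit <- fit_logistic(co), "separation")
  expect_true(attr(fit, "separation"))
  expect_error(fit_logistic(co[co$label == "benign", ]), "labels")
  expect_error(fit_logistic(co[c(1:4, 13:16), ]), "at least 10")
})

test_that("Mann-Whitney U agrees with exhaustive rank enumeration", {
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  res <- mann_whitney(a, b)
  expect_equal(res$U, 0)
  # exhaustive oracle: U statistics of every assignment of 6 ranks to
  # two groups of 3; p = P(U <= 0) * 2 under the null
  combs <- utils::combn(6, 3)
  u_all <- apply(combs, 2, function(ix) sum(ix) - 6)
  expect_equal(res$p, 2 * mean(u_all <= 0))

  a2 <- c(1.2, 3.4, 0.5, 2.2); b2 <- c(2.8, 4.1, 5.0)
  u_obs <- mann_whitney(a2, b2)$U
  ranks <- rank(c(a2, b2))
  expect_equal(u_obs, sum(ranks[1:4]) - 4 * 5 / 2)
})

test_that("Mann-Whitney handles ties, identity and large shifts", {
  expect_equal(mann_whitney(rep(2, 5), rep(2, 7))$p, 1)
  expect_lt(mann_whitney(rnorm(30), rnorm(30) + 10)$p, 0.001)
  withr::with_seed(5, {
    p_null <- mann_whitney(rnorm(25), rnorm(25))$p
    expect_gt(p_null, 0.01)
  })
})

test_that("ROC/AUC: trapezoid equals rank statistic; symmetry; bootstrap CI", {
  withr::with_seed(7, {
    scores <- c(rnorm(40, 1), rnorm(60, 0))
    labels <- rep(c("malignant", "benign"), c(40, 60))
  })
  roc <- roc_auc(scores, labels, n_boot = 200, seed = 3)
  expect_equal(roc$auc, quantus:::auc_rank(scores, labels))
  expect_true(roc$ci[1] <= roc$auc && roc$auc <= roc$ci[2])
  # anti-symmetry
  roc_neg <- roc_auc(-scores, labels, n_boot = 50, seed = 3)
  expect_equal(roc$auc + roc_neg$auc, 1)
  # perfect separation
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1),
                       n_boot = 20, seed = 1)$auc, 1)
  # determinism under seed
  r1 <- roc_auc(scores, labels, n_boot = 100, seed = 9)
  r2 <- roc_auc(scores, labels, n_boot = 100, seed = 9)
  expect_identical(r1$ci, r2$ci)
  expect_error(roc_auc(scores, rep("benign", 100)), "both classes")
})

test_that("Clopper-Pearson intervals match the beta-quantile closed form", {
  ci <- clopper_pearson(0, 10)
  expect_equal(unname(ci), c(0, 1 - 0.025^(1 / 10)), tolerance = 1e-12)
  expect_equal(unname(clopper_pearson(10, 10)), c(0.025^(1 / 10), 1),
               tolerance = 1e-12)
  ci5 <- clopper_pearson(5, 10)
  expect_equal(ci5[["lower"]], 1 - ci5[["upper"]])
  expect_error(clopper_pearson(3, 0), "trials")
  expect_error(clopper_pearson(11, 10))
})
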