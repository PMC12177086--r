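test_that("rank-based AUC equals exhaustive pairwise comparison", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  s <- c(0.1, 0.4, 0.35, 0.8); y <- c(0, 0, 1, 1)
  expect_equal(rocAuc(s, 1 - y), 1 - rocAuc(s, y))
  expect_error(rocAuc(c(0.2, 0.3), c(1, 1)), "both classes")
  set.seed(60)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    sc <- round(runif(n), 2)               # rounding forces ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb), aucOracle(sc, lb), tolerance = 1e-12)
  }
})

test_that("confusion summaries match hand counts and satisfy their identities", {
  s <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.45, 0.4, 0.3, 0.2, 0.1)
  y <- c(1,   1,   0,   1,   0,    1,    0,   0,   1,   0)
  cf <- confusionAt(s, y, 0.5)
  # hand-counted at threshold 0.5: predictions 1,1,1,1,1,0,0,0,0,0
  expect_identical(c(cf$TP, cf$FP, cf$TN, cf$FN), c(3L, 2L, 3L, 2L))
  expect_equal(cf$accuracy, 0.6)
  expect_equal(cf$sensitivity, 3 / 5)
  expect_equal(cf$specificity, 3 / 5)
  expect_equal(cf$ppv, 3 / 5); expect_equal(cf$npv, 3 / 5)
  expect_equal(cf$mistake_rate, 1 - cf$specificity, tolerance = 1e-12)
  expect_equal(cf$omission_rate, 1 - cf$sensitivity, tolerance = 1e-12)
  perfect <- confusionAt(y * 0.8 + 0.1, y, 0.5)
  expect_equal(perfect$sensitivity, 1); expect_equal(perfect$specificity, 1)
  set.seed(61)
  for (i in 1:10) {
    sc <- runif(30); lb <- rbinom(30, 1, 0.6)
    cc <- confusionAt(sc, lb, runif(1, 0.2, 0.8))
    if (!is.na(cc$f1))
      expect_equal(cc$f1, 2 * cc$ppv * cc$sensitivity /
                     (cc$ppv + cc$sensitivity), tolerance = 1e-12)
  }
})

test_that("DeLong test is exact for identical models and antisymmetric in swap", {
  set.seed(62)
  y <- rbinom(60, 1, 0.5); a <- runif(60) + 0.4 * y; b <- runif(60) + 0.2 * y
  same <- delongTest(a, a, y)
  expect_equal(same$aucA - same$aucB, 0)
  expect_identical(same$p, 1)
  d1 <- delongTest(a, b, y); d2 <- delongTest(b, a, y)
  expect_equal(d1$z, -d2$z, tolerance = 1e-12)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_gte(d1$varA, 0); expect_gte(d1$varB, 0)
  expect_error(delongTest(a[1:10], b, y), "paired")
})

test_that("DeLong results agree with an independent reference implementation", {
  set.seed(68)
  y <- rbinom(80, 1, 0.5)
  a <- runif(80) + 0.5 * y
  b <- runif(80) + 0.3 * y
  mine <- delongTest(a, b, y)
  ref <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        pROC::roc(y, b, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
  expect_equal(mine$aucA, as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE,
                                                         direction = "<"))),
               tolerance = 1e-12)
  ci <- delongCI(a, y)
  refci <- pROC::ci.auc(pROC::roc(y, a, quiet = TRUE, direction = "<"),
                        method = "delong")
  expect_equal(c(ci$lower, ci$upper), as.numeric(refci[c(1, 3)]),
               tolerance = 1e-6)
})

test_that("DeLong single-AUC variance tracks a bootstrap on 50 cases", {
  set.seed(63)
  y <- rep(c(1, 0), 25)
  s <- runif(50) + 0.6 * y
  v <- delongCI(s, y)$var
  bs <- replicate(4000, {
    i <- sample(50, replace = TRUE)
    if (length(unique(y[i])) < 2) NA_real_ else rocAuc(s[i], y[i])
  })
  vb <- var(bs, na.rm = TRUE)
  expect_lt(abs(v - vb) / vb, 0.35)       # both are noisy estimators
})

test_that("PR curve handles perfect, tied and hand-checked inputs", {
  expect_equal(prCurve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$ap, 1)
  tied <- prCurve(rep(0.5, 10), c(rep(1, 3), rep(0, 7)))
  expect_equal(tied$points$recall, 1)
  expect_equal(tied$points$precision, 0.3)
  # 6-case hand example, scores all distinct
  s <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4); y <- c(1, 0, 1, 1, 0, 0)
  pc <- prCurve(s, y)
  expect_equal(pc$points$precision, c(1, 1/2, 2/3, 3/4, 3/5, 3/6))
  expect_equal(pc$points$recall, c(1/3, 1/3, 2/3, 1, 1, 1))
  expect_equal(pc$ap, 1/3 * 1 + 1/3 * 2/3 + 1/3 * 3/4, tolerance = 1e-12)
})

test_that("decision-curve identities hold exactly", {
  set.seed(64)
  y <- rbinom(200, 1, 0.35); s <- runif(200)
  prev <- mean(y)
  d <- dca(s, y, thresholds = c(0.1, 0.25, prev, 0.6))
  expect_true(all(d$nb_none == 0))
  expect_equal(d$nb_all[d$threshold == prev], 0, tolerance = 1e-12)
  # perfect classifier: NB = prevalence at every threshold
  dp <- dca(y * 0.98 + 0.01, y, thresholds = c(0.2, 0.5, 0.8))
  expect_equal(dp$nb_model, rep(prev, 3), tolerance = 1e-12)
  # 8-case hand check at pt = 0.25: NB = TP/n - FP/n/3
  s8 <- c(0.9, 0.8, 0.6, 0.4, 0.3, 0.2, 0.15, 0.05)
  y8 <- c(1, 1, 0, 1, 0, 0, 1, 0)
  d8 <- dca(s8, y8, thresholds = 0.25)
  expect_equal(d8$nb_model, 3 / 8 - (2 / 8) * (0.25 / 0.75), tolerance = 1e-12)
  expect_error(dca(s8, y8, thresholds = c(0.5, 1)), "inside")
})

test_that("mean IoU follows the per-image foreground convention", {
  a <- matrix(0, 4, 4); a[2:3, 2:3] <- 1
  expect_equal(meanIoU(list(a), list(a)), 1)
  b <- matrix(0, 4, 4); b[1, 1] <- 1; c_ <- matrix(0, 4, 4); c_[4, 4] <- 1
  expect_equal(meanIoU(list(b), list(c_)), 0)
  r1 <- matrix(0, 1, 4); r1[1, 1:2] <- 1
  r2 <- matrix(0, 1, 4); r2[1, 2:3] <- 1
  expect_equal(meanIoU(list(r1), list(r2)), 1 / 3)
  # empty-union pairs count as IoU 1
  e <- matrix(0, 4, 4)
  expect_equal(meanIoU(list(e, a), list(e, a)), 1)
  expect_error(meanIoU(list(a), list(matrix(0, 3, 3))), "shape")
})

test_that("chi-square reproduces published cohort-comparison p-values", {
  # BI-RADS training vs internal test
  p1 <- chiSquareTest(rbind(c(66, 227, 438, 413), c(29, 51, 103, 90)))$p
  expect_equal(round(p1, 3), 0.036)
  # Ki67 training vs internal
  p2 <- chiSquareTest(rbind(c(102, 776, 266), c(34, 178, 61)))$p
  expect_equal(round(p2, 3), 0.204)
  # identical rows: statistic 0, p 1
  same <- chiSquareTest(rbind(c(10, 20, 30), c(10, 20, 30)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(chiSquareTest(rbind(c(0, 0), c(1, 2))), "all-zero")
})

test_that("chi-square p matches a fixed-margin permutation null", {
  tab <- rbind(c(12, 18, 9), c(7, 25, 14))
  got <- chiSquareTest(tab)
  set.seed(65)
  stat <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  draws <- r2dtable(20000, rowSums(tab), colSums(tab))
  null <- vapply(draws, stat, numeric(1))
  pPerm <- mean(null >= got$statistic - 1e-9)
  se <- sqrt(pPerm * (1 - pPerm) / 20000)
  expect_lt(abs(got$p - pPerm), 4 * se + 0.01)
})

test_that("clinical logistic model recovers known coefficients and orderings", {
  set.seed(66)
  rec <- simulateClinicalRecords(2000)
  truth <- attr(rec, "truth")
  fit <- fitClinicalModel(rec)
  expect_false(fit$separation)
  expect_true(all(abs(fit$coefficients - truth) <= 3 * fit$se))
  # null simulation: coefficients within 3 SE of zero
  rec0 <- simulateClinicalRecords(2000, intercept = 0.2,
                                  biradsCoef = c(0, 0, 0),
                                  tStageCoef = c(0, 0, 0))
  fit0 <- fitClinicalModel(rec0)
  expect_true(all(abs(fit0$coefficients[-1]) <= 3 * fit0$se[-1]))
  # monotone planted risk over BI-RADS gives monotone fitted probabilities
  nd <- data.frame(birads = c("4A", "4B", "4C", "5"), t_stage = "T2")
  pr <- fit$predict(nd)
  expect_true(all(diff(pr) > 0))
  # separation flagged with finite fallback
  sep <- data.frame(birads = rep(c("4A", "5"), each = 30),
                    t_stage = rep(c("T1", "T2"), 30),
                    label = rep(c(0, 1), each = 30))
  expect_warning(fs <- fitClinicalModel(sep), "separation")
  expect_true(all(is.finite(fs$coefficients)))
})

test_that("evaluation reports carry the full metric table and DeLong rows", {
  set.seed(67)
  n <- 80
  y <- rbinom(n, 1, 0.6)
  df <- rbind(
    data.frame(model = "two_stage", split = "internal_test",
               patient_id = sprintf("P%03d", 1:n),
               probability = plogis(2 * y + rnorm(n) - 1), label = y),
    data.frame(model = "clinical", split = "internal_test",
               patient_id = sprintf("P%03d", 1:n),
               probability = plogis(0.5 * y + rnorm(n)), label = y))
  rep <- evalReport(df)
  expect_s4_class(rep, "EvalReport")
  expect_true(all(c("auc", "accuracy", "sensitivity", "specificity",
                    "ppv", "npv", "f1") %in% names(rep@metrics)))
  expect_identical(nrow(rep@comparisons), 1L)
  direct <- delongTest(df$probability[df$model == "two_stage"],
                       df$probability[df$model == "clinical"], y)
  expect_equal(rep@comparisons$p, direct$p, tolerance = 1e-12)
  d <- tempfile(); writeEvalReport(rep, d, plots = FALSE)
  expect_true(file.exists(file.path(d, "metrics.tsv")))
})
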