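test_that("growth rate arithmetic and sign conventions", {
  expect_equal(growthRate(48, 51, 12), 0.25)
  expect_equal(growthRate(50, 50, 24), 0)
  expect_equal(growthRate(50, 49, 10), -0.1)
  expect_error(growthRate(48, 51, 0), "dt must be")
  expect_error(growthRate(48, 51, -3), "dt must be")
})

test_that("risk classes split at an inclusive 0.25 mm/month boundary", {
  cls <- assignClass(c(0.25, 0.2501, -0.1, 0.56))
  expect_equal(as.character(cls), c("low", "fast", "low", "fast"))
  expect_equal(levels(cls), c("low", "fast"))
  expect_equal(as.character(assignClass(0.3, threshold = 0.3)), "low")
})

test_that("Spearman correlation matches the rank-formula oracle", {
  expect_equal(spearmanCorrelation(1:4, c(1, 4, 9, 16))$statistic, 1)
  expect_equal(spearmanCorrelation(1:4, c(4, 3, 2, 1))$statistic, -1)
  x <- c(1, 2, 2, 4); y <- c(3, 1, 4, 2)
  expect_equal(spearmanCorrelation(x, y)$statistic,
               rankFormulaSpearman(x, y), tolerance = 1e-12)
  set.seed(5)
  for (i in 1:10) {
    x <- round(rnorm(12), 1); y <- round(rnorm(12), 1)
    expect_equal(spearmanCorrelation(x, y)$statistic,
                 rankFormulaSpearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearmanCorrelation(rep(1, 5), 1:5), "constant")
  expect_error(spearmanCorrelation(1:2, 1:2), "at least 3")
})

test_that("Mann-Whitney recovers exact and degenerate cases", {
  r <- mannWhitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 0.1)          # 2 / choose(6, 3)
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  expect_equal(mannWhitney(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_equal(mannWhitney(1, 2)$p.value, 1)
  expect_error(mannWhitney(numeric(0), 1), "non-empty")
})

test_that("confusion metrics reproduce printed-style values", {
  m <- metricsFromConfusion(ConfusionMatrix(tp = 5, tn = 38, fp = 3, fn = 4))
  expect_equal(round(100 * m$sensitivity, 1), 55.6)
  expect_equal(round(100 * m$specificity, 1), 92.7)
  expect_equal(round(100 * m$accuracy), 86)
  m2 <- metricsFromConfusion(ConfusionMatrix(tp = 6, tn = 41, fp = 0, fn = 3))
  expect_equal(round(100 * m2$accuracy), 94)
  expect_equal(round(100 * m2$sensitivity, 1), 66.7)
  expect_equal(m2$specificity, 1)
  m3 <- metricsFromConfusion(ConfusionMatrix(1, 1, 1, 1))
  expect_equal(unlist(m3), c(accuracy = 0.5, sensitivity = 0.5,
                             specificity = 0.5))
  expect_error(metricsFromConfusion(ConfusionMatrix(0, 5, 2, 0)),
               "sensitivity undefined")
  expect_error(metricsFromConfusion(ConfusionMatrix(3, 0, 0, 2)),
               "specificity undefined")
})

test_that("likelihood ratios cover finite, infinite and undefined cases", {
  lr <- likelihoodRatios(0.556, 0.927)
  expect_equal(round(lr[["pos"]], 2), 7.62)
  expect_equal(round(lr[["neg"]], 2), 0.48)
  lr2 <- likelihoodRatios(0.667, 1)
  expect_identical(lr2[["pos"]], Inf)
  expect_equal(round(lr2[["neg"]], 2), 0.33)
  lr3 <- likelihoodRatios(0, 1)
  expect_true(is.na(lr3[["pos"]]))
  expect_equal(lr3[["neg"]], 1)
  expect_equal(likelihoodRatios(0, 0.976)[["pos"]], 0)
  expect_error(likelihoodRatios(1.2, 0.5), "lie in")
})

test_that("likelihood-ratio identities hold for any full confusion matrix", {
  set.seed(9)
  for (i in 1:20) {
    cm <- ConfusionMatrix(tp = sample(1:20, 1), tn = sample(1:20, 1),
                          fp = sample(1:20, 1), fn = sample(1:20, 1))
    m <- metricsFromConfusion(cm)
    lr <- likelihoodRatios(m$sensitivity, m$specificity)
    expect_equal(lr[["pos"]] * (1 - m$specificity), m$sensitivity,
                 tolerance = 1e-12)
    expect_equal(lr[["neg"]] * m$specificity, 1 - m$sensitivity,
                 tolerance = 1e-12)
  }
})

test_that("AUROC equals exhaustive pair counting and survives monotone maps", {
  expect_equal(aurocScore(c(0.9, 0.8, 0.1, 0.2),
                          c("fast", "fast", "low", "low")), 1)
  expect_equal(aurocScore(rep(0.5, 6),
                          c("fast", "low", "fast", "low", "low", "low")), 0.5)
  expect_equal(aurocScore(c(3, 1, 2), c("fast", "low", "low")), 1)
  expect_equal(aurocScore(c(1, 3, 2), c("fast", "low", "low")), 0)
  expect_equal(aurocScore(c(2, 1, 3), c("fast", "low", "low")), 0.5)
  set.seed(31)
  for (i in 1:10) {
    sc <- round(rnorm(20), 1)
    lab <- sample(c("fast", "low"), 20, replace = TRUE,
                  prob = c(0.3, 0.7))
    if (length(unique(lab)) < 2) next
    expect_equal(aurocScore(sc, lab), pairCountAUROC(sc, lab),
                 tolerance = 1e-12)
    expect_equal(aurocScore(exp(2 * sc) + 5, lab), aurocScore(sc, lab),
                 tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  sc <- rnorm(30); lab <- rep(c("fast", "low"), c(10, 20))
  expect_equal(aurocScore(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, levels = c("low", "fast"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("all six classifiers separate a well-separated synthetic cohort", {
  set.seed(2)
  n <- 25
  coh <- data.frame(D = c(rnorm(n, 0, 1), rnorm(n, 6, 1)),
                    DCR = c(rnorm(n, 0, 1), rnorm(n, 6, 1)))
  labels <- factor(rep(c("low", "fast"), each = n), levels = c("low", "fast"))
  for (m in c("ld", "lr", "svm", "knn")) {
    r <- loocvClassify(coh, labels, m, featureSubset = c("D", "DCR"),
                       seed = 4)
    expect_equal(r@accuracy, 1, tolerance = 1e-9)
    expect_equal(r@auroc, 1, tolerance = 1e-9)
  }
})

test_that("LOOCV classification is deterministic given a seed", {
  coh <- simulateCohort(n = 40, nFast = 8, seed = 12)
  a <- loocvClassify(coh, coh$risk_class, "svm", seed = 99)
  b <- loocvClassify(coh, coh$risk_class, "svm", seed = 99)
  expect_identical(a@scores, b@scores)
  expect_identical(confusionCounts(a@confusion), confusionCounts(b@confusion))
})

test_that("classifier report metrics reproduce from its confusion matrix", {
  coh <- simulateCohort(n = 40, nFast = 10, seed = 3)
  r <- loocvClassify(coh, coh$risk_class, "knn", seed = 3)
  cm <- confusionCounts(r@confusion)
  expect_equal(sum(cm), 40L)
  m <- metricsFromConfusion(r@confusion)
  expect_equal(r@accuracy, m$accuracy, tolerance = 1e-12)
  expect_equal(r@sensitivity, m$sensitivity, tolerance = 1e-12)
  expect_equal(r@specificity, m$specificity, tolerance = 1e-12)
  expect_equal(r@prevalence, 0.25)
})

test_that("LOOCV input contracts are enforced", {
  coh <- simulateCohort(n = 20, nFast = 5, seed = 6)
  allLow <- factor(rep("low", 20), levels = c("low", "fast"))
  expect_error(loocvClassify(coh, allLow, "ld"), "single class")
  bad <- coh; bad$D[3] <- NA
  expect_error(loocvClassify(bad, coh$risk_class, "ld"), "row")
  expect_error(loocvClassify(coh, coh$risk_class, "ld",
                             featureSubset = "nope"), "not found")
})

test_that("paper-mode hyperparameter search remains deterministic and sane", {
  coh <- simulateCohort(n = 30, nFast = 8, seed = 8)
  a <- loocvClassify(coh, coh$risk_class, "knn", seed = 5, paperMode = TRUE)
  b <- loocvClassify(coh, coh$risk_class, "knn", seed = 5, paperMode = TRUE)
  expect_identical(a@scores, b@scores)
  expect_gte(a@auroc, 0.5)
})
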