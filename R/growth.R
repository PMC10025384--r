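#' Aneurysm growth rate between two exams
#'
#' `GR = (D2 - D1) / dt` in mm/month. Negative values (measurement noise
#' between exams) are legitimate and not clipped.
#'
#' @param d1,d2 maximum diameters at the first and second exam (mm).
#' @param dt inter-exam interval in months (> 0).
#' @return Growth rate in mm/month (vectorized).
#' @examples
#' growthRate(48, 51, 12)  # 0.25
#' @export
growthRate <- function(d1, d2, dt) {
  if (any(!is.finite(dt)) || any(dt <= 0))
    stop("dt must be > 0 months")
  (d2 - d1) / dt
}

#' Assign a growth-risk class
#'
#' Patients with `GR <= threshold` (default 0.25 mm/month, i.e. the
#' 3 mm/year guideline rate) form the low-risk class; the boundary is
#' inclusive on the low side. The rest are the fast-growth class.
#'
#' @param gr growth rate(s) in mm/month.
#' @param threshold class boundary in mm/month.
#' @return factor with levels `c("low", "fast")`.
#' @examples
#' assignClass(c(0.25, 0.2501, -0.1))
#' @export
assignClass <- function(gr, threshold = 0.25) {
  factor(ifelse(gr <= threshold, "low", "fast"), levels = c("low", "fast"))
}

#' Spearman rank correlation between a feature and growth rate
#'
#' Rank correlation with average ranks for ties; the two-sided p-value
#' uses the exact null distribution for small tie-free samples and the
#' t approximation otherwise.
#'
#' @param x,y equal-length numeric vectors (n >= 3).
#' @return `list(statistic, p.value)` with the correlation in
#'   `statistic`.
#' @examples
#' spearmanCorrelation(1:4, c(1, 4, 9, 16))$statistic  # 1
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(statistic = unname(ct$estimate), p.value = ct$p.value)
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two groups
#'
#' Two-sided test, e.g. growth rates from ECG-gated versus non-gated
#' acquisitions. Exact for small tie-free samples, normal approximation
#' with tie correction otherwise.
#'
#' @param a,b numeric vectors (non-empty).
#' @return `list(statistic, p.value)` with the U statistic in `statistic`.
#' @examples
#' mannWhitney(c(1, 2, 3), c(10, 11, 12))$p.value  # 0.1
#' @export
mannWhitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value)
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return `list(accuracy, sensitivity, specificity)` (fractions).
#' @examples
#' metricsFromConfusion(ConfusionMatrix(tp = 5, tn = 38, fp = 3, fn = 4))
#' @export
metricsFromConfusion <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; tn <- cm@tn; fp <- cm@fp; fn <- cm@fn
  total <- tp + tn + fp + fn
  if (total == 0L) stop("empty confusion matrix")
  if (tp + fn == 0L) stop("sensitivity undefined: no positive cases")
  if (tn + fp == 0L) stop("specificity undefined: no negative cases")
  list(accuracy = (tp + tn) / total,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp))
}

#' Diagnostic likelihood ratios
#'
#' `LHR+ = sensitivity / (1 - specificity)` and
#' `LHR- = (1 - sensitivity) / specificity`: the change in the odds of
#' fast growth given a positive (negative) test. A perfectly specific
#' test with non-zero sensitivity gives `LHR+ = +Inf`; a test with zero
#' sensitivity and perfect specificity has an undefined `LHR+`, returned
#' as `NA` (not an error).
#'
#' @param sensitivity,specificity fractions in [0, 1].
#' @return `c(pos = LHR+, neg = LHR-)`; `Inf` and `NA` as described.
#' @examples
#' likelihoodRatios(0.556, 0.927)  # ~ c(7.62, 0.48)
#' @export
likelihoodRatios <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0) ||
        any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  pos <- if (specificity == 1) {
    if (sensitivity > 0) Inf else NA_real_
  } else sensitivity / (1 - specificity)
  neg <- if (specificity == 0) {
    if (sensitivity < 1) Inf else NA_real_
  } else (1 - sensitivity) / specificity
  c(pos = pos, neg = neg)
}

#' Area under the ROC curve by pairwise comparison
#'
#' The probability that a randomly chosen fast-growth patient scores
#' higher than a randomly chosen low-risk patient, ties counting one
#' half — the Mann-Whitney formulation, computed from average ranks
#' (identical to exhaustive cross-pair counting).
#'
#' @param scores numeric classifier scores (higher = more likely fast).
#' @param labels factor/character/logical with positive class `"fast"`
#'   (or `TRUE`/1).
#' @return AUROC in [0, 1].
#' @examples
#' aurocScore(c(3, 1, 2), c("fast", "low", "low"))  # 1
#' @export
aurocScore <- function(scores, labels) {
  pos <- .asPositive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUROC")
  if (any(!is.finite(scores))) stop("non-finite scores")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.asPositive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == max(labels))
  as.character(labels) == "fast"
}

#' Leave-one-out cross-validated growth-risk classification
#'
#' Trains one of six classifiers — decision tree (`"dt"`), linear
#' discriminant (`"ld"`), logistic regression (`"lr"`), Gaussian naive
#' Bayes (`"nb"`), RBF support vector machine (`"svm"`), k-nearest
#' neighbours (`"knn"`) — on all patients but one and predicts the
#' held-out patient, for every patient in turn. Features are standardized
#' with training-fold statistics only (LD/LR/SVM/KNN). Hyperparameters
#' (tree complexity, SVM cost, k) are tuned by an inner cross-validation
#' on each training fold, i.e. nested, so no information from the
#' held-out patient leaks into model selection; logistic regression has
#' no tuned hyperparameter. With `paperMode = TRUE` the hyperparameters
#' are instead tuned once on the full data set before the outer loop
#' (the laxer protocol some studies use).
#'
#' Pooled held-out scores give the ROC; the confusion matrix of held-out
#' class predictions gives accuracy, sensitivity, specificity and the
#' likelihood ratios.
#'
#' @param features data.frame holding at least the columns in
#'   `featureSubset`.
#' @param labels factor with levels `c("low", "fast")` (or coercible).
#' @param model one of `"dt", "ld", "lr", "nb", "svm", "knn"`.
#' @param featureSubset character vector of feature column names
#'   (default `c("D", "DCR", "EILR", "T")` intersected with available).
#' @param seed integer seed; the run is deterministic given it.
#' @param paperMode logical, see above.
#' @return A [ClassifierReport-class].
#' @examples
#' coh <- simulateCohort(n = 30, nFast = 10, seed = 7)
#' rep <- loocvClassify(coh, coh$risk_class, "ld", c("D", "DCR"), seed = 7)
#' rep
#' @export
loocvClassify <- function(features, labels,
                          model = c("dt", "ld", "lr", "nb", "svm", "knn"),
                          featureSubset = c("D", "DCR", "EILR", "T"),
                          seed = 1, paperMode = FALSE) {
  model <- match.arg(model)
  labels <- factor(as.character(labels), levels = c("low", "fast"))
  if (any(is.na(labels))) stop("labels must be 'low' or 'fast'")
  if (nlevels(droplevels(labels)) < 2L)
    stop("labels contain a single class; need both 'low' and 'fast'")
  if (min(table(labels)) < 2L) stop("need at least 2 patients per class")
  featureSubset <- as.character(featureSubset)
  missingF <- setdiff(featureSubset, names(features))
  if (length(missingF) > 0L)
    stop("feature column(s) not found: ", paste(missingF, collapse = ", "))
  X <- as.matrix(features[, featureSubset, drop = FALSE])
  storage.mode(X) <- "double"
  bad <- which(!stats::complete.cases(X) | rowSums(!is.finite(X)) > 0)
  if (length(bad) > 0L)
    stop("non-finite feature value in row(s): ",
         paste(bad, collapse = ", "))
  n <- nrow(X)
  if (n != length(labels)) stop("features and labels differ in length")
  set.seed(as.integer(seed))

  hyperFull <- if (paperMode) .tuneModel(model, .standardize(X)$x, labels)
               else NULL
  scores <- numeric(n)
  pred <- character(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- labels[-i]
    Xte <- X[i, , drop = FALSE]
    if (model %in% c("ld", "lr", "svm", "knn")) {
      st <- .standardize(Xtr)
      Xtr <- st$x
      Xte <- sweep(sweep(Xte, 2, st$center), 2, st$scale, "/")
    }
    hyper <- if (paperMode) hyperFull else .tuneModel(model, Xtr, ytr)
    out <- .trainPredict(model, Xtr, ytr, Xte, hyper)
    scores[i] <- out$score
    pred[i] <- out$class
  }
  pred <- factor(pred, levels = c("low", "fast"))
  cm <- ConfusionMatrix(tp = sum(pred == "fast" & labels == "fast"),
                        tn = sum(pred == "low" & labels == "low"),
                        fp = sum(pred == "fast" & labels == "low"),
                        fn = sum(pred == "low" & labels == "fast"))
  met <- metricsFromConfusion(cm)
  lhr <- likelihoodRatios(met$sensitivity, met$specificity)
  new("ClassifierReport", model = model, features = featureSubset,
      confusion = cm, accuracy = met$accuracy,
      sensitivity = met$sensitivity, specificity = met$specificity,
      lhrPos = unname(lhr["pos"]), lhrNeg = unname(lhr["neg"]),
      auroc = aurocScore(scores, labels), scores = scores,
      predicted = pred, prevalence = mean(labels == "fast"))
}

.standardize <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-12] <- 1
  list(x = sweep(sweep(X, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

# Inner-CV hyperparameter selection on the training fold.
.tuneModel <- function(model, X, y) {
  n <- nrow(X)
  switch(model,
    knn = {
      ks <- c(1L, 3L, 5L, 7L, 9L)
      ks <- ks[ks < n]
      err <- vapply(ks, function(k)
        mean(class::knn.cv(X, y, k = k) != y), numeric(1))
      list(k = ks[which.min(err)])   # ties: smallest k
    },
    svm = {
      costs <- c(0.1, 1, 10, 100)
      acc <- vapply(costs, function(cc) {
        fit <- e1071::svm(X, y, kernel = "radial", cost = cc, cross = 10)
        fit$tot.accuracy
      }, numeric(1))
      list(cost = costs[which.max(acc)])
    },
    dt = {
      df <- data.frame(y = y, X)
      fit <- rpart::rpart(y ~ ., data = df, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         cp = 0, xval = 10))
      tab <- fit$cptable
      list(cp = tab[which.min(tab[, "xerror"]), "CP"])
    },
    list())
}

.trainPredict <- function(model, Xtr, ytr, Xte, hyper) {
  dtr <- data.frame(y = ytr, Xtr)
  dte <- data.frame(Xte)
  names(dte) <- colnames(Xtr)
  switch(model,
    ld = {
      fit <- MASS::lda(Xtr, grouping = ytr)
      pr <- stats::predict(fit, Xte)
      list(class = as.character(pr$class),
           score = pr$posterior[1, "fast"])
    },
    lr = {
      fit <- suppressWarnings(stats::glm(y ~ ., data = dtr,
                                         family = stats::binomial()))
      p <- suppressWarnings(stats::predict(fit, dte, type = "response"))
      list(class = if (p > 0.5) "fast" else "low", score = unname(p))
    },
    nb = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      p <- stats::predict(fit, Xte, type = "raw")[1, "fast"]
      cl <- as.character(stats::predict(fit, Xte, type = "class"))
      list(class = cl, score = unname(p))
    },
    svm = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", cost = hyper$cost)
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      sc <- dv[1, 1]
      if (!startsWith(colnames(dv)[1], "fast")) sc <- -sc
      list(class = as.character(pr[1]), score = unname(sc))
    },
    knn = {
      pr <- class::knn(Xtr, Xte, ytr, k = hyper$k, prob = TRUE)
      p <- attr(pr, "prob")
      sc <- if (as.character(pr) == "fast") p else 1 - p
      list(class = as.character(pr), score = unname(sc))
    },
    dt = {
      fit <- rpart::rpart(y ~ ., data = dtr, method = "class",
                          control = rpart::rpart.control(minsplit = 5,
                                                         cp = 0, xval = 0))
      fit <- rpart::prune(fit, cp = hyper$cp)
      p <- stats::predict(fit, dte, type = "prob")[1, "fast"]
      list(class = if (p > 0.5) "fast" else "low", score = unname(p))
    })
}
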