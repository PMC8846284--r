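# the published multiclass confusion matrix (rows = predicted PD/MSA/PSP,
# columns = true), used as the arithmetic oracle for the metric suite
publishedMatrix <- function() {
  confusionMatrix(matrix(c(43, 5, 4,
                           6, 29, 2,
                           1, 3, 14), 3, 3, byrow = TRUE),
                  classes = c("PD", "MSA", "PSP"))
}

test_that("the published confusion matrix reproduces its printed metrics", {
  m <- metricsFromMatrix(publishedMatrix())
  expect_equal(asPercent(m$accuracy), 80.4)
  pc <- m$perClass
  expect_equal(asPercent(pc$sensitivity[pc$class == "PD"]), 86.0)
  expect_equal(asPercent(pc$specificity[pc$class == "PD"]), 84.2)
  expect_equal(asPercent(pc$ppv[pc$class == "MSA"]), 78.4)
  expect_equal(asPercent(pc$npv[pc$class == "MSA"]), 88.6)
  expect_equal(asPercent(pc$sensitivity[pc$class == "MSA"]), 78.4)
  expect_equal(asPercent(pc$specificity[pc$class == "MSA"]), 88.6)
  expect_equal(asPercent(pc$specificity[pc$class == "PSP"]), 95.4)
  expect_equal(asPercent(pc$sensitivity[pc$class == "PSP"]), 70.0)
  expect_equal(asPercent(pc$ppv[pc$class == "PD"]), 82.7)
  expect_equal(asPercent(pc$npv[pc$class == "PD"]), 87.3)
  expect_equal(asPercent(pc$npv[pc$class == "PSP"]), 93.3)
  # 14/18 rounds to 77.8 at one decimal (printed sources sometimes
  # truncate); the recomputed value is asserted
  expect_equal(asPercent(pc$ppv[pc$class == "PSP"]), 77.8)
})

test_that("perfect and degenerate classifiers give boundary metrics", {
  perfect <- confusionMatrix(diag(c(10L, 10L, 10L)),
                             classes = c("PD", "MSA", "PSP"))
  m <- metricsFromMatrix(perfect)
  expect_equal(m$accuracy, 1)
  expect_true(all(unlist(m$perClass[, -1]) == 1))
  onecol <- confusionMatrix(matrix(c(10, 10, 10, 0, 0, 0, 0, 0, 0),
                                   3, 3, byrow = TRUE),
                            classes = c("PD", "MSA", "PSP"))
  m2 <- metricsFromMatrix(onecol)
  expect_equal(m2$perClass$sensitivity[1], 1)
  expect_equal(m2$perClass$specificity[1], 0)
  # classes never predicted have undefined PPV, flagged not raised
  expect_true(is.na(m2$perClass$ppv[2]))
  expect_true("MSA:ppv" %in% m2$undefined)
})

test_that("metrics agree with a per-subject counting oracle", {
  set.seed(42)
  classes <- c("PD", "MSA", "PSP")
  for (rep in 1:100) {
    cm <- matrix(rpois(9, 5), 3, 3, dimnames = list(classes, classes))
    if (sum(cm) == 0) next
    m <- metricsFromMatrix(confusionMatrix(cm))
    # expand to per-subject labels and count directly
    pred <- rep(rep(classes, 3), as.vector(cm))
    true <- rep(rep(classes, each = 3), as.vector(cm))
    expect_equal(m$accuracy, mean(pred == true))
    for (cl in classes) {
      tp <- sum(pred == cl & true == cl); fn <- sum(pred != cl & true == cl)
      fp <- sum(pred == cl & true != cl); tn <- sum(pred != cl & true != cl)
      i <- which(m$perClass$class == cl)
      if (tp + fn > 0) expect_equal(m$perClass$sensitivity[i], tp / (tp + fn))
      if (tn + fp > 0) expect_equal(m$perClass$specificity[i], tn / (tn + fp))
      if (tp + fp > 0) expect_equal(m$perClass$ppv[i], tp / (tp + fp))
      if (tn + fn > 0) expect_equal(m$perClass$npv[i], tn / (tn + fn))
    }
  }
})

test_that("binary accuracies rebuild from sensitivity/specificity", {
  expect_equal(asPercent(binaryAccuracyFromSensSpec(0.840, 0.860, 50, 57)),
               85.0)
  expect_equal(asPercent(binaryAccuracyFromSensSpec(0.730, 0.871, 37, 70)),
               82.2)
  expect_equal(asPercent(binaryAccuracyFromSensSpec(0.700, 0.943, 20, 87)),
               89.7)
  expect_equal(binaryAccuracyFromSensSpec(1, 1, 13, 29), 1)
  expect_error(binaryAccuracyFromSensSpec(1.2, 0.5, 10, 10), "\\[0, 1\\]")
})

test_that("error counts convert to percentage accuracies", {
  expect_equal(accuracyFromErrorCount(8, 36), 77.8)
  expect_equal(accuracyFromErrorCount(11, 36), 69.4)
  expect_equal(accuracyFromErrorCount(15, 36), 58.3)
  expect_equal(accuracyFromErrorCount(16, 36), 55.6)
  expect_equal(accuracyFromErrorCount(0, 17), 100.0)
  expect_error(accuracyFromErrorCount(5, 4), "errors")
})

test_that("rank AUC handles perfect order, ties and the printed example", {
  expect_equal(aucRank(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(aucRank(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(aucRank(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_error(aucRank(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("rank AUC equals the all-pairs enumeration on random sets", {
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # ties likely
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
    expect_equal(aucRank(scores, labels), mean(pairs), tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  scores <- rnorm(40); labels <- rbinom(40, 1, 0.5)
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(aucRank(scores, labels), ref, tolerance = 1e-10)
})

test_that("confusion matrices validate their structure", {
  expect_error(confusionMatrix(matrix(c(1, -2, 3, 4), 2, 2,
                                      dimnames = list(c("a", "b"),
                                                      c("a", "b")))),
               "nonnegative")
  res <- confusionMatrix(true = c("PD", "MSA", "PD"),
                         predicted = c("PD", "PD", "PD"),
                         classes = c("PD", "MSA"))
  expect_equal(sum(counts(res)), 3L)
  expect_equal(unname(colSums(counts(res))), c(2L, 1L))
})
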