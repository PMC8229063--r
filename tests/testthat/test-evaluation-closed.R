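test_that("stratified folds respect the class balance bands", {
  labels <- rep(CLS, c(83L, 294L, 71L, 149L))
  plan <- stratifiedKFold(labels, 10L, seed = 2L)
  tab <- foldSizes(plan)
  expect_true(all(tab["C1", ] %in% 8:9))
  expect_true(all(tab["C2", ] %in% 29:30))
  expect_true(all(tab["C3", ] %in% 7:8))
  expect_true(all(tab["C4", ] %in% 14:15))
  # a fold testing 8 + 29 + 7 + 15 = 59 samples trains on 538
  testTotals <- colSums(tab)
  expect_true(59 %in% testTotals)
  for (fold in seq_len(10L)) {
    fi <- foldIndices(plan, fold)
    expect_equal(length(fi$train) + length(fi$test), 597L)
    expect_length(intersect(fi$train, fi$test), 0L)
  }
  expect_equal(length(plan@foldId), 597L)
})

test_that("fold assignment is seeded and handles edge cases", {
  labels <- rep("C1", 20L)
  plan <- stratifiedKFold(labels, 10L, seed = 1L)
  expect_true(all(foldSizes(plan) == 2L))
  expect_identical(stratifiedKFold(rep(CLS, 10), 5L, 7L)@foldId,
                   stratifiedKFold(rep(CLS, 10), 5L, 7L)@foldId)
  expect_false(identical(stratifiedKFold(rep(CLS, 10), 5L, 7L)@foldId,
                         stratifiedKFold(rep(CLS, 10), 5L, 8L)@foldId))
  expect_warning(stratifiedKFold(c(rep("C1", 20), "C2"), 10L, 1L),
                 "fewer samples")

  # property: partition/balance invariants on arbitrary class sizes
  set.seed(6)
  for (i in 1:10) {
    sizes <- sample(1:40, 4L)
    labs <- rep(CLS, sizes)
    pl <- suppressWarnings(stratifiedKFold(labs, sample(2:10, 1L), seed = i))
    tb <- foldSizes(pl)
    expect_true(all(apply(tb, 1, function(x) diff(range(x))) <= 1))
    expect_equal(sum(tb), length(labs))
  }
})

test_that("confusion matrices tally exactly", {
  cmAll <- confusionMatrix(CLS, CLS)
  expect_identical(counts(cmAll), diag(1L, 4L, 4L),
                   ignore_attr = TRUE)

  truth <- rep(c("c1", "c2"), each = 10L)
  pred <- truth
  pred[c(3, 7)] <- "c2"; pred[15] <- "c1"
  cm <- confusionMatrix(pred, truth, c("c1", "c2"))
  expect_equal(unname(counts(cm)), matrix(c(8L, 1L, 2L, 9L), 2L))

  expect_error(confusionMatrix(c("C1", "Depuyy"), c("C1", "C2"), CLS),
               "Depuyy")

  # TP/TN/FP/FN vs an independent per-sample counting loop
  set.seed(7)
  truth4 <- sample(CLS, 200L, replace = TRUE)
  pred4 <- sample(CLS, 200L, replace = TRUE)
  cc <- classCounts(confusionMatrix(pred4, truth4, CLS))
  for (k in CLS) {
    tp <- fp <- fn <- tn <- 0L
    for (i in seq_along(truth4)) {
      if (truth4[i] == k && pred4[i] == k) tp <- tp + 1L
      else if (truth4[i] != k && pred4[i] == k) fp <- fp + 1L
      else if (truth4[i] == k && pred4[i] != k) fn <- fn + 1L
      else tn <- tn + 1L
    }
    row <- cc[cc$class == k, ]
    expect_equal(c(row$TP, row$FP, row$FN, row$TN), c(tp, fp, fn, tn))
  }
})

test_that("macro metrics agree with a brute-force oracle in all modes", {
  perfect <- confusionMatrix(rep(CLS, 5L), rep(CLS, 5L), CLS)
  for (am in c("overall", "eq4_literal")) {
    r <- metricsReport(perfect, accuracyMode = am)
    expect_equal(unname(metricsVector(r)), rep(100, 4L))
  }

  cm <- methods::new("ConfusionMatrix",
                     counts = matrix(c(8L, 1L, 2L, 9L), 2L,
                                     dimnames = list(c("a", "b"),
                                                     c("a", "b"))))
  r <- metricsReport(cm)
  expect_equal(r@recall, (0.8 + 0.9) / 2 * 100)
  expect_equal(r@accuracy, 85)
  expect_equal(metricsReport(cm, accuracyMode = "eq4_literal")@accuracy, 85)

  # oracle equivalence on 100 random confusion matrices (K = 4), plus the
  # affine identity between the two accuracy modes
  set.seed(8)
  for (i in 1:100) {
    n <- sample(20:80, 1L)
    truth <- sample(CLS, n, replace = TRUE)
    pred <- ifelse(stats::runif(n) < 0.6, truth,
                   sample(CLS, n, replace = TRUE))
    cmr <- confusionMatrix(pred, truth, CLS)
    rep_ <- suppressWarnings(metricsReport(cmr))
    # brute-force per-class computation from raw labels
    prec <- rec <- numeric(4L)
    for (ki in 1:4) {
      k <- CLS[ki]
      tp <- sum(truth == k & pred == k)
      fp <- sum(truth != k & pred == k)
      fn <- sum(truth == k & pred != k)
      prec[ki] <- if (tp + fp == 0) 0 else tp / (tp + fp)
      rec[ki] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    }
    expect_equal(rep_@precision, mean(prec) * 100, tolerance = 1e-10)
    expect_equal(rep_@recall, mean(rec) * 100, tolerance = 1e-10)
    expect_equal(rep_@accuracy, mean(pred == truth) * 100,
                 tolerance = 1e-10)
    expect_equal(rep_@f1,
                 2 * rep_@precision * rep_@recall /
                   (rep_@precision + rep_@recall), tolerance = 1e-10)
    lit <- suppressWarnings(
      metricsReport(cmr, accuracyMode = "eq4_literal"))
    expect_equal(lit@accuracy, 100 - (100 - rep_@accuracy) / 2,
                 tolerance = 1e-10)
  }
})

test_that("the literal recall variant divides by TP + TN", {
  cm <- confusionMatrix(c("C1", "C1", "C2", "C2"),
                        c("C1", "C2", "C1", "C2"), c("C1", "C2"))
  r <- metricsReport(cm, recallMode = "eq7_literal")
  # per class TP = 1, TN = 1 -> 0.5 each
  expect_equal(r@recall, 50)
  expect_error(metricsReport(confusionMatrix(character(0), character(0),
                                             c("C1", "C2"))),
               "empty")
})

test_that("pooled paired t-test handles regular and degenerate inputs", {
  set.seed(9)
  mk <- function(shift = 0, noise = 0) lapply(1:10, function(i) {
    v <- stats::runif(4, 60, 90) + shift + stats::rnorm(4, 0, noise)
    methods::new("MetricsReport", accuracy = v[1], f1 = v[2],
                 precision = v[3], recall = v[4],
                 accuracyMode = "overall", recallMode = "standard")
  })
  A <- mk()
  expect_equal(pooledPairedTTest(A, A)$p.value, 1)

  B <- lapply(A, function(r)
    methods::new("MetricsReport", accuracy = r@accuracy - 5,
                 f1 = r@f1 - 5, precision = r@precision - 5,
                 recall = r@recall - 5, accuracyMode = "overall",
                 recallMode = "standard"))
  degenerate <- pooledPairedTTest(A, B)
  expect_equal(degenerate$p.value, 0)
  expect_true(is.infinite(degenerate$statistic))

  C <- mk(shift = 2, noise = 3)
  res <- pooledPairedTTest(A, C)
  # textbook paired t statistic on the pooled 40 differences
  d <- unlist(lapply(A, metricsVector)) - unlist(lapply(C, metricsVector))
  tstat <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  p <- 2 * stats::pt(-abs(tstat), df = length(d) - 1)
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  expect_equal(res$p.value, p, tolerance = 1e-10)
  expect_equal(res$df, 39)
})

test_that("closed-world protocol accounting holds on the reduced runs", {
  runs <- closedWorldResults()
  man <- phantomManifest()
  for (res in runs) {
    expect_length(res$folds, 2L)
    # every sample tested exactly once across the k = 2 folds
    expect_equal(sum(counts(res$confusion)), nrow(man))
    expect_equal(unname(rowSums(counts(res$confusion))[CLS]),
                 unname(as.vector(table(man$label)[CLS])))
    testTotals <- colSums(foldSizes(res$plan))
    expect_equal(sum(testTotals), nrow(man))
  }
})
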