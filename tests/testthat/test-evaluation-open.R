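test_that("gallery means equal brute-force accumulation", {
  g1 <- buildGallery(matrix(c(1, 2, 3), 1L), "C1")
  expect_equal(unname(g1@means[, "C1"]), c(1, 2, 3))

  X <- rbind(rep(0, 5), rep(2, 5))
  g2 <- buildGallery(X, c("C1", "C1"))
  expect_equal(unname(g2@means[, "C1"]), rep(1, 5))

  set.seed(10)
  X3 <- matrix(rnorm(60), 12L)
  lab3 <- sample(CLS[1:3], 12L, replace = TRUE)
  g3 <- buildGallery(X3, lab3)
  for (cl in unique(lab3)) {
    acc <- rep(0, 5); n <- 0L
    for (i in seq_along(lab3)) if (lab3[i] == cl) {
      acc <- acc + X3[i, ]; n <- n + 1L
    }
    expect_equal(unname(g3@means[, cl]), acc / n, tolerance = 1e-12)
  }
})

test_that("nearest-class-mean matching is exact on constructed cases", {
  e1 <- c(1, rep(0, 4)); e2 <- c(0, 1, rep(0, 3))
  g <- buildGallery(rbind(e1, e2), c("L1", "L2"))
  expect_identical(matchGallery(e1, g), "L1")
  expect_identical(matchGallery(0.9 * e1 + 0.1 * e2, g), "L1")

  # translation invariance of L2 matching
  set.seed(11)
  q <- rnorm(5); shift <- rnorm(5)
  gShift <- buildGallery(rbind(e1 + rep(1, 5) * 0, e2) +
                           matrix(shift, 2L, 5L, byrow = TRUE),
                         c("L1", "L2"))
  expect_identical(matchGallery(q, g), matchGallery(q + shift, gShift))

  # permutation equivariance of labels
  gPerm <- buildGallery(rbind(e2, e1), c("L2", "L1"))
  expect_identical(matchGallery(q, g), matchGallery(q, gPerm))

  # ties break toward the earliest registered label
  gTie <- buildGallery(rbind(e1, e1), c("A", "B"))
  expect_identical(matchGallery(e1, gTie), "A")
  expect_error(matchGallery(c(1, 2), g), "dimension")
})

test_that("class registration is isolated and needs no retraining", {
  set.seed(12)
  base <- matrix(rnorm(20), 4L)
  g <- buildGallery(base, c("A", "A", "B", "B"))
  enroll <- matrix(rnorm(10, mean = 8), 2L)
  g2 <- registerClass(g, "C", enroll)
  expect_equal(ncol(g2@means), 3L)
  expect_identical(g2@means[, c("A", "B")], g@means[, c("A", "B")])
  expect_identical(matchGallery(enroll[1L, ], g2), "C")
  expect_error(registerClass(g2, "C", enroll), "already registered")
  g3 <- registerClass(g2, "C", enroll + 1, overwrite = TRUE)
  expect_equal(unname(g3@means[, "C"]), colMeans(enroll + 1))
})

test_that("open-world plans are class-disjoint", {
  plan <- openWorldPlan(labels = CLS)
  expect_length(plan@runs, 4L)
  expect_identical(plan@runs[["1st fold-A"]]$train, c("C1", "C2"))
  expect_identical(plan@runs[["1st fold-A"]]$test, c("C3", "C4"))
  expect_identical(plan@runs[["2nd fold-A"]]$test, c("C4", "C2"))
  expect_error(openWorldPlan(list(bad = list(train = c("C1", "C2"),
                                             test = c("C2", "C3")))),
               "disjoint")
})

test_that("leave-one-out means exclude the query", {
  # two classes; one outlier query would match its own class only if the
  # leave-one-out mean excluded it is violated
  A <- rbind(c(0, 0), c(0.2, 0), c(0, 0.2), c(10, 10))
  labs <- c("A", "A", "A", "B")
  B <- rbind(A, c(5.4, 5.4), c(10.2, 10))
  labs <- c("A", "A", "A", "B", "A", "B")
  pred <- DRENet:::.leaveOneOutMatch(B, labs, c("A", "B"))
  # the 5th sample (labelled A, but sitting at (5.4, 5.4)) must be judged
  # against the A-mean computed WITHOUT itself (~(0.07, 0.07)), so it
  # matches B; with self-inclusion the A-mean would move to ~(1.4, 1.4)
  # and keep it as A
  expect_identical(pred[5L], "B")
  # recomputation check for every sample
  for (i in seq_along(labs)) {
    means <- sapply(c("A", "B"), function(cl) {
      idx <- setdiff(which(labs == cl), i)
      colMeans(B[idx, , drop = FALSE])
    })
    want <- c("A", "B")[which.min(colSums((means - B[i, ])^2))]
    expect_identical(pred[i], want)
  }
})

test_that("degenerate clusters give perfect open-world accuracy", {
  X <- rbind(matrix(1, 3L, 4L), matrix(5, 3L, 4L))
  labs <- rep(c("A", "B"), each = 3L)
  pred <- DRENet:::.leaveOneOutMatch(X, labs, c("A", "B"))
  expect_identical(pred, labs)
})

test_that("open-world runs evaluate each test image exactly once", {
  runs <- openWorldResults()
  man <- phantomManifest()
  plan <- openWorldPlan(labels = CLS)
  for (res in runs) {
    expect_named(res$runs, names(plan@runs))
    for (nm in names(res$runs)) {
      testClasses <- plan@runs[[nm]]$test
      expect_equal(sum(counts(res$runs[[nm]]$confusion)),
                   sum(man$label %in% testClasses))
    }
  }
})

test_that("concat-layer features ignore the head weights", {
  model <- buildDRENet(cachedExtractor("resnet50_modified"),
                       cachedExtractor("densenet201_modified"))
  img <- phantomImages()[[3L]]
  f <- extractConcatFeatures(model, img)
  expect_identical(dim(f), c(1L, 3968L))
  set.seed(13)
  model2 <- buildDRENet(model@resnet, model@densenet,
                        scnHead(matrix(rnorm(4 * 3968), 4L), rnorm(4)))
  expect_identical(extractConcatFeatures(model2, img), f)
  expect_identical(extractConcatFeatures(model, img), f)
})
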