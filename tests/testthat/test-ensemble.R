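test_that("feature concatenation is ordered, injective and validated", {
  f1 <- as.numeric(seq_len(2048)); f2 <- as.numeric(-seq_len(1920))
  f <- concatFeatures(f1, f2)
  expect_length(f, 3968L)
  expect_identical(f[1:2048], as.numeric(f1))
  expect_identical(f[2049:3968], as.numeric(f2))
  expect_identical(concatFeatures(rep(0, 2048), rep(0, 1920)), rep(0, 3968))
  expect_error(concatFeatures(rep(0, 2047), rep(0, 1920)), "2048")

  # injectivity on random pairs
  set.seed(3)
  for (i in 1:10) {
    a <- list(rnorm(2048), rnorm(1920))
    b <- list(rnorm(2048), rnorm(1920))
    expect_false(identical(concatFeatures(a[[1]], a[[2]]),
                           concatFeatures(b[[1]], b[[2]])))
  }
})

test_that("the fully-connected layer matches a brute-force oracle", {
  h0 <- scnHead(matrix(0, 4, 6), bias = c(1, -2, 0.5, 0),
                classLabels = CLS, inputDim = 6L)
  expect_equal(unname(fclForward(rep(1, 6), h0)), c(1, -2, 0.5, 0))

  # selector rows pick out coordinates
  W <- matrix(0, 2, 4); W[1, 1] <- 1; W[2, 2] <- 1
  hs <- scnHead(W, classLabels = c("a", "b"), inputDim = 4L)
  expect_equal(unname(fclForward(c(1, 2, 9, 9), hs)), c(1, 2))

  set.seed(11)
  W <- matrix(rnorm(4 * 6), 4, 6); b <- rnorm(4)
  h <- scnHead(W, b, CLS, inputDim = 6L)
  f <- rnorm(6)
  want <- vapply(1:4, function(j) {
    acc <- b[j]
    for (l in 1:6) acc <- acc + W[j, l] * f[l]  # elementwise accumulation
    acc
  }, 0)
  expect_equal(unname(fclForward(f, h)), want, tolerance = 1e-12)
  expect_error(fclForward(c(1, NA, 1, 1, 1, 1), h), "finite")
})

test_that("softmax satisfies its closed forms and invariances", {
  u <- softmaxProbs(c(0, 0, 0, 0))
  expect_equal(unname(u@probabilities), rep(0.25, 4))
  expect_equal(unname(softmaxProbs(c(7, 7, 7, 7))@probabilities),
               rep(0.25, 4))

  p <- softmaxProbs(c(1, 0, 0, 0))
  expect_equal(unname(p@probabilities),
               c(exp(1) / (exp(1) + 3), rep(1 / (exp(1) + 3), 3)))

  set.seed(4)
  for (i in 1:25) {
    z <- rnorm(4, sd = 10)
    pr <- softmaxProbs(z)@probabilities
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-9)
    expect_equal(unname(pr),
                 unname(softmaxProbs(z + 123.45)@probabilities),
                 tolerance = 1e-12)
  }
  # argmax ties break toward the lowest index
  expect_identical(softmaxProbs(c(a = 1, b = 1, c = 0))@label, "a")
  expect_error(softmaxProbs(c(1, Inf)), "finite")
})

test_that("cross entropy matches its definition", {
  expect_equal(crossEntropy(c(C1 = 1, C2 = 0, C3 = 0, C4 = 0), "C1"), 0)
  expect_equal(crossEntropy(rep(0.25, 4), 2), log(4))

  set.seed(5)
  zs <- matrix(rnorm(40), 10, 4)
  batchMean <- mean(vapply(1:10, function(i)
    crossEntropy(softmaxProbs(zs[i, ]), sample(4, 1)), 0))
  # independent per-sample loop oracle
  set.seed(5)
  zs2 <- matrix(rnorm(40), 10, 4)
  acc <- 0
  for (i in 1:10) {
    e <- exp(zs2[i, ] - max(zs2[i, ])); p <- e / sum(e)
    acc <- acc - log(p[sample(4, 1)])
  }
  expect_equal(batchMean, acc / 10, tolerance = 1e-10)

  # CE >= 0 with equality only at certainty
  expect_gt(crossEntropy(c(0.99, 0.01, 0, 0), 1), 0)
})

test_that("assembled DRE-Net predicts deterministically", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  model <- buildDRENet(rn, dn)     # zero-weight head
  expect_identical(featureDim(model), 3968L)
  expect_identical(classLabels(model),
                   c("Cofield", "Depuy", "Tornier", "Zimmer"))

  img <- phantomImages()[[5L]]
  p1 <- predictClasses(model, img)
  expect_s4_class(p1, "ClassProbabilities")
  expect_equal(unname(p1@probabilities), rep(0.25, 4))  # zero-weight head
  p2 <- predictClasses(model, img)
  expect_identical(p1@probabilities, p2@probabilities)

  # head input dimension is validated
  expect_error(buildDRENet(rn, dn, scnHead(inputDim = 100L)), "3968")
})

test_that("model bundles round-trip through disk", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  set.seed(8)
  head <- scnHead(matrix(rnorm(4 * 3968), 4), rnorm(4))
  model <- buildDRENet(rn, dn, head)
  dir <- file.path(tempdir(), "bundle")
  saveDRENet(model, dir)
  back <- loadDRENet(dir)
  expect_equal(back@head@weights, model@head@weights)
  expect_equal(back@resnet@params$rn.conv1.W, rn@params$rn.conv1.W)
  img <- phantomImages()[[2L]]
  expect_identical(predictClasses(back, img)@probabilities,
                   predictClasses(model, img)@probabilities)
})
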