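test_that("feature dimensions and stage shapes match the architectures", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  expect_identical(featureDim(rn), 2048L)
  expect_identical(featureDim(dn), 1920L)

  rnWant <- data.frame(
    stage = c("Image Input", "Conv 1", "Max Pooling", "Conv 2_x",
              "Conv 3_x", "Conv 4_x", "Conv 5_x", "Average Pooling"),
    height = c(224L, 112L, 56L, 56L, 28L, 14L, 7L, 1L),
    width = c(224L, 112L, 56L, 56L, 28L, 14L, 7L, 1L),
    channels = c(3L, 64L, 64L, 256L, 512L, 1024L, 2048L, 2048L))
  expect_equal(stageShapes(rn), rnWant, ignore_attr = TRUE)

  dnWant <- data.frame(
    stage = c("Image Input", "Conv 1", "Max Pooling", "DenseBlock_1",
              "Transition_1", "DenseBlock_2", "Transition_2",
              "DenseBlock_3", "Transition_3", "DenseBlock_4",
              "Average Pooling"),
    height = c(224L, 112L, 56L, 56L, 28L, 28L, 14L, 14L, 7L, 7L, 1L),
    width = c(224L, 112L, 56L, 56L, 28L, 28L, 14L, 14L, 7L, 7L, 1L),
    channels = c(3L, 64L, 64L, 256L, 128L, 512L, 256L, 1792L, 896L, 1920L,
                 1920L))
  expect_equal(stageShapes(dn), dnWant, ignore_attr = TRUE)

  expect_error(buildExtractor("vgg16"))
  expect_error(buildExtractor("resnet50_modified", pretrained = TRUE),
               "weightsFile")
})

test_that("extraction is deterministic and batch-invariant", {
  rn <- cachedExtractor("resnet50_modified")
  imgs <- phantomImages()[c(1L, 31L)]
  f1 <- extractFeatures(rn, imgs[[1L]])
  expect_identical(dim(f1), c(1L, 2048L))
  fBatch <- extractFeatures(rn, imgs)
  expect_lt(max(abs(fBatch[1L, ] - f1[1L, ])), 1e-5)
  expect_identical(extractFeatures(rn, imgs[[1L]]), f1)
  expect_true(all(is.finite(f1)))
})

test_that("random initialization is seed-reproducible and seed-sensitive", {
  a <- buildExtractor("resnet50_modified", seed = 9L)
  b <- buildExtractor("resnet50_modified", seed = 9L)
  expect_identical(a@params, b@params)
  c_ <- buildExtractor("resnet50_modified", seed = 10L)
  expect_false(identical(a@params$rn.conv1.W, c_@params$rn.conv1.W))
})

test_that("temporary head behaves like a softmax classifier", {
  rn <- cachedExtractor("resnet50_modified")
  expect_error(attachTempHead(rn, 1L), ">= 2")
  clf <- attachTempHead(rn, 4L, seed = 2L)
  img <- phantomImages()[[1L]]

  # zeroed head weights and bias give uniform probabilities
  clf0 <- clf
  clf0$headW[] <- 0
  p <- tempHeadPredict(clf0, img)
  expect_equal(as.vector(p), rep(0.25, 4L), tolerance = 1e-7)

  # detaching returns the extractor with untouched parameters
  expect_identical(detachHead(clf)@params, rn@params)
})

test_that("activation maps are normalized and focus on the implant", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")

  img <- renderPhantom(phantomSpec("C4", seed = 1L))
  m <- blockActivationMap(dn, img, "DenseBlock_2")
  expect_identical(dim(m), c(224L, 224L))
  expect_gte(min(m), 0)
  expect_lte(max(m), 1)
  expect_error(blockActivationMap(dn, img, "Conv 9_x"), "DenseBlock_1")
  expect_length(activationStages(dn), 5L)
  expect_length(activationStages(rn), 5L)

  # bright implant on black background: final-stage peak inside the implant
  for (cl in c("C1", "C2", "C4")) for (s in 1:2) {
    sp <- phantomSpec(cl, seed = s, noiseSd = 0,
                      backgroundGradient = c(0, 0))
    ph <- renderPhantom(sp, returnMask = TRUE)
    b <- attr(ph, "bbox")
    mm <- blockActivationMap(rn, ph, "Conv 5_x")
    am <- which(mm == max(mm), arr.ind = TRUE)[1L, ]
    expect_true(am[1L] >= b[1L] && am[1L] <= b[2L] &&
                  am[2L] >= b[3L] && am[2L] <= b[4L],
                label = sprintf("activation peak inside bbox (%s, seed %d)",
                                cl, s))
  }
})
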