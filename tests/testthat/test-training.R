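test_that("train/validation split is stratified, seeded and exhaustive", {
  man <- data.frame(path = sprintf("p%03d", 1:100),
                    label = rep(CLS, 25), split = "train")
  sp <- splitTrainValidation(man, 0.25, seed = 3L)
  expect_equal(nrow(sp$train), 75L)
  expect_equal(nrow(sp$validation), 25L)
  expect_length(intersect(sp$train$path, sp$validation$path), 0L)
  expect_setequal(c(sp$train$path, sp$validation$path), man$path)

  man2 <- data.frame(label = rep(CLS, each = 40))
  sp2 <- splitTrainValidation(man2, 0.25, seed = 1L)
  expect_equal(as.vector(table(sp2$train$label)), rep(30L, 4))
  expect_equal(as.vector(table(sp2$validation$label)), rep(10L, 4))

  expect_identical(splitTrainValidation(man, 0.25, seed = 9L),
                   splitTrainValidation(man, 0.25, seed = 9L))
  expect_warning(splitTrainValidation(data.frame(label = c("C1", "C2", "C2")),
                                      0.5, 1L), "fewer than 2")
})

test_that("the momentum SGD step follows its recurrence", {
  cfg <- trainConfig(learningRate = 0.1, momentum = 0, l2 = 0)
  # loss w^2 at w = 1: gradient 2, step to 0.8
  st <- sgdStep(1, 2, NULL, cfg)
  expect_equal(st$parameters, 0.8)

  # zero gradient, zero velocity: fixed point
  st0 <- sgdStep(c(1, 2), c(0, 0), NULL, cfg)
  expect_equal(st0$parameters, c(1, 2))

  # lr -> 0 leaves parameters unchanged for any number of steps
  stz <- sgdStep(c(1, 2), c(5, -3), NULL, cfg, lr = 0)
  expect_equal(stz$parameters, c(1, 2))

  # two momentum steps on a 2-D quadratic vs an explicit recurrence
  cfg2 <- trainConfig(learningRate = 0.1, momentum = 0.9, l2 = 0)
  w <- c(1, -2); st <- NULL
  for (i in 1:2) {
    upd <- sgdStep(w, c(2 * w[1], 6 * w[2]), st, cfg2)
    w <- upd$parameters; st <- upd$state
  }
  vv <- c(0, 0); ww <- c(1, -2)
  for (i in 1:2) {
    vv <- 0.9 * vv - 0.1 * c(2 * ww[1], 6 * ww[2])
    ww <- ww + vv
  }
  expect_equal(w, ww, tolerance = 1e-12)

  expect_error(sgdStep(1, NaN, NULL, cfg), "parameter block")
})

test_that("SCN training separates high-margin feature clusters", {
  set.seed(42)
  mu <- matrix(0, 4, 3968)
  for (k in 1:4) mu[k, ((k - 1) * 900 + 1):((k - 1) * 900 + 900)] <- 5
  X <- mu[rep(1:4, each = 10), ] + matrix(rnorm(40 * 3968, 0, 0.5), 40)
  lab <- rep(CLS, each = 10)
  res <- trainSCN(X, lab, trainConfig(seed = 1L))
  z <- X %*% t(res$head@weights) +
    matrix(res$head@bias, 40, 4, byrow = TRUE)
  expect_equal(mean(CLS[max.col(z, ties.method = "first")] == lab), 1)
  # 9 epochs x 4 mini-batches of 10
  expect_equal(nrow(res$trace), 36L)
  expect_equal(max(res$trace$epoch), 9L)
})

test_that("sequential stage 3 never touches backbone parameters", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  imgs <- phantomImages()[c(1L, 31L, 61L, 91L)]
  labs <- CLS
  cfg <- trainConfig(epochsBackbone = 0L, epochsSCN = 2L, minibatch = 2L,
                     seed = 3L)
  fit <- trainSequential(config = cfg, resnet = rn, densenet = dn,
                         images = imgs, labels = labs)
  expect_identical(fit$model@resnet@params, rn@params)
  expect_identical(fit$model@densenet@params, dn@params)
  expect_s4_class(fit$model, "DRENet")
})

test_that("backbone fine-tuning updates the extractors", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  imgs <- phantomImages()[c(1L, 61L)]
  cfg <- trainConfig(epochsBackbone = 1L, epochsSCN = 1L, minibatch = 2L,
                     seed = 3L)
  fit <- trainSequential(config = cfg, resnet = rn, densenet = dn,
                         images = imgs, labels = c("C1", "C3"),
                         classLabels = CLS)
  expect_false(identical(fit$model@resnet@params$rn.conv1.W,
                         rn@params$rn.conv1.W))
  expect_false(identical(fit$model@densenet@params$dn.conv1.W,
                         dn@params$dn.conv1.W))
  expect_true(all(vapply(fit$model@resnet@params,
                         function(p) all(is.finite(p)), TRUE)))
})

test_that("end-to-end training reaches both extractors and is reproducible", {
  rn <- cachedExtractor("resnet50_modified")
  dn <- cachedExtractor("densenet201_modified")
  imgs <- phantomImages()[c(1L, 31L)]
  cfg <- trainConfig("end_to_end", epochsEndToEnd = 1L, minibatch = 2L,
                     seed = 4L)
  e1 <- trainEndToEnd(config = cfg, resnet = rn, densenet = dn,
                      images = imgs, labels = c("C1", "C2"),
                      classLabels = CLS)
  # gradient flows into both extractors after one step
  expect_false(identical(e1$model@resnet@params$rn.conv1.W,
                         rn@params$rn.conv1.W))
  expect_false(identical(e1$model@densenet@params$dn.conv1.W,
                         dn@params$dn.conv1.W))
  e2 <- trainEndToEnd(config = cfg, resnet = rn, densenet = dn,
                      images = imgs, labels = c("C1", "C2"),
                      classLabels = CLS)
  expect_identical(e1$model@head@weights, e2$model@head@weights)
  expect_equal(nrow(e1$trace), 1L)
})

test_that("SCN training loss decreases on the reduced synthetic problem", {
  # epoch-smoothed loss over the first epochs, median across 3 seeds
  tr <- closedWorldResults()  # ensures features exist
  cache <- sharedFeatureCache()
  man <- phantomManifest()
  feats <- t(vapply(man$path, function(p) cache[[paste0(p, "|0")]],
                    numeric(3968L)))
  ok <- vapply(1:3, function(s) {
    res <- trainSCN(feats, man$label, trainConfig(seed = 20L + s))
    byEpoch <- tapply(res$trace$loss, res$trace$epoch, mean)
    # non-increasing within a small stochastic tolerance, and an overall
    # decrease from the first to the last epoch
    all(diff(byEpoch) <= 0.05 * byEpoch[[1L]]) &&
      byEpoch[[length(byEpoch)]] < byEpoch[[1L]]
  }, TRUE)
  expect_gte(median(ok), 1)
})
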