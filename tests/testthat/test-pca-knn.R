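test_that("PCA matches an explicit covariance eigendecomposition", {
  # rank-1 data on the line y = 2x
  x <- seq(-2, 2, length.out = 9)
  lineData <- cbind(x, 2 * x)
  mLine <- pcaFit(lineData)
  expect_equal(mLine@eigenvalues[2L], 0, tolerance = 1e-12)
  expect_equal(mLine@eigenvalues[1L],
               sum(apply(lineData, 2L, stats::var)), tolerance = 1e-10)

  set.seed(14)
  X <- matrix(rnorm(15), 5L, 3L)
  m <- pcaFit(X)
  # independent oracle: explicitly form the covariance and eigendecompose
  Xc <- sweep(X, 2L, colMeans(X))
  C <- t(Xc) %*% Xc / (nrow(X) - 1L)
  eig <- eigen(C, symmetric = TRUE)
  expect_equal(m@eigenvalues, eig$values[1:3], tolerance = 1e-8)
  for (j in 1:3) {
    v <- eig$vectors[, j]
    nz <- which(abs(v) > 1e-12)[1L]
    if (v[nz] < 0) v <- -v
    expect_equal(m@rotation[, j], v, tolerance = 1e-8)
  }
  # orthonormality and the fixed sign convention make refits identical
  expect_lt(max(abs(t(m@rotation) %*% m@rotation - diag(3L))), 1e-8)
  expect_identical(m@rotation, pcaFit(X)@rotation)
  expect_error(pcaFit(X[1L, , drop = FALSE]), "at least 2")
})

test_that("projection is centred and isometric at full rank", {
  set.seed(15)
  X <- matrix(rnorm(60), 12L, 5L)
  m <- pcaFit(X)
  P <- pcaProject(m, X, 5L)
  expect_equal(as.vector(stats::dist(P)), as.vector(stats::dist(X)),
               tolerance = 1e-8)
  expect_equal(as.vector(pcaProject(m, colMeans(X), 5L)), rep(0, 5L),
               tolerance = 1e-10)
  expect_error(pcaProject(m, X, 6L), "lambda")

  # reconstruction error is non-increasing in lambda, and eigenvalues sum
  # to the total variance
  Xc <- sweep(X, 2L, colMeans(X))
  errs <- vapply(1:5, function(l) {
    R <- pcaProject(m, X, l) %*% t(m@rotation[, 1:l, drop = FALSE])
    sum((Xc - R)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-8))
  expect_equal(sum(m@eigenvalues), sum(apply(X, 2L, stats::var)),
               tolerance = 1e-6)

  # a 3968-d feature vector reduces to the requested dimension
  set.seed(16)
  F12 <- matrix(rnorm(12 * 3968), 12L)
  m12 <- pcaFit(F12)
  expect_identical(dim(pcaProject(m12, F12[1L, ], 10L)), c(1L, 10L))
})

test_that("KNN agrees with an exhaustive search oracle", {
  train <- rbind(c(0, 0), c(1, 0), c(1.1, 0), c(5, 5))
  labs <- c("A", "A", "B", "B")
  expect_identical(knnClassify(train, labs, c(1, 0), k = 1L), "A")
  expect_identical(knnClassify(train, labs, c(1.04, 0), k = 3L), "A")
  expect_error(knnClassify(train, labs, c(0, 0), k = 5L), "exceeds")

  set.seed(17)
  tr <- matrix(rnorm(80), 20L, 4L)
  trLab <- sample(CLS, 20L, replace = TRUE)
  qs <- matrix(rnorm(40), 10L, 4L)
  for (k in c(1L, 3L, 5L)) {
    got <- knnClassify(tr, trLab, qs, k)
    for (i in 1:10) {
      d <- vapply(1:20, function(j) sum((tr[j, ] - qs[i, ])^2), 0)
      nb <- order(d)[1:k]
      votes <- table(factor(trLab[nb], sort(unique(trLab))))
      expect_identical(got[i], names(votes)[which.max(votes)])
    }
  }
  # K = 1 reproduces the training labels on distinct points
  expect_identical(knnClassify(tr, trLab, tr, 1L), trLab)
})

test_that("the eigenvector sweep finds low-dimensional structure", {
  set.seed(18)
  B <- qr.Q(qr(matrix(rnorm(30 * 4), 30L, 4L)))
  centers <- matrix(rnorm(16, sd = 4), 4L)
  X <- (centers[rep(1:4, each = 15L), ] +
          matrix(rnorm(60 * 4, 0, 0.3), 60L)) %*% t(B) +
    matrix(rnorm(60 * 30, 0, 0.2), 60L)
  labs <- rep(CLS, each = 15L)
  sw <- lambdaSweep(X, labs, lambdas = 1:15, folds = 3L, seed = 2L)
  expect_lte(sw$bestLambda, 10L)
  # accuracy plateaus beyond the intrinsic dimension
  expect_equal(sw$curve$meanAccuracy[10L], sw$curve$meanAccuracy[15L],
               tolerance = 2)
  expect_gte(max(sw$curve$meanAccuracy), 95)

  expect_identical(lambdaSweep(X, labs, lambdas = 5L, folds = 3L,
                               seed = 1L)$bestLambda, 5L)
  expect_identical(lambdaSweep(X, labs, lambdas = 1:8, folds = 3L,
                               seed = 3L)$curve,
                   lambdaSweep(X, labs, lambdas = 1:8, folds = 3L,
                               seed = 3L)$curve)
})
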