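# Feature-space ablation: PCA of the concatenation-layer features with an
# eigenvector-count sweep, followed by a K-nearest-neighbour classifier
# (default K = 1; the smallest assumption, configurable).

#' Fit a PCA model on training features
#'
#' Features are centred by the training mean and decomposed by SVD
#' (equivalent to an eigendecomposition of the training covariance with
#' denominator N-1). Components are ordered by non-increasing eigenvalue
#' and each eigenvector's sign is fixed so its first non-zero coordinate is
#' positive.
#'
#' @param features N x D matrix, N >= 2.
#' @return a [PCAModel] with `min(N - 1, D)` components.
#' @export
pcaFit <- function(features) {
  if (nrow(features) < 2L) stop("PCA requires at least 2 samples")
  pr <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(nrow(features) - 1L, ncol(features)))
  rot <- pr$rotation[, keep, drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    nz <- which(abs(rot[, j]) > 1e-12)
    if (length(nz) > 0 && rot[nz[1L], j] < 0) rot[, j] <- -rot[, j]
  }
  new("PCAModel", center = unname(pr$center), rotation = unname(rot),
      eigenvalues = unname(pr$sdev[keep]^2))
}

#' Project features onto the top eigenvectors
#'
#' @param model a [PCAModel].
#' @param features N x D matrix (or a single length-D vector).
#' @param lambda number of leading eigenvectors to keep
#'   (1 <= lambda <= available components).
#' @return N x lambda matrix of projections of the centred features.
#' @export
pcaProject <- function(model, features, lambda) {
  if (is.null(dim(features))) features <- matrix(features, 1L)
  if (lambda < 1L || lambda > ncol(model@rotation))
    stop("lambda must lie in 1..", ncol(model@rotation))
  sweep(features, 2L, model@center) %*%
    model@rotation[, seq_len(lambda), drop = FALSE]
}

#' K-nearest-neighbour classification
#'
#' Euclidean-distance KNN with deterministic tie handling: neighbour
#' distance ties prefer the earlier training point, vote ties prefer the
#' lowest label in sort order.
#'
#' @param train N x d matrix of training points.
#' @param labels length-N training labels.
#' @param queries M x d matrix (or single vector).
#' @param k neighbourhood size (default 1; must not exceed N).
#' @return character vector of M predicted labels.
#' @export
knnClassify <- function(train, labels, queries, k = 1L) {
  if (is.null(dim(queries))) queries <- matrix(queries, 1L)
  n <- nrow(train)
  if (n == 0L) stop("empty training set")
  if (k > n) stop("k (", k, ") exceeds the training size (", n, ")")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  out <- character(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    d2 <- rowSums(sweep(train, 2L, queries[i, ])^2)
    nb <- order(d2)[seq_len(k)]   # order() is stable: earlier point wins ties
    votes <- table(factor(labels[nb], lev))
    out[i] <- lev[which.max(votes)]
  }
  out
}

#' Eigenvector-count sweep for the PCA + KNN baseline
#'
#' Scores each candidate lambda by seeded stratified k-fold cross-validated
#' KNN accuracy computed on the training features only (PCA refit on each
#' fold's training portion, so no fold sees its own test points in the
#' eigenbasis). The best lambda is the argmax; ties break toward the
#' smallest lambda.
#'
#' @param features N x D training feature matrix.
#' @param labels length-N labels.
#' @param lambdas candidate eigenvector counts (default 1..100).
#' @param folds number of cross-validation folds.
#' @param k KNN neighbourhood size.
#' @param seed integer seed for the fold assignment.
#' @return list: `curve` (data.frame lambda/meanAccuracy), `bestLambda`.
#' @export
lambdaSweep <- function(features, labels, lambdas = 1:100, folds = 5L,
                        k = 1L, seed = 1L) {
  labels <- as.character(labels)
  plan <- stratifiedKFold(labels, folds, seed)
  maxLambda <- max(lambdas)
  acc <- matrix(NA_real_, length(lambdas), folds)
  for (fold in seq_len(folds)) {
    fi <- foldIndices(plan, fold)
    model <- pcaFit(features[fi$train, , drop = FALSE])
    avail <- ncol(model@rotation)
    if (maxLambda > avail)
      stop("lambda range exceeds available components (", avail, ")")
    ptr <- pcaProject(model, features[fi$train, , drop = FALSE], maxLambda)
    pte <- pcaProject(model, features[fi$test, , drop = FALSE], maxLambda)
    for (li in seq_along(lambdas)) {
      lam <- lambdas[li]
      pred <- knnClassify(ptr[, seq_len(lam), drop = FALSE],
                          labels[fi$train],
                          pte[, seq_len(lam), drop = FALSE], k)
      acc[li, fold] <- mean(pred == labels[fi$test])
    }
  }
  curve <- data.frame(lambda = lambdas, meanAccuracy = rowMeans(acc) * 100)
  list(curve = curve,
       bestLambda = lambdas[which.max(curve$meanAccuracy)])
}
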