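# Closed-world protocol: stratified 10-fold cross-validation, confusion
# matrices, macro metrics, and the pooled paired t-test for comparing two
# methods across folds.

#' Stratified k-fold assignment
#'
#' Within each class, samples are shuffled (seeded) and dealt into k folds
#' of near-equal size; remainder samples go to the earliest folds, so fold
#' sizes within a class differ by at most 1.
#'
#' @param labels per-sample class labels (or a manifest data.frame with a
#'   `label` column).
#' @param k number of folds (default 10).
#' @param seed integer seed.
#' @return a [FoldPlan].
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.character(labels)
  n <- length(labels)
  foldId <- integer(n)
  .withSeed(seed, for (lb in unique(labels)) {
    idx <- which(labels == lb)
    if (length(idx) < k)
      warning("class ", lb, " has fewer samples (", length(idx),
              ") than folds (", k, "): some folds will lack it")
    perm <- sample(idx)
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
    foldId[perm] <- rep(seq_len(k), sizes)
  })
  new("FoldPlan", k = as.integer(k), foldId = foldId, labels = labels)
}

#' @rdname stratifiedKFold
#' @param plan a [FoldPlan].
#' @param fold fold index.
#' @return `foldSizes`: class-by-fold count table; `foldIndices`: list with
#'   `train` and `test` row indices for one fold.
#' @export
foldSizes <- function(plan) table(plan@labels, plan@foldId)

#' @rdname stratifiedKFold
#' @export
foldIndices <- function(plan, fold) {
  stopifnot(fold >= 1L, fold <= plan@k)
  list(train = which(plan@foldId != fold), test = which(plan@foldId == fold))
}

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d samples in %d folds\n", length(object@foldId),
              object@k))
  print(foldSizes(object))
})

#' Confusion matrix from predictions
#'
#' @param predicted,truth equal-length label vectors.
#' @param labels ordered label set; both inputs must draw from it.
#' @return a [ConfusionMatrix] (true classes in rows, predicted in columns).
#' @export
confusionMatrix <- function(predicted, truth, labels = NULL) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(length(predicted) == length(truth))
  labels <- labels %||% sort(unique(c(predicted, truth)))
  bad <- setdiff(unique(c(predicted, truth)), labels)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  m <- table(factor(truth, labels), factor(predicted, labels))
  cm <- matrix(as.integer(m), nrow(m), ncol(m),
               dimnames = list(labels, labels))
  new("ConfusionMatrix", counts = cm)
}

#' @rdname confusionMatrix
#' @param object a [ConfusionMatrix].
#' @export
setMethod("counts", "ConfusionMatrix", function(object) object@counts)

#' Per-class TP/FP/FN/TN of a confusion matrix
#' @param cm a [ConfusionMatrix].
#' @return data.frame with one row per class.
#' @export
classCounts <- function(cm) {
  m <- counts(cm)
  total <- sum(m)
  tp <- diag(m)
  fp <- colSums(m) - tp
  fn <- rowSums(m) - tp
  tn <- total - tp - fp - fn
  data.frame(class = rownames(m), TP = tp, FP = fp, FN = fn, TN = tn,
             row.names = NULL)
}

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix (rows = truth, columns = predicted)\n")
  print(object@counts)
})

#' Macro classification metrics
#'
#' Precision is the macro mean of per-class `TP/(TP+FP)`. Two documented
#' modes exist for accuracy and recall:
#' \itemize{
#' \item `accuracyMode = "overall"` (default): `trace/total`, the fraction
#'   of correctly classified samples. `"eq4_literal"` instead averages the
#'   per-class one-vs-rest binary accuracies
#'   `(TP+TN)/(TP+TN+FP+FN)` over classes.
#' \item `recallMode = "standard"` (default): macro mean of `TP/(TP+FN)`.
#'   `"eq7_literal"` computes `TP/(TP+TN)` instead, preserving a printed
#'   formula variant for auditability; it is not a recall in the usual
#'   sense.
#' }
#' The F1-score is always `2*precision*recall/(precision+recall)` from the
#' report's own macro precision and recall. Per-class terms with a zero
#' denominator contribute 0 (with a warning). All values are percentages.
#'
#' @param cm a [ConfusionMatrix].
#' @param accuracyMode,recallMode see above.
#' @return a [MetricsReport].
#' @export
metricsReport <- function(cm, accuracyMode = c("overall", "eq4_literal"),
                          recallMode = c("standard", "eq7_literal")) {
  accuracyMode <- match.arg(accuracyMode)
  recallMode <- match.arg(recallMode)
  cc <- classCounts(cm)
  total <- sum(counts(cm))
  if (total == 0) stop("empty confusion matrix")
  safeDiv <- function(num, den, what) {
    bad <- den == 0
    if (any(bad))
      warning("zero denominator for class(es) ",
              paste(cc$class[bad], collapse = ", "), " in ", what,
              "; contributing 0")
    out <- ifelse(bad, 0, num / den)
    out
  }
  precision <- mean(safeDiv(cc$TP, cc$TP + cc$FP, "precision")) * 100
  recall <- switch(recallMode,
    standard = mean(safeDiv(cc$TP, cc$TP + cc$FN, "recall")) * 100,
    eq7_literal = mean(safeDiv(cc$TP, cc$TP + cc$TN, "recall")) * 100)
  accuracy <- switch(accuracyMode,
    overall = sum(diag(counts(cm))) / total * 100,
    eq4_literal = mean((cc$TP + cc$TN) /
                         (cc$TP + cc$TN + cc$FP + cc$FN)) * 100)
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  new("MetricsReport", accuracy = accuracy, f1 = f1, precision = precision,
      recall = recall, accuracyMode = accuracyMode, recallMode = recallMode)
}

#' @rdname metricsReport
#' @param report a [MetricsReport].
#' @return `metricsVector`: named numeric vector (accuracy, f1, precision,
#'   recall).
#' @export
metricsVector <- function(report) {
  c(accuracy = report@accuracy, f1 = report@f1,
    precision = report@precision, recall = report@recall)
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf(paste0("MetricsReport (accuracy mode %s, recall mode %s)\n",
                     "  accuracy %.2f%%  F1 %.2f%%  precision %.2f%%  ",
                     "recall %.2f%%\n"),
              object@accuracyMode, object@recallMode, object@accuracy,
              object@f1, object@precision, object@recall))
})

#' Closed-world k-fold evaluation
#'
#' For each fold: the training portion is (optionally) RIA-expanded, a
#' DRE-Net is trained per the configuration, and the untouched test portion
#' is classified. Per-fold metrics, their means and the summed confusion
#' matrix are returned.
#'
#' With `config$epochsBackbone == 0` the supplied backbones stay frozen
#' (feature extraction only, the SCN head is trained per fold); in that
#' reduced protocol features are computed once per distinct image and
#' reused across folds via `featureCache`.
#'
#' @param manifest dataset manifest (`path`, `label`); images on disk, or
#'   pass `images` (list of arrays, same order as manifest rows).
#' @param config a [trainConfig()].
#' @param k number of folds.
#' @param seed seed for the fold assignment (training seeds derive from it).
#' @param resnet,densenet backbones used as the starting point of every
#'   fold.
#' @param ria apply rotational invariant augmentation to each fold's
#'   training portion (`policy`); test images are never augmented.
#' @param policy RIA [rotationPolicy()].
#' @param images optional in-memory images.
#' @param featureCache optional environment caching features keyed by
#'   `path|angle` (frozen-backbone protocol only).
#' @param classLabels ordered label set.
#' @return list: `folds` (per-fold [MetricsReport]s), `mean` (named vector
#'   of mean metrics), `confusion` (summed [ConfusionMatrix]), `plan`.
#' @export
runClosedWorld <- function(manifest, config = trainConfig(), k = 10L,
                           seed = 1L,
                           resnet = buildExtractor("resnet50_modified"),
                           densenet = buildExtractor("densenet201_modified"),
                           ria = TRUE, policy = rotationPolicy(),
                           images = NULL, featureCache = NULL,
                           classLabels = NULL) {
  classLabels <- classLabels %||% sort(unique(as.character(manifest$label)))
  plan <- stratifiedKFold(manifest$label, k, seed)
  if (is.null(images)) images <- .loadImages(manifest)
  frozen <- config$epochsBackbone == 0L && config$regime == "sequential"
  if (frozen && is.null(featureCache)) featureCache <- new.env()
  reports <- vector("list", k)
  cmSum <- NULL
  for (fold in seq_len(k)) {
    fi <- foldIndices(plan, fold)
    predicted <- if (frozen) {
      .closedWorldFoldFrozen(manifest, images, fi, config, resnet, densenet,
                             ria, policy, featureCache, classLabels)
    } else {
      .closedWorldFoldFull(manifest, images, fi, config, resnet, densenet,
                           ria, policy, classLabels)
    }
    cm <- confusionMatrix(predicted, manifest$label[fi$test], classLabels)
    cmSum <- if (is.null(cmSum)) counts(cm) else cmSum + counts(cm)
    reports[[fold]] <- metricsReport(cm)
  }
  means <- colMeans(do.call(rbind, lapply(reports, metricsVector)))
  list(folds = reports, mean = means,
       confusion = new("ConfusionMatrix", counts = cmSum), plan = plan)
}

.cachedFeature <- function(cache, key, compute) {
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  v <- compute()
  if (!is.null(cache)) cache[[key]] <- v
  v
}

.concatFeatureRows <- function(manifest, images, idx, resnet, densenet,
                               cache, angles = 0) {
  rows <- list()
  for (i in idx) {
    for (a in angles) {
      key <- paste0(manifest$path[i], "|", a)
      rows[[length(rows) + 1L]] <- list(
        f = .cachedFeature(cache, key, function() {
          img <- if (a == 0) images[[i]]
                 else rotateImage(images[[i]], a)
          concatFeatures(extractFeatures(resnet, img),
                         extractFeatures(densenet, img))[1L, ]
        }),
        label = manifest$label[i])
    }
  }
  list(features = do.call(rbind, lapply(rows, `[[`, "f")),
       labels = vapply(rows, `[[`, "", "label"))
}

.closedWorldFoldFrozen <- function(manifest, images, fi, config, resnet,
                                   densenet, ria, policy, cache,
                                   classLabels) {
  angles <- if (ria) policy@anglesDeg else 0
  tr <- .concatFeatureRows(manifest, images, fi$train, resnet, densenet,
                           cache, angles)
  te <- .concatFeatureRows(manifest, images, fi$test, resnet, densenet,
                           cache, 0)
  scn <- trainSCN(tr$features, tr$labels, config, classLabels = classLabels)
  z <- te$features %*% t(scn$head@weights) +
    matrix(scn$head@bias, nrow(te$features), length(classLabels),
           byrow = TRUE)
  classLabels[max.col(z, ties.method = "first")]
}

.closedWorldFoldFull <- function(manifest, images, fi, config, resnet,
                                 densenet, ria, policy, classLabels) {
  trImgs <- images[fi$train]
  trLabels <- manifest$label[fi$train]
  if (ria) {
    trImgs <- riaExpand(trImgs, policy)
    trLabels <- rep(trLabels, each = length(policy@anglesDeg))
  }
  fit <- if (config$regime == "end_to_end")
    trainEndToEnd(config = config, resnet = resnet, densenet = densenet,
                  images = trImgs, labels = trLabels,
                  classLabels = classLabels)
  else
    trainSequential(config = config, resnet = resnet, densenet = densenet,
                    images = trImgs, labels = trLabels,
                    classLabels = classLabels)
  pred <- predictClasses(fit$model, images[fi$test])
  pred$label
}

#' Pooled paired t-test across folds
#'
#' Pools the four metrics (accuracy, F1, precision, recall) over the k folds
#' of two methods into k*4 paired values and performs a two-tailed paired
#' t-test. Degenerate cases: all differences zero gives p = 1; constant
#' non-zero differences (zero variance) give p = 0 (|t| unbounded; reported
#' as below machine precision).
#'
#' @param reportsA,reportsB equal-length lists of [MetricsReport]s.
#' @return list: `p.value`, `statistic`, `df`.
#' @export
pooledPairedTTest <- function(reportsA, reportsB) {
  stopifnot(length(reportsA) == length(reportsB))
  a <- unlist(lapply(reportsA, metricsVector))
  b <- unlist(lapply(reportsB, metricsVector))
  d <- a - b
  if (stats::sd(d) == 0) {
    if (all(d == 0))
      return(list(p.value = 1, statistic = 0, df = length(d) - 1L))
    return(list(p.value = 0, statistic = sign(mean(d)) * Inf,
                df = length(d) - 1L))
  }
  tt <- stats::t.test(a, b, paired = TRUE, alternative = "two.sided")
  list(p.value = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter))
}
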