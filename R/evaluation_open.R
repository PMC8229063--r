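# Open-world protocol: train on one pair of manufacturers, identify images
# of the other (unseen) pair by L2 nearest-class-mean matching of
# concatenation-layer features. New classes are registered by storing a mean
# feature vector -- no retraining.

#' Extract concatenation-layer features
#'
#' The 3968-d feature vector of each image taken at the SCN's concatenation
#' layer (before the fully-connected layer, so the head weights are unused).
#'
#' @param model a [DRENet].
#' @param images single array or list of arrays (0-255).
#' @return N x 3968 matrix.
#' @export
extractConcatFeatures <- function(model, images) {
  stopifnot(is(model, "DRENet"))
  if (is.array(images)) images <- list(images)
  concatFeatures(extractFeatures(model@resnet, images),
                 extractFeatures(model@densenet, images))
}

#' Build a reference gallery of class mean features
#'
#' @param features N x D matrix.
#' @param labels length-N labels; every group must be non-empty.
#' @return a [ReferenceGallery] of per-class arithmetic mean vectors.
#' @export
buildGallery <- function(features, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  means <- sapply(lev, function(lb)
    colMeans(features[labels == lb, , drop = FALSE]))
  new("ReferenceGallery", means = means,
      counts = as.integer(table(labels)[lev]))
}

#' @rdname buildGallery
#' @param gallery a [ReferenceGallery].
#' @return `galleryLabels`: registered class labels in registration order.
#' @export
galleryLabels <- function(gallery) colnames(gallery@means)

setMethod("show", "ReferenceGallery", function(object) {
  cat(sprintf("ReferenceGallery: %d classes, feature dimension %d\n",
              ncol(object@means), nrow(object@means)))
  print(stats::setNames(object@counts, galleryLabels(object)))
})

#' Match a query feature vector against a gallery
#'
#' Returns the label of the gallery mean with the smallest Euclidean (L2)
#' distance; ties break toward the earliest registered label.
#'
#' @param query length-D feature vector.
#' @param gallery a [ReferenceGallery].
#' @return matched class label.
#' @export
matchGallery <- function(query, gallery) {
  if (length(query) != nrow(gallery@means))
    stop("query length ", length(query), " does not match gallery dimension ",
         nrow(gallery@means))
  d2 <- colSums((gallery@means - query)^2)
  galleryLabels(gallery)[which.min(d2)]
}

#' Register a new class in a gallery
#'
#' Adds the mean of the enrollment vectors under a new label. No retraining
#' happens and existing means are untouched.
#'
#' @param gallery a [ReferenceGallery].
#' @param label new class label.
#' @param vectors matrix (rows = enrollment feature vectors) or one vector.
#' @param overwrite allow replacing an existing label.
#' @return the updated [ReferenceGallery].
#' @export
registerClass <- function(gallery, label, vectors, overwrite = FALSE) {
  if (label %in% galleryLabels(gallery) && !overwrite)
    stop("label '", label, "' already registered (use overwrite = TRUE)")
  if (is.null(dim(vectors))) vectors <- matrix(vectors, 1L)
  m <- colMeans(vectors)
  means <- gallery@means
  cnt <- gallery@counts
  if (label %in% colnames(means)) {
    means[, label] <- m
    cnt[match(label, colnames(means))] <- nrow(vectors)
  } else {
    means <- cbind(means, m)
    colnames(means)[ncol(means)] <- label
    cnt <- c(cnt, nrow(vectors))
  }
  new("ReferenceGallery", means = means, counts = as.integer(cnt))
}

#' Open-world two-fold evaluation plan
#'
#' The default plan contains the four class-disjoint runs of the two-fold
#' open-world cross-validation: 1st fold-A/B train on (C1, C2) / (C3, C4)
#' and test on the complementary pair; 2nd fold-A/B train on (C3, C1) /
#' (C4, C2).
#'
#' @param runs optional named list of `list(train =, test =)` label pairs.
#' @param labels the four class labels in order.
#' @return an [OpenWorldPlan].
#' @export
openWorldPlan <- function(runs = NULL, labels = .CLASS_LABELS) {
  if (is.null(runs)) {
    runs <- list(
      `1st fold-A` = list(train = labels[c(1, 2)], test = labels[c(3, 4)]),
      `1st fold-B` = list(train = labels[c(3, 4)], test = labels[c(1, 2)]),
      `2nd fold-A` = list(train = labels[c(3, 1)], test = labels[c(4, 2)]),
      `2nd fold-B` = list(train = labels[c(4, 2)], test = labels[c(3, 1)]))
  }
  new("OpenWorldPlan", runs = runs)
}

setMethod("show", "OpenWorldPlan", function(object) {
  cat("OpenWorldPlan with", length(object@runs), "runs\n")
  for (nm in names(object@runs)) {
    r <- object@runs[[nm]]
    cat(sprintf("  %s: train {%s} test {%s}\n", nm,
                paste(r$train, collapse = ", "),
                paste(r$test, collapse = ", ")))
  }
})

#' Open-world evaluation
#'
#' For each run of the plan: a DRE-Net is trained on the training classes
#' (optionally RIA-expanded), concatenation-layer features of the unseen
#' testing-class images are extracted (unaugmented), and each query is
#' matched against leave-one-out class means of the testing classes. Per-run
#' confusion matrices and metrics are reported with their average.
#'
#' @inheritParams runClosedWorld
#' @param plan an [OpenWorldPlan].
#' @return list: `runs` (per-run list with `confusion` and `report`),
#'   `mean` (named vector of mean metrics).
#' @export
runOpenWorld <- function(manifest, plan = NULL,
                         config = trainConfig(), seed = 1L,
                         resnet = buildExtractor("resnet50_modified"),
                         densenet = buildExtractor("densenet201_modified"),
                         ria = TRUE, policy = rotationPolicy(),
                         images = NULL, featureCache = NULL) {
  if (is.null(plan)) {
    present <- unique(as.character(manifest$label))
    lev <- if (all(present %in% .CLASS_IDS)) .CLASS_IDS else .CLASS_LABELS
    plan <- openWorldPlan(labels = lev[lev %in% present])
  }
  stopifnot(all(unlist(lapply(plan@runs, unlist)) %in% manifest$label))
  if (is.null(images)) images <- .loadImages(manifest)
  frozen <- config$epochsBackbone == 0L && config$regime == "sequential"
  if (frozen && is.null(featureCache)) featureCache <- new.env()
  out <- list()
  for (nm in names(plan@runs)) {
    r <- plan@runs[[nm]]
    trIdx <- which(manifest$label %in% r$train)
    teIdx <- which(manifest$label %in% r$test)
    if (frozen) {
      rn <- resnet; dn <- densenet
      tr <- .concatFeatureRows(manifest, images, trIdx, rn, dn, featureCache,
                               if (ria) policy@anglesDeg else 0)
      trainSCN(tr$features, tr$labels, config, classLabels = r$train)
      te <- .concatFeatureRows(manifest, images, teIdx, rn, dn, featureCache,
                               0)
    } else {
      trImgs <- images[trIdx]
      trLabels <- manifest$label[trIdx]
      if (ria) {
        trImgs <- riaExpand(trImgs, policy)
        trLabels <- rep(trLabels, each = length(policy@anglesDeg))
      }
      fit <- trainSequential(config = config, resnet = resnet,
                             densenet = densenet, images = trImgs,
                             labels = trLabels, classLabels = r$train)
      te <- list(features = extractConcatFeatures(fit$model, images[teIdx]),
                 labels = manifest$label[teIdx])
    }
    pred <- .leaveOneOutMatch(te$features, te$labels, r$test)
    cm <- confusionMatrix(pred, te$labels, r$test)
    out[[nm]] <- list(confusion = cm, report = metricsReport(cm))
  }
  means <- colMeans(do.call(rbind, lapply(out, function(o)
    metricsVector(o$report))))
  list(runs = out, mean = means)
}

# each query is matched against class means computed without the query
.leaveOneOutMatch <- function(features, labels, classOrder) {
  labels <- as.character(labels)
  sums <- rowsum(features, labels)
  ns <- as.vector(table(labels)[rownames(sums)])
  pred <- character(nrow(features))
  for (i in seq_len(nrow(features))) {
    means <- sums
    for (cl in rownames(sums)) {
      if (cl == labels[i]) {
        if (ns[match(cl, rownames(sums))] < 2L)
          stop("leave-one-out mean undefined: class ", cl,
               " has a single sample")
        means[cl, ] <- (sums[cl, ] - features[i, ]) /
          (ns[match(cl, rownames(sums))] - 1L)
      } else {
        means[cl, ] <- sums[cl, ] / ns[match(cl, rownames(sums))]
      }
    }
    ordered <- means[classOrder, , drop = FALSE]
    d2 <- rowSums((ordered - matrix(features[i, ], nrow(ordered),
                                    ncol(features), byrow = TRUE))^2)
    pred[i] <- classOrder[which.min(d2)]
  }
  pred
}
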