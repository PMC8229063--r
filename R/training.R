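# Momentum-SGD training in the two regimes: sequential (each backbone
# fine-tuned with a temporary head, then the SCN trained on frozen concat
# features) and end-to-end (both backbones and the head updated jointly
# under one cross-entropy loss).

#' Training configuration
#'
#' Defaults follow the standard recipe for this model family: sequential
#' backbone fine-tuning for 13 epochs each and 9 SCN epochs (7 epochs for
#' end-to-end), mini-batch 10, learning rate 0.001, momentum 0.9, L2
#' regularization 1e-4. The learning-rate drop factor is recorded but no
#' drop period is applied unless one is given.
#'
#' @param regime `"sequential"` or `"end_to_end"`.
#' @param epochsBackbone,epochsSCN,epochsEndToEnd epoch counts per component.
#'   `epochsBackbone = 0` freezes the backbones (feature-extraction only).
#' @param minibatch mini-batch size.
#' @param learningRate,momentum,l2 optimizer parameters.
#' @param lrDropFactor,lrDropPeriod step learning-rate schedule; with
#'   `lrDropPeriod = NA` (default) the rate is constant.
#' @param validationFraction fraction of training data held out for
#'   monitoring (no early stopping).
#' @param gradClipNorm global L2 gradient-norm threshold applied in the
#'   loops that update backbone parameters (gradients are rescaled when the
#'   pooled norm exceeds it). Randomly initialized deep backbones produce
#'   very large early gradients; clipping keeps their fine-tuning finite
#'   without affecting well-scaled problems. `Inf` disables clipping. The
#'   SCN-only trainer never clips.
#' @param standardizeSCN precondition SCN training by per-dimension
#'   standardization of the input features; the scaling is absorbed back
#'   into the returned head weights, so the trained head still operates on
#'   raw concatenated features.
#' @param seed integer seed driving shuffling and initialization.
#' @return a list with class `"trainConfig"`.
#' @export
trainConfig <- function(regime = c("sequential", "end_to_end"),
                        epochsBackbone = 13L, epochsSCN = 9L,
                        epochsEndToEnd = 7L, minibatch = 10L,
                        learningRate = 0.001, momentum = 0.9, l2 = 1e-4,
                        lrDropFactor = 0.1, lrDropPeriod = NA_integer_,
                        validationFraction = 0.25, standardizeSCN = TRUE,
                        gradClipNorm = 10, seed = 1L) {
  regime <- match.arg(regime)
  stopifnot(validationFraction > 0, validationFraction < 1,
            minibatch >= 1, epochsSCN >= 1, epochsEndToEnd >= 1,
            epochsBackbone >= 0)
  structure(list(regime = regime, epochsBackbone = as.integer(epochsBackbone),
                 epochsSCN = as.integer(epochsSCN),
                 epochsEndToEnd = as.integer(epochsEndToEnd),
                 minibatch = as.integer(minibatch),
                 learningRate = learningRate, momentum = momentum, l2 = l2,
                 lrDropFactor = lrDropFactor, lrDropPeriod = lrDropPeriod,
                 validationFraction = validationFraction,
                 standardizeSCN = isTRUE(standardizeSCN),
                 gradClipNorm = gradClipNorm,
                 seed = as.integer(seed)),
            class = "trainConfig")
}

.lrAt <- function(config, epoch) {
  if (is.na(config$lrDropPeriod)) return(config$learningRate)
  config$learningRate *
    config$lrDropFactor^((epoch - 1L) %/% config$lrDropPeriod)
}

#' Stratified train/validation split
#'
#' @param manifest data.frame with a `label` column.
#' @param fraction validation fraction in (0, 1).
#' @param seed integer seed.
#' @return list with elements `train` and `validation` (disjoint, union =
#'   input). Classes with fewer than 2 samples go entirely to train, with a
#'   warning.
#' @export
splitTrainValidation <- function(manifest, fraction = 0.25, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  labs <- unique(manifest$label)
  sizes <- vapply(labs, function(lb) sum(manifest$label == lb), 0L)
  eligible <- sizes >= 2L
  if (any(!eligible))
    warning("class(es) ", paste(labs[!eligible], collapse = ", "),
            " have fewer than 2 samples: all go to train")
  # per-class validation counts by largest remainder, so the overall split
  # hits round(n * fraction) while staying stratified
  want <- sizes * fraction
  nVal <- floor(want)
  short <- round(sum(sizes[eligible]) * fraction) - sum(nVal[eligible])
  if (short > 0) {
    ord <- order(want - nVal, decreasing = TRUE)
    ord <- ord[eligible[ord]]
    nVal[ord[seq_len(min(short, length(ord)))]] <-
      nVal[ord[seq_len(min(short, length(ord)))]] + 1L
  }
  valIdx <- integer(0)
  .withSeed(seed, for (li in seq_along(labs)) {
    if (!eligible[li] || nVal[li] == 0L) next
    idx <- which(manifest$label == labs[li])
    valIdx <- c(valIdx, sample(idx, nVal[li]))
  })
  list(train = manifest[setdiff(seq_len(nrow(manifest)), valIdx), ,
                        drop = FALSE],
       validation = manifest[valIdx, , drop = FALSE])
}

#' One SGD step with classical momentum and L2 weight decay
#'
#' `v <- momentum * v - lr * (gradient + l2 * parameter)` followed by
#' `parameter <- parameter + v`, applied elementwise to a named list of
#' parameter arrays.
#'
#' @param parameters named list of numeric arrays (or a single array).
#' @param gradients matching gradients.
#' @param state optimizer state (velocities); `NULL` initializes zeros.
#' @param config a [trainConfig()]; `learningRate`, `momentum` and `l2` are
#'   used. An explicit `lr` overrides the config rate (for schedules).
#' @param lr optional overriding learning rate.
#' @return list with updated `parameters` and `state`.
#' @export
sgdStep <- function(parameters, gradients, state = NULL, config = trainConfig(),
                    lr = NULL) {
  single <- !is.list(parameters)
  if (single) {
    parameters <- list(p = parameters)
    gradients <- list(p = gradients)
    if (!is.null(state)) state <- list(p = state)
  }
  if (is.null(state)) state <- lapply(parameters, function(p) p * 0)
  lr <- lr %||% config$learningRate
  for (nm in names(parameters)) {
    g <- gradients[[nm]]
    if (any(!is.finite(g)))
      stop("non-finite gradient in parameter block '", nm, "'")
    state[[nm]] <- config$momentum * state[[nm]] -
      lr * (g + config$l2 * parameters[[nm]])
    parameters[[nm]] <- parameters[[nm]] + state[[nm]]
  }
  if (single) list(parameters = parameters$p, state = state$p)
  else list(parameters = parameters, state = state)
}

# ---- SCN head training on precomputed features ----------------------------

#' Train the SCN head on concatenated features
#'
#' Multinomial softmax regression trained with mini-batch momentum SGD and
#' cross-entropy loss. With `standardizeSCN` preconditioning (see
#' [trainConfig()]) the learned affine map is re-expressed in raw feature
#' coordinates before the head is returned.
#'
#' @param features N x D matrix of concatenated feature vectors.
#' @param labels length-N class labels.
#' @param config a [trainConfig()]; `epochsSCN` epochs are run.
#' @param classLabels ordered label set (defaults to the sorted unique
#'   labels observed).
#' @param validation optional list(features, labels) monitored per epoch.
#' @return list: `head` (an [SCNHead]) and `trace` (data.frame of
#'   per-iteration loss/accuracy plus per-epoch validation columns).
#' @export
trainSCN <- function(features, labels, config = trainConfig(),
                     classLabels = NULL, validation = NULL) {
  classLabels <- classLabels %||% sort(unique(as.character(labels)))
  y <- match(as.character(labels), classLabels)
  stopifnot(!anyNA(y))
  n <- nrow(features); d <- ncol(features); k <- length(classLabels)
  if (config$standardizeSCN) {
    mu <- colMeans(features)
    sd_ <- pmax(apply(features, 2L, stats::sd), 1e-8)
    X <- sweep(sweep(features, 2L, mu), 2L, sd_, "/")
  } else {
    mu <- rep(0, d); sd_ <- rep(1, d)
    X <- features
  }
  W <- matrix(0, k, d); b <- rep(0, k)
  state <- NULL
  trace <- list()
  it <- 0L
  for (epoch in seq_len(config$epochsSCN)) {
    ord <- .withSeed(config$seed + epoch, sample.int(n))
    lr <- .lrAt(config, epoch)
    for (start in seq(1L, n, by = config$minibatch)) {
      idx <- ord[start:min(start + config$minibatch - 1L, n)]
      Xb <- X[idx, , drop = FALSE]
      Z <- Xb %*% t(W) + matrix(b, length(idx), k, byrow = TRUE)
      Z <- Z - apply(Z, 1L, max)
      P <- exp(Z) / rowSums(exp(Z))
      Y <- matrix(0, length(idx), k)
      Y[cbind(seq_along(idx), y[idx])] <- 1
      loss <- mean(-log(pmax(P[cbind(seq_along(idx), y[idx])], 1e-300)))
      acc <- mean(max.col(P, ties.method = "first") == y[idx])
      G <- P - Y
      grads <- list(W = t(G) %*% Xb / length(idx), b = colMeans(G))
      upd <- sgdStep(list(W = W, b = b), grads, state, config, lr = lr)
      W <- upd$parameters$W; b <- upd$parameters$b; state <- upd$state
      it <- it + 1L
      trace[[it]] <- data.frame(iteration = it, epoch = epoch, loss = loss,
                                accuracy = acc, valLoss = NA_real_,
                                valAccuracy = NA_real_)
    }
    if (!is.null(validation)) {
      Xv <- sweep(sweep(validation$features, 2L, mu), 2L, sd_, "/")
      yv <- match(as.character(validation$labels), classLabels)
      Zv <- Xv %*% t(W) + matrix(b, nrow(Xv), k, byrow = TRUE)
      Zv <- Zv - apply(Zv, 1L, max)
      Pv <- exp(Zv) / rowSums(exp(Zv))
      trace[[it]]$valLoss <-
        mean(-log(pmax(Pv[cbind(seq_len(nrow(Xv)), yv)], 1e-300)))
      trace[[it]]$valAccuracy <-
        mean(max.col(Pv, ties.method = "first") == yv)
    }
  }
  # absorb the standardization into raw-feature coordinates
  Wraw <- sweep(W, 2L, sd_, "/")
  braw <- b - drop(Wraw %*% mu)
  list(head = scnHead(Wraw, braw, classLabels),
       trace = do.call(rbind, trace))
}

# ---- backbone fine-tuning --------------------------------------------------

# rescale gradients when their pooled L2 norm exceeds the threshold
.clipGrads <- function(grads, maxNorm) {
  if (!is.finite(maxNorm)) return(grads)
  nrm <- sqrt(sum(vapply(grads, function(g) sum(g^2), 0)))
  if (is.finite(nrm) && nrm > maxNorm)
    grads <- lapply(grads, function(g) g * (maxNorm / nrm))
  grads
}

.loadImages <- function(manifest) lapply(manifest$path, readImageFile)

# fine-tune a tempClassifier for `epochs` epochs on in-memory images
.trainClassifier <- function(classifier, images, y0, config, epochs) {
  cg <- .classifierGraph(classifier)
  params <- cg$params
  state <- NULL
  n <- length(images)
  trace <- list(); it <- 0L
  for (epoch in seq_len(epochs)) {
    ord <- .withSeed(config$seed + 131L * epoch, sample.int(n))
    lr <- .lrAt(config, epoch)
    for (start in seq(1L, n, by = config$minibatch)) {
      idx <- ord[start:min(start + config$minibatch - 1L, n)]
      res <- .nn_grad_batch(cg$layers, params,
                            lapply(images[idx], .preprocess),
                            as.integer(y0[idx]))
      grads <- .clipGrads(res$grads[names(params)], config$gradClipNorm)
      upd <- sgdStep(params, grads, state, config, lr = lr)
      params <- upd$parameters; state <- upd$state
      it <- it + 1L
      trace[[it]] <- data.frame(
        iteration = it, epoch = epoch, loss = res$loss,
        accuracy = mean(res$pred == y0[idx]))
    }
  }
  fx <- classifier$extractor
  fxNames <- names(fx@params)
  fx@params <- params[fxNames]
  list(classifier = structure(list(extractor = fx,
                                   headW = params$tmphead.W,
                                   headB = params$tmphead.b),
                              class = "tempClassifier"),
       trace = if (it > 0) do.call(rbind, trace) else NULL)
}

#' Sequential DRE-Net training
#'
#' Stage 1: each backbone plus a temporary 4-class head is fine-tuned
#' independently (`epochsBackbone` epochs; 0 keeps the backbones frozen).
#' Stage 2: the heads are discarded, the backbones frozen, and concatenated
#' features extracted once. Stage 3: the SCN head is trained on those
#' features for `epochsSCN` epochs. Backbone parameters are untouched by
#' stage 3.
#'
#' @param manifest training manifest (typically RIA-expanded) with `path`
#'   and `label` columns; images must exist on disk. Alternatively pass
#'   `images`/`labels` directly.
#' @param config a [trainConfig()].
#' @param resnet,densenet the backbones to start from.
#' @param images optional list of in-memory images (overrides manifest
#'   paths).
#' @param labels labels matching `images`.
#' @param classLabels ordered label set.
#' @return list: `model` (a [DRENet]), `traces` (per-component training
#'   traces).
#' @export
trainSequential <- function(manifest = NULL, config = trainConfig(),
                            resnet = buildExtractor("resnet50_modified"),
                            densenet = buildExtractor("densenet201_modified"),
                            images = NULL, labels = NULL,
                            classLabels = NULL) {
  if (is.null(images)) {
    stopifnot(!is.null(manifest))
    images <- .loadImages(manifest)
    labels <- manifest$label
  }
  classLabels <- classLabels %||% sort(unique(as.character(labels)))
  y0 <- match(as.character(labels), classLabels) - 1L
  traces <- list()
  if (config$epochsBackbone > 0L) {
    for (which in c("resnet", "densenet")) {
      fx <- if (which == "resnet") resnet else densenet
      clf <- attachTempHead(fx, length(classLabels), seed = config$seed)
      res <- .trainClassifier(clf, images, y0, config, config$epochsBackbone)
      traces[[which]] <- res$trace
      if (which == "resnet") resnet <- detachHead(res$classifier)
      else densenet <- detachHead(res$classifier)
    }
  }
  f <- concatFeatures(extractFeatures(resnet, images),
                      extractFeatures(densenet, images))
  scn <- trainSCN(f, labels, config, classLabels = classLabels)
  traces$scn <- scn$trace
  list(model = buildDRENet(resnet, densenet, scn$head), traces = traces)
}

# single trainable graph over both backbones + SCN head
.combinedGraph <- function(resnet, densenet, head) {
  rl <- resnet@layers
  dl <- densenet@layers
  nR <- length(rl)
  shift <- function(l) {
    l$`in` <- ifelse(l$`in` == 1L, 1L, l$`in` + nR - 1L)
    l
  }
  layers <- c(rl, lapply(dl[-1L], shift))
  nD <- length(layers)
  layers <- c(layers, list(
    list(type = "concat", `in` = c(nR, nD)),
    list(type = "dense", `in` = nD + 1L, prefix = "scn")))
  params <- c(resnet@params, densenet@params,
              list(scn.W = head@weights, scn.b = head@bias))
  list(layers = layers, params = params)
}

#' End-to-end DRE-Net training
#'
#' All parameters -- both backbones and the SCN head -- are updated jointly
#' for `epochsEndToEnd` epochs under the shared cross-entropy loss.
#'
#' @inheritParams trainSequential
#' @param headSeed seed for the SCN weight initialization (small gaussian,
#'   needed so gradients reach the backbones from the first step).
#' @return list: `model` (a [DRENet]) and `trace`.
#' @export
trainEndToEnd <- function(manifest = NULL, config = trainConfig("end_to_end"),
                          resnet = buildExtractor("resnet50_modified"),
                          densenet = buildExtractor("densenet201_modified"),
                          images = NULL, labels = NULL, classLabels = NULL,
                          headSeed = 7L) {
  if (is.null(images)) {
    stopifnot(!is.null(manifest))
    images <- .loadImages(manifest)
    labels <- manifest$label
  }
  classLabels <- classLabels %||% sort(unique(as.character(labels)))
  y0 <- match(as.character(labels), classLabels) - 1L
  d <- resnet@featureDim + densenet@featureDim
  k <- length(classLabels)
  head <- scnHead(.withSeed(headSeed, matrix(stats::rnorm(k * d, sd = 0.01),
                                             k, d)),
                  classLabels = classLabels, inputDim = d)
  cg <- .combinedGraph(resnet, densenet, head)
  params <- cg$params
  state <- NULL
  n <- length(images)
  trace <- list(); it <- 0L
  for (epoch in seq_len(config$epochsEndToEnd)) {
    ord <- .withSeed(config$seed + 977L * epoch, sample.int(n))
    lr <- .lrAt(config, epoch)
    for (start in seq(1L, n, by = config$minibatch)) {
      idx <- ord[start:min(start + config$minibatch - 1L, n)]
      res <- .nn_grad_batch(cg$layers, params,
                            lapply(images[idx], .preprocess),
                            as.integer(y0[idx]))
      grads <- .clipGrads(res$grads[names(params)], config$gradClipNorm)
      upd <- sgdStep(params, grads, state, config, lr = lr)
      params <- upd$parameters; state <- upd$state
      it <- it + 1L
      trace[[it]] <- data.frame(iteration = it, epoch = epoch,
                                loss = res$loss,
                                accuracy = mean(res$pred == y0[idx]))
    }
  }
  resnet@params <- params[names(resnet@params)]
  densenet@params <- params[names(densenet@params)]
  head <- scnHead(params$scn.W, params$scn.b, classLabels)
  list(model = buildDRENet(resnet, densenet, head),
       trace = do.call(rbind, trace))
}

#' Export a training trace as CSV
#' @param trace data.frame as returned in training results.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
writeTrainingTrace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
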