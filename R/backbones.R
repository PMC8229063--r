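# Modified ResNet-50 and DenseNet-201 feature extractors: the fully
# connected, softmax and classification-output layers of the stock
# architectures are removed, so each network ends at its 7x7 global average
# pool and yields a flat feature vector (f1: 2048-d, f2: 1920-d).

#' Build a modified feature extractor
#'
#' Constructs the modified ResNet-50 (2048-d output) or modified DenseNet-201
#' (1920-d output): all classification layers removed, output taken at global
#' average pooling.
#'
#' @param arch `"resnet50_modified"` or `"densenet201_modified"`.
#' @param pretrained logical. `FALSE` (default) initializes all parameters
#'   from a seeded random draw (He-normal convolutions, identity batch-norm
#'   affine terms). `TRUE` requires externally supplied ImageNet weights via
#'   `weightsFile` (a readRDS-able named parameter list); no download is
#'   attempted.
#' @param seed integer seed for random initialization.
#' @param weightsFile optional path to a saved parameter list.
#' @return a [FeatureExtractor].
#' @examples
#' fx <- buildExtractor("resnet50_modified", seed = 1)
#' featureDim(fx)  # 2048
#' @export
buildExtractor <- function(arch = c("resnet50_modified",
                                    "densenet201_modified"),
                           pretrained = FALSE, seed = 1L,
                           weightsFile = NULL) {
  arch <- match.arg(arch)
  built <- switch(arch,
    resnet50_modified = .buildResNet50Graph("rn"),
    densenet201_modified = .buildDenseNet201Graph("dn"))
  g <- built$graph
  if (pretrained && is.null(weightsFile))
    stop("pretrained = TRUE requires 'weightsFile': no weight source is ",
         "bundled and none is downloaded")
  params <- if (is.null(weightsFile)) .ngInitParams(g, seed)
            else readRDS(weightsFile)
  stageNodes <- built$stageNodes
  stages <- data.frame(
    stage = c("Image Input", names(stageNodes)),
    node = c(1L, unname(stageNodes)),
    height = NA_integer_, width = NA_integer_, channels = NA_integer_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(stages))) {
    sh <- .ngShape(g, stages$node[i])
    stages$height[i] <- sh[1L]; stages$width[i] <- sh[2L]
    stages$channels[i] <- sh[3L]
  }
  new("FeatureExtractor", arch = arch, layers = .ngCompile(g),
      params = params,
      featureDim = .ngShape(g, built$final)[3L],
      stages = stages, pretrained = pretrained, seed = as.integer(seed))
}

#' @describeIn buildExtractor feature-vector length of an extractor.
#' @param x a [FeatureExtractor] or [DRENet].
#' @export
setMethod("featureDim", "FeatureExtractor", function(x) x@featureDim)

#' @rdname stageShapes
setMethod("stageShapes", "FeatureExtractor", function(x)
  x@stages[, c("stage", "height", "width", "channels")])

setMethod("show", "FeatureExtractor", function(object) {
  cat(sprintf("%s feature extractor (%s)\n", object@arch,
              if (object@pretrained) "pretrained" else
                sprintf("random init, seed %d", object@seed)))
  cat(sprintf("  input 224x224x3 -> feature vector of length %d\n",
              object@featureDim))
  cat(sprintf("  %d graph nodes, %d parameter arrays\n",
              length(object@layers), length(object@params)))
})

# scale [0, 255] intensities to the network input range
.preprocess <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L)
    stop("images must be H x W x C arrays")
  img / 255
}

#' Extract feature vectors from images
#'
#' Runs images through a truncated backbone in inference mode. Rows are
#' independent of batch composition and repeated calls are deterministic.
#'
#' @param extractor a [FeatureExtractor].
#' @param images a single H x W x 3 array (intensities 0-255) or a list of
#'   such arrays.
#' @return N x D numeric matrix of feature vectors.
#' @export
extractFeatures <- function(extractor, images) {
  stopifnot(is(extractor, "FeatureExtractor"))
  if (is.array(images)) images <- list(images)
  imgs <- lapply(images, .preprocess)
  .nn_forward(extractor@layers, extractor@params, imgs)
}

#' Attach a temporary classification head to an extractor
#'
#' Backbone fine-tuning needs a classification output; this attaches a
#' fully-connected + softmax head on top of the feature vector. The head is
#' detachable and detaching never mutates the extractor parameters.
#'
#' @param extractor a [FeatureExtractor].
#' @param numClasses number of classes (>= 2).
#' @param seed seed for the (small gaussian) head weight initialization.
#' @return a list with class `"tempClassifier"`: `extractor`, `headW`,
#'   `headB`.
#' @export
attachTempHead <- function(extractor, numClasses, seed = 1L) {
  if (numClasses < 2) stop("numClasses must be >= 2")
  d <- extractor@featureDim
  headW <- .withSeed(seed,
                     matrix(stats::rnorm(numClasses * d, sd = 0.01),
                            numClasses, d))
  structure(list(extractor = extractor, headW = headW,
                 headB = rep(0, numClasses)),
            class = "tempClassifier")
}

#' Detach the temporary head
#' @param classifier a `"tempClassifier"` from [attachTempHead()].
#' @return the (possibly fine-tuned) [FeatureExtractor], head discarded.
#' @export
detachHead <- function(classifier) {
  stopifnot(inherits(classifier, "tempClassifier"))
  classifier$extractor
}

# layer list + params of a tempClassifier as one trainable graph
.classifierGraph <- function(classifier) {
  fx <- classifier$extractor
  nFinal <- length(fx@layers)
  layers <- c(fx@layers, list(list(type = "dense", `in` = nFinal,
                                   prefix = "tmphead")))
  params <- c(fx@params, list(tmphead.W = classifier$headW,
                              tmphead.b = classifier$headB))
  list(layers = layers, params = params)
}

#' Predict class probabilities with a temporary classifier
#' @param classifier a `"tempClassifier"`.
#' @param images single array or list of arrays (0-255).
#' @return N x K matrix of class probabilities (rows sum to 1).
#' @export
tempHeadPredict <- function(classifier, images) {
  if (is.array(images)) images <- list(images)
  cg <- .classifierGraph(classifier)
  z <- .nn_forward(cg$layers, cg$params, lapply(images, .preprocess))
  t(apply(z, 1L, function(r) softmaxProbs(r)@probabilities))
}

#' Block activation map
#'
#' Channel-mean activation of a named backbone stage, min-max normalized and
#' bilinearly upsampled to the input size. With the stock stage lists this
#' yields the five maps F1..F5 (post max-pool plus the four convolutional
#' blocks) for either backbone.
#'
#' @param extractor a [FeatureExtractor].
#' @param image H x W x 3 array (0-255).
#' @param stage stage name as reported by [stageShapes()].
#' @return 224 x 224 matrix with values in \[0, 1\].
#' @export
blockActivationMap <- function(extractor, image, stage) {
  st <- extractor@stages
  if (!stage %in% st$stage)
    stop("unknown stage '", stage, "'; valid stages: ",
         paste(st$stage, collapse = ", "))
  node <- st$node[st$stage == stage]
  out <- .nn_forward_capture(extractor@layers, extractor@params,
                             .preprocess(image), node)[[1L]]
  m <- apply(out, c(1L, 2L), mean)
  rng <- range(m)
  m <- if (diff(rng) > 0) (m - rng[1L]) / diff(rng) else m * 0
  .bilinearResize(m, dim(image)[1L], dim(image)[2L])
}

#' Stage names whose activation maps form the F1..F5 sequence
#' @param extractor a [FeatureExtractor].
#' @return character vector of five stage names.
#' @export
activationStages <- function(extractor) {
  if (extractor@arch == "resnet50_modified")
    c("Max Pooling", "Conv 2_x", "Conv 3_x", "Conv 4_x", "Conv 5_x")
  else
    c("Max Pooling", "DenseBlock_1", "DenseBlock_2", "DenseBlock_3",
      "DenseBlock_4")
}
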