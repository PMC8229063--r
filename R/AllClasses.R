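#' @import methods
NULL

.CLASS_LABELS <- c("Cofield", "Depuy", "Tornier", "Zimmer")
.CLASS_IDS <- c("C1", "C2", "C3", "C4")

#' Rotation policy for in-plane augmentation
#'
#' Describes the set of rotation angles and the resampling conventions used by
#' rotational invariant augmentation (RIA). The default policy rotates about
#' the image centre at 10 degree steps, producing 36 poses per image
#' (the 0 degree pose, i.e. the original image, is one of them).
#'
#' @slot anglesDeg numeric vector of rotation angles in degrees, unique
#'   modulo 360.
#' @slot interpolation `"bilinear"` or `"nearest"`. Multiples of 90 degrees
#'   are always exact array reindexings regardless of this setting.
#' @slot fillValue intensity (0-255) used for canvas corners exposed by the
#'   rotation.
#' @export
setClass("RotationPolicy", representation(
  anglesDeg = "numeric", interpolation = "character", fillValue = "numeric"))

setValidity("RotationPolicy", function(object) {
  a <- object@anglesDeg %% 360
  if (anyDuplicated(round(a, 9))) return("angles must be unique modulo 360")
  if (!object@interpolation %in% c("bilinear", "nearest"))
    return("interpolation must be 'bilinear' or 'nearest'")
  if (length(object@fillValue) != 1 || object@fillValue < 0 ||
      object@fillValue > 255)
    return("fillValue must be a single intensity in [0, 255]")
  TRUE
})

#' Synthetic implant phantom specification
#'
#' Geometry, intensity and pose parameters for one synthetic shoulder-implant
#' radiograph: a rod-shaped stem with a class-specific head (rounded,
#' hemispherical or angled), optional collar, soft-tissue-like background
#' gradient and additive Gaussian noise. Identical spec + seed always renders
#' a pixel-identical image.
#'
#' @slot classId one of `"C1"`..`"C4"`.
#' @slot stemLengthPx,stemWidthPx,headRadiusPx implant geometry in pixels.
#' @slot headShape `"rounded"`, `"hemispherical"` or `"angled"`.
#' @slot collar logical; draw a collar bar below the head.
#' @slot foregroundIntensity implant intensity, 0-255.
#' @slot backgroundGradient length-2 intensities (top, bottom), 0-255.
#' @slot noiseSd standard deviation of additive Gaussian intensity noise.
#' @slot poseAngleDeg in-plane pose rotation in degrees.
#' @slot poseOffsetPx length-2 integer offset (rows, cols) of the implant.
#' @slot seed integer seed controlling the noise draw.
#' @export
setClass("ImplantPhantomSpec", representation(
  classId = "character", stemLengthPx = "integer", stemWidthPx = "integer",
  headRadiusPx = "integer", headShape = "character", collar = "logical",
  foregroundIntensity = "numeric", backgroundGradient = "numeric",
  noiseSd = "numeric", poseAngleDeg = "numeric", poseOffsetPx = "integer",
  seed = "integer"))

setValidity("ImplantPhantomSpec", function(object) {
  if (!object@classId %in% .CLASS_IDS) return("classId must be C1..C4")
  if (!object@headShape %in% c("rounded", "hemispherical", "angled"))
    return("headShape must be rounded, hemispherical or angled")
  dims <- c(object@stemLengthPx, object@stemWidthPx, object@headRadiusPx)
  if (any(dims <= 0)) return("all pixel dimensions must be positive")
  span <- object@stemLengthPx + object@headRadiusPx +
    2L * max(abs(object@poseOffsetPx))
  if (span > 224L) return("implant geometry exceeds the 224x224 canvas")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  if (length(object@backgroundGradient) != 2 ||
      any(object@backgroundGradient < 0 | object@backgroundGradient > 255))
    return("backgroundGradient must be two intensities in [0, 255]")
  if (object@foregroundIntensity < 0 || object@foregroundIntensity > 255)
    return("foregroundIntensity must be in [0, 255]")
  TRUE
})

#' Truncated CNN feature extractor
#'
#' A modified ResNet-50 or DenseNet-201: the classification layers are
#' removed so the network ends at global average pooling and maps a
#' 224x224x3 image to a flat feature vector (2048-d for ResNet-50, 1920-d for
#' DenseNet-201).
#'
#' @slot arch `"resnet50_modified"` or `"densenet201_modified"`.
#' @slot layers internal layer-graph descriptor list.
#' @slot params named list of parameter arrays.
#' @slot featureDim length of the output feature vector.
#' @slot stages data.frame of named stages (stage, node, height, width,
#'   channels) mirroring the architecture tables.
#' @slot pretrained logical; `FALSE` means seeded random initialization.
#' @slot seed integer seed used for random initialization.
#' @export
setClass("FeatureExtractor", representation(
  arch = "character", layers = "list", params = "list",
  featureDim = "integer", stages = "data.frame", pretrained = "logical",
  seed = "integer"))

setValidity("FeatureExtractor", function(object) {
  want <- switch(object@arch, resnet50_modified = 2048L,
                 densenet201_modified = 1920L, return("unknown arch"))
  if (object@featureDim != want)
    return(sprintf("featureDim must be %d for %s", want, object@arch))
  TRUE
})

#' Shallow concatenation network head
#'
#' The single fully-connected + softmax classification head applied to the
#' concatenated feature vector f = (f1, f2) of length 3968.
#'
#' @slot weights K x D weight matrix (rows = classes).
#' @slot bias length-K bias vector.
#' @slot classLabels ordered class labels.
#' @export
setClass("SCNHead", representation(
  weights = "matrix", bias = "numeric", classLabels = "character"))

setValidity("SCNHead", function(object) {
  if (nrow(object@weights) != length(object@bias))
    return("weight row count must equal bias length")
  if (nrow(object@weights) != length(object@classLabels))
    return("weight row count must equal the number of class labels")
  TRUE
})

#' Dense residual ensemble network
#'
#' The assembled DRE-Net: a modified ResNet-50 and a modified DenseNet-201
#' feeding a shallow concatenation network head. The head input dimension is
#' 2048 + 1920 = 3968.
#'
#' @slot resnet,densenet [FeatureExtractor] objects.
#' @slot head an [SCNHead].
#' @export
setClass("DRENet", representation(
  resnet = "FeatureExtractor", densenet = "FeatureExtractor",
  head = "SCNHead"))

setValidity("DRENet", function(object) {
  d <- object@resnet@featureDim + object@densenet@featureDim
  if (ncol(object@head@weights) != d)
    return(sprintf("head input dimension must be %d", d))
  TRUE
})

#' Class probability vector
#'
#' Softmax output for one sample: non-negative probabilities summing to one,
#' with the predicted label (argmax, ties broken toward the lowest class
#' index).
#'
#' @slot probabilities named numeric vector.
#' @slot label predicted class label.
#' @export
setClass("ClassProbabilities", representation(
  probabilities = "numeric", label = "character"))

setValidity("ClassProbabilities", function(object) {
  p <- object@probabilities
  if (any(p < 0)) return("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-9) return("probabilities must sum to 1")
  TRUE
})

#' Stratified fold assignment
#'
#' @slot k number of folds.
#' @slot foldId per-sample fold membership (1..k).
#' @slot labels per-sample class labels.
#' @export
setClass("FoldPlan", representation(
  k = "integer", foldId = "integer", labels = "character"))

setValidity("FoldPlan", function(object) {
  if (length(object@foldId) != length(object@labels))
    return("foldId and labels must have equal length")
  if (any(object@foldId < 1L | object@foldId > object@k))
    return("fold ids must lie in 1..k")
  tab <- table(object@labels, object@foldId)
  if (any(apply(tab, 1, function(x) diff(range(x))) > 1))
    return("within each class, fold sizes may differ by at most 1")
  TRUE
})

#' Confusion matrix
#'
#' K x K table of counts with true classes in rows and predicted classes in
#' columns.
#'
#' @slot counts integer matrix with identical row/column dimnames.
#' @export
setClass("ConfusionMatrix", representation(counts = "matrix"))

setValidity("ConfusionMatrix", function(object) {
  m <- object@counts
  if (nrow(m) != ncol(m)) return("counts must be square")
  if (any(m < 0)) return("counts must be non-negative")
  if (!identical(rownames(m), colnames(m)))
    return("row and column names must agree")
  TRUE
})

#' Macro classification metrics
#'
#' Accuracy, F1-score, precision and recall in percent. Two documented
#' reading modes exist for accuracy and recall (see [metricsReport()]).
#'
#' @slot accuracy,f1,precision,recall percentages in [0, 100].
#' @slot accuracyMode `"overall"` or `"eq4_literal"`.
#' @slot recallMode `"standard"` or `"eq7_literal"`.
#' @export
setClass("MetricsReport", representation(
  accuracy = "numeric", f1 = "numeric", precision = "numeric",
  recall = "numeric", accuracyMode = "character", recallMode = "character"))

setValidity("MetricsReport", function(object) {
  v <- c(object@accuracy, object@f1, object@precision, object@recall)
  if (any(v < -1e-9 | v > 100 + 1e-9)) return("metrics must lie in [0, 100]")
  TRUE
})

#' Reference gallery of class mean feature vectors
#'
#' Per-class mean concatenation-layer feature vectors used for open-world
#' nearest-class-mean identification. New classes can be registered without
#' retraining.
#'
#' @slot means D x K matrix; one column per registered class.
#' @slot counts number of enrolled vectors per class.
#' @export
setClass("ReferenceGallery", representation(
  means = "matrix", counts = "integer"))

setValidity("ReferenceGallery", function(object) {
  if (ncol(object@means) != length(object@counts))
    return("one count per registered class required")
  if (is.null(colnames(object@means))) return("class labels required")
  if (any(object@counts < 1L)) return("counts must be >= 1")
  TRUE
})

#' Open-world evaluation plan
#'
#' Class-disjoint train/test pairings. The default plan holds the four
#' two-fold cross-validation runs used for open-world evaluation.
#'
#' @slot runs named list; each element has `train` and `test` label vectors.
#' @export
setClass("OpenWorldPlan", representation(runs = "list"))

setValidity("OpenWorldPlan", function(object) {
  for (r in object@runs) {
    if (!all(c("train", "test") %in% names(r)))
      return("each run needs 'train' and 'test' class sets")
    if (length(intersect(r$train, r$test)) > 0)
      return("train and test class sets must be disjoint")
  }
  TRUE
})

#' Principal component model
#'
#' PCA of training features: training mean, orthonormal eigenvectors ordered
#' by non-increasing eigenvalue (sign fixed so each eigenvector's first
#' non-zero coordinate is positive), and the eigenvalues of the training
#' covariance.
#'
#' @slot center length-D training mean.
#' @slot rotation D x m matrix of eigenvectors (columns).
#' @slot eigenvalues length-m non-increasing, non-negative.
#' @export
setClass("PCAModel", representation(
  center = "numeric", rotation = "matrix", eigenvalues = "numeric"))

setValidity("PCAModel", function(object) {
  if (ncol(object@rotation) != length(object@eigenvalues))
    return("one eigenvalue per eigenvector required")
  if (any(object@eigenvalues < -1e-8)) return("eigenvalues must be >= 0")
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    return("eigenvalues must be non-increasing")
  TRUE
})
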