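#' Feature dimension of an extractor or model
#' @param x a [FeatureExtractor] or [DRENet].
#' @return integer feature-vector length.
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' Stage-wise output shapes
#'
#' Reports the named stages of a feature extractor with their output feature
#' map sizes, mirroring the architecture tables of the modified ResNet-50 and
#' DenseNet-201.
#' @param x a [FeatureExtractor].
#' @return data.frame with columns `stage`, `height`, `width`, `channels`.
#' @export
setGeneric("stageShapes", function(x) standardGeneric("stageShapes"))

#' Ordered class labels of a model or report
#' @param x an object carrying class labels.
#' @return character vector.
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' Predict class probabilities for images
#' @param object a [DRENet].
#' @param images a single 224x224x3 array or a list of such arrays
#'   (intensities 0-255).
#' @param ... unused.
#' @return a [ClassProbabilities] for a single image, otherwise a data.frame
#'   with one row per image (probability columns plus `label`).
#' @export
setGeneric("predictClasses",
           function(object, images, ...) standardGeneric("predictClasses"))

#' Counts of a confusion matrix
#' @param object a [ConfusionMatrix].
#' @return integer matrix (true classes in rows).
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))
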