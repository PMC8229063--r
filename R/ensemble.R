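# The DRE-Net assembly: concatenation of the two backbone feature vectors,
# the shallow concatenation network (SCN) head -- one fully-connected layer
# followed by softmax -- and prediction.

#' Concatenate backbone feature vectors
#'
#' `f = (f1, f2)`: the 2048-d ResNet-50 vector followed by the 1920-d
#' DenseNet-201 vector, giving the 3968-d SCN input. The order is fixed.
#'
#' @param f1 numeric vector of length 2048 (or N x 2048 matrix).
#' @param f2 numeric vector of length 1920 (or N x 1920 matrix).
#' @return vector of length 3968 (or N x 3968 matrix).
#' @export
concatFeatures <- function(f1, f2) {
  if (is.matrix(f1) || is.matrix(f2)) {
    if (ncol(f1) != 2048L || ncol(f2) != 1920L)
      stop("expected feature dimensions 2048 and 1920, got ",
           ncol(f1), " and ", ncol(f2))
    return(cbind(f1, f2))
  }
  if (length(f1) != 2048L || length(f2) != 1920L)
    stop("expected feature dimensions 2048 and 1920, got ",
         length(f1), " and ", length(f2))
  c(f1, f2)
}

#' Construct an SCN head
#'
#' @param weights K x D matrix (defaults to a zero matrix).
#' @param bias length-K vector (defaults to zeros).
#' @param classLabels ordered labels (default Cofield, Depuy, Tornier,
#'   Zimmer).
#' @param inputDim head input dimension (default 3968).
#' @return an [SCNHead].
#' @export
scnHead <- function(weights = NULL, bias = NULL,
                    classLabels = .CLASS_LABELS, inputDim = 3968L) {
  k <- length(classLabels)
  if (is.null(weights)) weights <- matrix(0, k, inputDim)
  if (is.null(bias)) bias <- rep(0, k)
  new("SCNHead", weights = weights, bias = as.numeric(bias),
      classLabels = classLabels)
}

#' Fully-connected layer forward pass
#'
#' `z_j = sum_l w_{j,l} f_l + b_j`.
#'
#' @param f input feature vector (length = head input dimension).
#' @param head an [SCNHead].
#' @return numeric K-vector of logits, named by class label.
#' @export
fclForward <- function(f, head) {
  if (!all(is.finite(f))) stop("non-finite feature input")
  if (length(f) != ncol(head@weights))
    stop("feature length ", length(f), " does not match head input ",
         ncol(head@weights))
  z <- drop(head@weights %*% f) + head@bias
  names(z) <- head@classLabels
  z
}

#' Softmax with argmax prediction
#'
#' `f(z)_i = exp(z_i) / sum_j exp(z_j)`, computed with max-subtraction for
#' numerical stability (mathematically identical). Ties in the argmax break
#' toward the lowest class index.
#'
#' @param z finite numeric vector of logits (optionally named).
#' @return a [ClassProbabilities].
#' @export
softmaxProbs <- function(z) {
  if (!all(is.finite(z))) stop("logits must be finite")
  e <- exp(z - max(z))
  p <- e / sum(e)
  lbl <- if (!is.null(names(z))) names(z) else as.character(seq_along(z))
  new("ClassProbabilities", probabilities = stats::setNames(p, lbl),
      label = lbl[which.max(p)])
}

#' Cross-entropy loss of a prediction
#'
#' `CE = -log p(true class)`. A zero probability for the true class is
#' capped: the loss is evaluated on `max(p, 1e-300)` (about 690.8), keeping
#' the loss finite; this cap is only reachable through hard-saturated
#' inputs.
#'
#' @param probabilities a [ClassProbabilities] or bare probability vector.
#' @param trueLabel the true class label (or index for unnamed vectors).
#' @return non-negative scalar loss (nats).
#' @export
crossEntropy <- function(probabilities, trueLabel) {
  p <- if (is(probabilities, "ClassProbabilities"))
    probabilities@probabilities else probabilities
  pt <- if (is.character(trueLabel)) {
    if (!trueLabel %in% names(p)) stop("unknown label: ", trueLabel)
    p[[trueLabel]]
  } else p[[trueLabel]]
  -log(max(pt, 1e-300))
}

#' Assemble a DRE-Net
#'
#' @param resnet a `resnet50_modified` [FeatureExtractor].
#' @param densenet a `densenet201_modified` [FeatureExtractor].
#' @param head an [SCNHead] (default: zero-initialized 4-class head).
#' @return a [DRENet].
#' @export
buildDRENet <- function(resnet = buildExtractor("resnet50_modified"),
                        densenet = buildExtractor("densenet201_modified"),
                        head = scnHead()) {
  stopifnot(resnet@arch == "resnet50_modified",
            densenet@arch == "densenet201_modified")
  new("DRENet", resnet = resnet, densenet = densenet, head = head)
}

#' @rdname featureDim
#' @export
setMethod("featureDim", "DRENet", function(x)
  x@resnet@featureDim + x@densenet@featureDim)

#' @rdname classLabels
#' @export
setMethod("classLabels", "DRENet", function(x) x@head@classLabels)

#' @rdname classLabels
#' @export
setMethod("classLabels", "SCNHead", function(x) x@classLabels)

setMethod("show", "DRENet", function(object) {
  cat("DRE-Net ensemble\n")
  cat(sprintf("  f1: %s (%d-d), f2: %s (%d-d) -> concat %d-d\n",
              object@resnet@arch, object@resnet@featureDim,
              object@densenet@arch, object@densenet@featureDim,
              featureDim(object)))
  cat("  SCN head classes:", paste(classLabels(object), collapse = ", "),
      "\n")
})

#' @rdname predictClasses
#' @export
setMethod("predictClasses", "DRENet", function(object, images, ...) {
  single <- is.array(images)
  if (single) images <- list(images)
  f1 <- extractFeatures(object@resnet, images)
  f2 <- extractFeatures(object@densenet, images)
  f <- concatFeatures(f1, f2)
  out <- lapply(seq_len(nrow(f)), function(i)
    softmaxProbs(fclForward(f[i, ], object@head)))
  if (single) return(out[[1L]])
  probs <- do.call(rbind, lapply(out, function(o) o@probabilities))
  data.frame(probs, label = vapply(out, function(o) o@label, ""),
             check.names = FALSE)
})

#' Save / load a DRE-Net model bundle
#'
#' Serializes a model to a directory: per-component parameter arrays as raw
#' binary doubles with a JSON metadata sidecar (shapes, architecture
#' identifiers, class-label order).
#'
#' @param model a [DRENet].
#' @param dir bundle directory.
#' @return `dir` (or, for `loadDRENet`, the restored [DRENet]).
#' @export
saveDRENet <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- list(resnet = model@resnet@params, densenet = model@densenet@params,
                head = list(W = model@head@weights, b = model@head@bias))
  meta <- list(classLabels = classLabels(model),
               resnetArch = model@resnet@arch,
               densenetArch = model@densenet@arch,
               resnetSeed = model@resnet@seed,
               densenetSeed = model@densenet@seed,
               shapes = lapply(comps, function(pl)
                 lapply(pl, function(p) dim(p) %||% length(p))))
  for (nm in names(comps)) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "wb")
    for (p in comps[[nm]]) writeBin(as.numeric(p), con)
    close(con)
  }
  jsonlite::write_json(meta, file.path(dir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname saveDRENet
#' @export
loadDRENet <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "bundle.json"),
                              simplifyVector = TRUE)
  readComp <- function(nm, template) {
    con <- file(file.path(dir, paste0(nm, ".bin")), "rb")
    on.exit(close(con))
    out <- template
    for (i in seq_along(template)) {
      p <- template[[i]]
      v <- readBin(con, "numeric", n = length(p))
      out[[i]] <- if (is.matrix(p)) matrix(v, nrow(p), ncol(p)) else v
    }
    out
  }
  rn <- buildExtractor(meta$resnetArch, seed = meta$resnetSeed)
  dn <- buildExtractor(meta$densenetArch, seed = meta$densenetSeed)
  rn@params <- readComp("resnet", rn@params)
  dn@params <- readComp("densenet", dn@params)
  k <- length(meta$classLabels)
  d <- rn@featureDim + dn@featureDim
  headT <- list(W = matrix(0, k, d), b = rep(0, k))
  headV <- readComp("head", headT)
  buildDRENet(rn, dn, scnHead(headV$W, headV$b, meta$classLabels))
}
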