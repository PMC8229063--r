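# Shared fixtures, memoised across test files: the two random-init
# backbones, a 120-image easy-mode phantom dataset, and the concat-feature
# cache the reduced-scale evaluations reuse. Everything is generated in code
# at test time.

.fixtures <- new.env()

CLS <- c("C1", "C2", "C3", "C4")

cachedExtractor <- function(arch) {
  if (is.null(.fixtures[[arch]]))
    .fixtures[[arch]] <- buildExtractor(
      arch, seed = if (arch == "resnet50_modified") 101L else 202L)
  .fixtures[[arch]]
}

phantomManifest <- function() {
  if (is.null(.fixtures$manifest)) {
    dir <- file.path(tempdir(), "drenet-phantoms")
    .fixtures$manifest <- generateDataset(
      c(C1 = 30L, C2 = 30L, C3 = 30L, C4 = 30L), dir, masterSeed = 11L)
  }
  .fixtures$manifest
}

phantomImages <- function() {
  if (is.null(.fixtures$images))
    .fixtures$images <- lapply(phantomManifest()$path, readImageFile)
  .fixtures$images
}

sharedFeatureCache <- function() {
  if (is.null(.fixtures$cache)) .fixtures$cache <- new.env()
  .fixtures$cache
}

# reduced-protocol closed-world runs over three seeds (frozen backbones, no
# augmentation, k = 2); heavy feature extraction happens once via the cache
closedWorldResults <- function() {
  if (is.null(.fixtures$closed)) {
    .fixtures$closed <- lapply(1:3, function(s)
      runClosedWorld(phantomManifest(),
                     trainConfig(epochsBackbone = 0L, seed = 5L + s),
                     k = 2L, seed = s,
                     resnet = cachedExtractor("resnet50_modified"),
                     densenet = cachedExtractor("densenet201_modified"),
                     ria = FALSE, images = phantomImages(),
                     featureCache = sharedFeatureCache()))
  }
  .fixtures$closed
}

openWorldResults <- function() {
  if (is.null(.fixtures$open)) {
    .fixtures$open <- lapply(1:3, function(s)
      runOpenWorld(phantomManifest(),
                   config = trainConfig(epochsBackbone = 0L, seed = 5L + s),
                   seed = s,
                   resnet = cachedExtractor("resnet50_modified"),
                   densenet = cachedExtractor("densenet201_modified"),
                   ria = FALSE, images = phantomImages(),
                   featureCache = sharedFeatureCache()))
  }
  .fixtures$open
}

# ---- independent template-matching oracle ---------------------------------
# Normalized cross-correlation against noiseless canonical class templates,
# maximised over a small grid of rotations and shifts. Entirely independent
# of the CNN pipeline.

.oracleShift <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  sr <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  sc <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[sr, sc] <- m[sr - dy, sc - dx]
  out
}

oracleTemplates <- function() {
  if (!is.null(.fixtures$templates)) return(.fixtures$templates)
  canonical <- function(cl) {
    sp <- phantomSpec(cl, seed = 0, noiseSd = 0, poseAngleDeg = 0,
                      poseOffsetPx = c(0L, 0L), foregroundIntensity = 255,
                      backgroundGradient = c(0, 0))
    renderPhantom(sp, antialias = FALSE)[, , 1]
  }
  .fixtures$templates <- lapply(CLS, function(cl) {
    t0 <- canonical(cl)
    v <- list()
    for (ang in seq(-15, 15, by = 5)) {
      tr <- rotateImage(t0, ang)
      for (dy in c(-8, -4, 0, 4, 8)) for (dx in c(-8, -4, 0, 4, 8)) {
        s <- .oracleShift(tr, dy, dx)
        v[[length(v) + 1L]] <- s - mean(s)
      }
    }
    v
  })
  .fixtures$templates
}

oracleClassify <- function(img) {
  tmpl <- oracleTemplates()
  a <- img - mean(img)
  scores <- vapply(tmpl, function(v)
    max(vapply(v, function(t)
      sum(a * t) / sqrt(sum(a^2) * sum(t^2)), 0)), 0)
  CLS[which.max(scores)]
}

oracleAccuracy <- function(difficulty, nPerClass) {
  correct <- 0L
  for (cl in CLS) for (i in seq_len(nPerClass)) {
    sp <- phantomSpec(cl, seed = i * 17L + match(cl, CLS),
                      difficulty = difficulty)
    if (oracleClassify(renderPhantom(sp)[, , 1]) == cl)
      correct <- correct + 1L
  }
  correct / (4 * nPerClass)
}
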