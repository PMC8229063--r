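# Synthetic implant radiograph generator. The phantoms are deliberately
# simple: a bright rod-shaped stem with a class-specific head on a vertical
# soft-tissue-like background gradient plus Gaussian intensity noise. Class
# C4 is rendered geometrically close to C2 (both hemispherical heads) to
# emulate the high Depuy/Zimmer inter-class similarity of the real data.

.CANVAS <- 224L

# class-conditional parameter ranges; columns lo/hi. In "easy" difficulty the
# geometry ranges of the four classes are pairwise disjoint; "hard" narrows
# the C2/C4 gap until the ranges nearly touch.
.phantomRanges <- function(difficulty = c("easy", "hard")) {
  difficulty <- match.arg(difficulty)
  r <- list(
    C1 = list(stemLength = c(70, 85), stemWidth = c(16, 19),
              headRadius = c(22, 26), headShape = "rounded", collar = TRUE),
    C2 = list(stemLength = c(135, 150), stemWidth = c(28, 32),
              headRadius = c(34, 38), headShape = "hemispherical",
              collar = FALSE),
    C3 = list(stemLength = c(55, 65), stemWidth = c(10, 13),
              headRadius = c(14, 17), headShape = "angled", collar = FALSE),
    C4 = list(stemLength = c(118, 132), stemWidth = c(21, 25),
              headRadius = c(29, 33), headShape = "hemispherical",
              collar = FALSE))
  if (difficulty == "hard") {
    r$C4$stemLength <- c(128, 140)
    r$C4$stemWidth <- c(25.5, 28)
    r$C4$headRadius <- c(32, 34)
  }
  r
}

# order-independent per-sample seed derived from (masterSeed, index)
.sampleSeed <- function(masterSeed, index) {
  as.integer((abs(as.numeric(masterSeed)) * 48271 + index * 104729 + 12345) %%
               2147483647)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' Construct an implant phantom specification
#'
#' Either pass explicit geometry or draw a class-typical spec from the
#' class-conditional parameter ranges (seeded, hence reproducible).
#'
#' @param classId `"C1"`..`"C4"`.
#' @param seed integer seed; controls both the sampled parameters and the
#'   rendered noise.
#' @param difficulty `"easy"` (disjoint class geometry ranges) or `"hard"`
#'   (the C2/C4 gap is narrowed).
#' @param stemLengthPx,stemWidthPx,headRadiusPx,headShape,collar optional
#'   explicit geometry overriding the sampled values.
#' @param foregroundIntensity,backgroundGradient,noiseSd,poseAngleDeg,poseOffsetPx
#'   optional intensity/pose overrides.
#' @return an [ImplantPhantomSpec].
#' @examples
#' spec <- phantomSpec("C1", seed = 1)
#' img <- renderPhantom(spec)
#' @export
phantomSpec <- function(classId, seed = 1L,
                        difficulty = c("easy", "hard"),
                        stemLengthPx = NULL, stemWidthPx = NULL,
                        headRadiusPx = NULL, headShape = NULL, collar = NULL,
                        foregroundIntensity = NULL,
                        backgroundGradient = NULL, noiseSd = NULL,
                        poseAngleDeg = NULL, poseOffsetPx = NULL) {
  difficulty <- match.arg(difficulty)
  stopifnot(classId %in% .CLASS_IDS)
  rng <- .phantomRanges(difficulty)[[classId]]
  draw <- .withSeed(seed, {
    list(stemLength = round(stats::runif(1, rng$stemLength[1],
                                         rng$stemLength[2])),
         stemWidth = round(stats::runif(1, rng$stemWidth[1],
                                        rng$stemWidth[2])),
         headRadius = round(stats::runif(1, rng$headRadius[1],
                                         rng$headRadius[2])),
         fg = round(stats::runif(1, 190, 230)),
         bgTop = round(stats::runif(1, 20, 50)),
         bgBot = round(stats::runif(1, 60, 100)),
         angle = stats::runif(1, -15, 15),
         off = round(stats::runif(2, -8, 8)))
  })
  new("ImplantPhantomSpec",
      classId = classId,
      stemLengthPx = as.integer(stemLengthPx %||% draw$stemLength),
      stemWidthPx = as.integer(stemWidthPx %||% draw$stemWidth),
      headRadiusPx = as.integer(headRadiusPx %||% draw$headRadius),
      headShape = headShape %||% rng$headShape,
      collar = collar %||% rng$collar,
      foregroundIntensity = foregroundIntensity %||% draw$fg,
      backgroundGradient = as.numeric(backgroundGradient %||%
                                        c(draw$bgTop, draw$bgBot)),
      noiseSd = noiseSd %||% 8,
      poseAngleDeg = poseAngleDeg %||% draw$angle,
      poseOffsetPx = as.integer(poseOffsetPx %||% draw$off),
      seed = as.integer(seed))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# membership test of implant silhouette at implant-frame coordinates
# (u = across stem, v = along stem; v = 0 at the head centre, growing down)
.phantomInside <- function(u, v, spec) {
  hw <- spec@stemWidthPx / 2
  r <- spec@headRadiusPx
  inside <- (abs(u) <= hw) & (v >= 0) & (v <= spec@stemLengthPx)
  inside <- inside | switch(spec@headShape,
    rounded = (u^2 + v^2) <= r^2,
    hemispherical = ((u^2 + v^2) <= r^2) & (v <= 0),
    angled = (v <= 0) & (v >= -r) & (abs(u) <= ((v + r) / r) * r * 0.9))
  if (spec@collar) {
    cw <- 2.2 * hw
    inside <- inside | ((abs(u) <= cw) & (v >= r * 0.4) & (v <= r * 0.4 + 6))
  }
  inside
}

#' Render a synthetic implant radiograph
#'
#' Draws the implant silhouette at its pose on the background gradient, adds
#' seeded Gaussian noise, and clips to \[0, 255\]. Rendering is fully
#' deterministic in the spec (including its seed).
#'
#' @param spec an [ImplantPhantomSpec].
#' @param antialias logical; smooth silhouette borders by 2x supersampling.
#'   With `antialias = FALSE`, zero noise and flat backgrounds the image is
#'   exactly binary.
#' @param returnMask also attach the silhouette mask and its bounding box as
#'   attributes `mask` and `bbox` (`c(rowmin, rowmax, colmin, colmax)`).
#' @return 224 x 224 x 3 numeric array with three identical channels,
#'   values in \[0, 255\].
#' @export
renderPhantom <- function(spec, antialias = TRUE, returnMask = FALSE) {
  validObject(spec)
  n <- .CANVAS
  # place the silhouette's vertical span centrally, plus the pose offset
  cy <- n / 2 - (spec@stemLengthPx - spec@headRadiusPx) / 2 +
    spec@poseOffsetPx[1L]
  cx <- n / 2 + spec@poseOffsetPx[2L]
  th <- spec@poseAngleDeg * pi / 180
  cth <- cos(th); sth <- sin(th)
  sub <- if (antialias) c(-0.25, 0.25) else 0
  alpha <- matrix(0, n, n)
  for (dr in sub) for (dc in sub) {
    rows <- matrix(seq_len(n) - 1 + dr - cy, n, n)        # row offsets
    cols <- matrix(seq_len(n) - 1 + dc - cx, n, n, byrow = TRUE)
    u <- cols * cth - rows * sth
    v <- rows * cth + cols * sth
    alpha <- alpha + .phantomInside(u, v, spec)
  }
  alpha <- alpha / length(sub)^2
  bg <- matrix(rep(seq(spec@backgroundGradient[1L],
                       spec@backgroundGradient[2L], length.out = n), n), n, n)
  img <- bg * (1 - alpha) + spec@foregroundIntensity * alpha
  if (spec@noiseSd > 0) {
    img <- img + .withSeed(spec@seed,
                           matrix(stats::rnorm(n * n, 0, spec@noiseSd), n, n))
  }
  img <- pmin(pmax(img, 0), 255)
  out <- array(img, c(n, n, 3L))
  if (returnMask) {
    mask <- alpha > 0.5
    idx <- which(mask, arr.ind = TRUE)
    attr(out, "mask") <- mask
    attr(out, "bbox") <- c(min(idx[, 1]), max(idx[, 1]),
                           min(idx[, 2]), max(idx[, 2]))
  }
  out
}

#' Generate a synthetic implant dataset on disk
#'
#' Renders one PNG per sample with per-sample seeds derived reproducibly from
#' `masterSeed` (order-independent), and writes a manifest CSV with header
#' `path,label,split,seed`.
#'
#' @param countsPerClass named vector (names `C1`..`C4` or the manufacturer
#'   labels) of non-negative sample counts.
#' @param outDir output directory (created if needed).
#' @param masterSeed integer master seed.
#' @param difficulty `"easy"` or `"hard"` (see [phantomSpec()]).
#' @param split split label(s) recorded in the manifest (recycled).
#' @param imageSize canvas size; only 224 is supported.
#' @return the manifest as a data.frame (invisibly also written to
#'   `file.path(outDir, "manifest.csv")`).
#' @export
generateDataset <- function(countsPerClass, outDir, masterSeed = 1L,
                            difficulty = c("easy", "hard"), split = "train",
                            imageSize = 224L) {
  difficulty <- match.arg(difficulty)
  stopifnot(imageSize == 224L)
  counts <- .normalizeCounts(countsPerClass)
  if (sum(counts) == 0L) {
    warning("zero total count: writing an empty manifest")
    man <- data.frame(path = character(0), label = character(0),
                      split = character(0), seed = integer(0))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(man, file.path(outDir, "manifest.csv"),
                     row.names = FALSE)
    return(man)
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  labels <- rep(names(counts), counts)
  n <- length(labels)
  split <- rep_len(split, n)
  seeds <- vapply(seq_len(n), function(i) .sampleSeed(masterSeed, i), 1L)
  paths <- file.path(outDir, sprintf("%s_%04d.png", labels, seq_len(n)))
  for (i in seq_len(n)) {
    spec <- phantomSpec(labels[i], seed = seeds[i], difficulty = difficulty)
    writeImageFile(renderPhantom(spec), paths[i])
  }
  man <- data.frame(path = paths, label = labels, split = split,
                    seed = seeds, stringsAsFactors = FALSE)
  utils::write.csv(man, file.path(outDir, "manifest.csv"), row.names = FALSE)
  man
}

.normalizeCounts <- function(countsPerClass) {
  nm <- names(countsPerClass)
  if (is.null(nm)) {
    stopifnot(length(countsPerClass) == 4L)
    nm <- .CLASS_IDS
  }
  nm[nm %in% .CLASS_LABELS] <- .CLASS_IDS[match(nm[nm %in% .CLASS_LABELS],
                                                .CLASS_LABELS)]
  stopifnot(all(nm %in% .CLASS_IDS), all(countsPerClass >= 0))
  out <- stats::setNames(rep(0L, 4L), .CLASS_IDS)
  out[nm] <- as.integer(countsPerClass)
  out
}
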