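# Rotational invariant augmentation (RIA): each training image is expanded
# into 36 in-plane poses by rotating about the image centre at 10 degree
# steps (the 0 degree pose -- the original image -- is one of the 36). Test
# images are never augmented.

#' Construct a rotation policy
#'
#' @param anglesDeg rotation angles in degrees; the default is the RIA set
#'   `seq(0, 350, by = 10)` (36 angles including 0).
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @param fillValue intensity for exposed corners (default 0, black).
#' @return a [RotationPolicy].
#' @export
rotationPolicy <- function(anglesDeg = seq(0, 350, by = 10),
                           interpolation = c("bilinear", "nearest"),
                           fillValue = 0) {
  new("RotationPolicy", anglesDeg = as.numeric(anglesDeg),
      interpolation = match.arg(interpolation),
      fillValue = as.numeric(fillValue))
}

#' Alternative benchmarking policy: random rotation and translation
#'
#' A labelled alternative augmentation policy (random in-plane rotation plus
#' translation) provided for benchmarking against RIA; it is not part of RIA
#' itself. Returned as a plain parameter list consumed by callers that
#' implement their own sampling.
#'
#' @param maxAngleDeg,maxShiftPx sampling bounds.
#' @return a list with class `"randomAugmentPolicy"`.
#' @export
randomAugmentPolicy <- function(maxAngleDeg = 180, maxShiftPx = 10) {
  structure(list(maxAngleDeg = maxAngleDeg, maxShiftPx = maxShiftPx),
            class = "randomAugmentPolicy")
}

#' Rotate an image about its centre
#'
#' Rotation preserves the canvas: content rotated outside the canvas is
#' discarded and exposed corners take the policy's fill value. Angles that
#' are multiples of 90 degrees are exact array reindexings (no interpolation
#' error); other angles use inverse-mapping interpolation about the
#' geometric centre ((H-1)/2, (W-1)/2).
#'
#' @param img H x W or H x W x C numeric array.
#' @param angleDeg rotation angle in degrees (counter-clockwise in matrix
#'   convention); must be finite.
#' @param policy a [RotationPolicy] (supplies interpolation and fill value).
#' @return array of identical dimensions.
#' @export
rotateImage <- function(img, angleDeg, policy = rotationPolicy()) {
  if (!is.finite(angleDeg)) stop("rotation angle must be finite")
  d <- dim(img)
  if (is.null(d)) stop("img must be a matrix or array")
  if (length(d) == 2L) {
    return(.rotate2d(img, angleDeg, policy))
  }
  out <- img
  for (ch in seq_len(d[3L]))
    out[, , ch] <- .rotate2d(img[, , ch], angleDeg, policy)
  out
}

.rotate2d <- function(m, angleDeg, policy) {
  a <- angleDeg %% 360
  if (isTRUE(all.equal(a, 0)) || isTRUE(all.equal(a, 360))) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (isTRUE(all.equal(a, 180))) return(m[nr:1, nc:1, drop = FALSE])
  if (nr == nc) {
    if (isTRUE(all.equal(a, 90))) return(t(m)[nr:1, , drop = FALSE])
    if (isTRUE(all.equal(a, 270))) return(t(m)[, nc:1, drop = FALSE])
  }
  th <- a * pi / 180
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  rows <- matrix(seq_len(nr) - 1 - cy, nr, nc)
  cols <- matrix(seq_len(nc) - 1 - cx, nr, nc, byrow = TRUE)
  # inverse mapping: source coordinates of each target pixel
  sy <- rows * cos(th) + cols * sin(th) + cy
  sx <- -rows * sin(th) + cols * cos(th) + cx
  inside <- sy >= 0 & sy <= nr - 1 & sx >= 0 & sx <= nc - 1
  out <- matrix(policy@fillValue, nr, nc)
  if (policy@interpolation == "nearest") {
    ri <- round(sy[inside]) + 1; ci <- round(sx[inside]) + 1
    out[inside] <- m[cbind(ri, ci)]
  } else {
    y0 <- pmin(floor(sy[inside]), nr - 2); x0 <- pmin(floor(sx[inside]), nc - 2)
    wy <- sy[inside] - y0; wx <- sx[inside] - x0
    v <- m[cbind(y0 + 1, x0 + 1)] * (1 - wy) * (1 - wx) +
      m[cbind(y0 + 2, x0 + 1)] * wy * (1 - wx) +
      m[cbind(y0 + 1, x0 + 2)] * (1 - wy) * wx +
      m[cbind(y0 + 2, x0 + 2)] * wy * wx
    out[inside] <- v
  }
  out
}

#' Expand images by rotational invariant augmentation
#'
#' @param images non-empty list of image arrays.
#' @param policy a [RotationPolicy]; the default produces 36 poses per image.
#' @return list of length `length(images) * length(policy@anglesDeg)`,
#'   ordered image-major then angle (the first output of each image is its
#'   0 degree pose when 0 is the first angle).
#' @export
riaExpand <- function(images, policy = rotationPolicy()) {
  if (length(images) == 0L) {
    warning("empty input: nothing to augment")
    return(list())
  }
  out <- vector("list", length(images) * length(policy@anglesDeg))
  i <- 0L
  for (img in images) {
    for (a in policy@anglesDeg) {
      i <- i + 1L
      out[[i]] <- rotateImage(img, a, policy)
    }
  }
  out
}

#' Expand a dataset manifest by RIA
#'
#' Applies RIA to the rows with `split == "train"` only; test rows pass
#' through untouched. Augmented rows record their source path and angle.
#'
#' @param manifest data.frame with columns `path`, `label`, `split`.
#' @param policy a [RotationPolicy].
#' @param outDir directory for augmented PNGs (filename suffix
#'   `_rot{angle}`).
#' @param writeImages logical; when `FALSE` only the augmented manifest is
#'   produced (rotated files are not materialized), which is sufficient for
#'   augmentation accounting.
#' @return augmented manifest data.frame with extra columns `sourcePath`
#'   and `angleDeg`.
#' @export
riaExpandManifest <- function(manifest, policy = rotationPolicy(),
                              outDir = NULL, writeImages = TRUE) {
  stopifnot(all(c("path", "label", "split") %in% names(manifest)))
  isTrain <- manifest$split == "train"
  if (writeImages && any(isTrain)) {
    missing <- manifest$path[isTrain][!file.exists(manifest$path[isTrain])]
    if (length(missing) > 0)
      stop("missing image file(s): ", paste(missing, collapse = ", "))
    if (is.null(outDir)) outDir <- dirname(manifest$path[isTrain][1L])
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  }
  pieces <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, , drop = FALSE]
    if (!isTRUE(isTrain[i])) {
      row$sourcePath <- NA_character_
      row$angleDeg <- NA_real_
      pieces[[length(pieces) + 1L]] <- row
      next
    }
    img <- if (writeImages) readImageFile(row$path) else NULL
    base <- sub("\\.png$", "", basename(row$path))
    for (a in policy@anglesDeg) {
      newRow <- row
      newRow$sourcePath <- row$path
      newRow$angleDeg <- a
      newRow$path <- file.path(if (is.null(outDir)) dirname(row$path)
                               else outDir,
                               sprintf("%s_rot%g.png", base, a))
      if (writeImages)
        writeImageFile(rotateImage(img, a, policy), newRow$path)
      pieces[[length(pieces) + 1L]] <- newRow
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
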