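# Image I/O and resampling helpers. The package-wide in-memory convention is
# a numeric H x W x 3 array with intensities in [0, 255]; PNG files store the
# same data scaled to [0, 1].

#' Read an image file
#'
#' Reads a PNG; greyscale images are replicated to three channels and any
#' alpha channel is dropped.
#'
#' @param path file path.
#' @return H x W x 3 numeric array with values in \[0, 255\].
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(x, c(dim(x), 1L))
  if (dim(x)[3L] >= 3L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3L] == 1L) x <- array(rep(x, 3L), c(dim(x)[1:2], 3L))
  x * 255
}

#' Write an image file
#' @param img H x W (x C) numeric array, values in \[0, 255\].
#' @param path destination PNG path.
#' @return `path`, invisibly.
#' @export
writeImageFile <- function(img, path) {
  png::writePNG(pmin(pmax(img / 255, 0), 1), path)
  invisible(path)
}

# bilinear resize of one 2-D matrix to nr x nc (used for activation maps)
.bilinearResize <- function(m, nr, nc) {
  sr <- nrow(m); sc <- ncol(m)
  if (sr == 1L && sc == 1L) return(matrix(m[1L], nr, nc))
  # map target pixel centres into source coordinates
  ys <- (seq_len(nr) - 0.5) / nr * sr - 0.5
  xs <- (seq_len(nc) - 0.5) / nc * sc - 0.5
  ys <- pmin(pmax(ys, 0), sr - 1); xs <- pmin(pmax(xs, 0), sc - 1)
  y0 <- pmin(floor(ys), sr - 2); x0 <- pmin(floor(xs), sc - 2)
  wy <- ys - y0; wx <- xs - x0
  a <- m[cbind(rep(y0 + 1, nc), rep(x0 + 1, each = nr))]
  b <- m[cbind(rep(y0 + 2, nc), rep(x0 + 1, each = nr))]
  c_ <- m[cbind(rep(y0 + 1, nc), rep(x0 + 2, each = nr))]
  d <- m[cbind(rep(y0 + 2, nc), rep(x0 + 2, each = nr))]
  wyr <- rep(wy, nc); wxr <- rep(wx, each = nr)
  matrix(a * (1 - wyr) * (1 - wxr) + b * wyr * (1 - wxr) +
           c_ * (1 - wyr) * wxr + d * wyr * wxr, nr, nc)
}
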