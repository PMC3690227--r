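# Image input/output. Images travel through the pipeline as plain numeric
# arrays `height x width x 3` with 8-bit channel values in [0, 255]; file
# I/O is delegated to EBImage (PNG, TIFF, JPEG).

#' Read and write 8-bit RGB images
#'
#' `readRGB()` reads a PNG/TIFF/JPEG file into the package's image
#' convention (numeric array `height x width x 3`, values 0-255; grayscale
#' files are replicated across the three channels). `writeRGB()` writes
#' such an array back to disk; the format follows the file extension.
#'
#' @param path image file path.
#' @param image numeric array `height x width x 3`, values in \[0, 255\].
#' @return `readRGB()` returns the image array; `writeRGB()` returns
#'   `path` invisibly.
#' @export
readRGB <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3L), c(dim(dat), 3L))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]   # drop alpha
  # EBImage stores x (width) as the first dimension; transpose to rows = y
  out <- aperm(dat, c(2L, 1L, 3L))
  array(roundHalfUp(clamp(out * 255, 0, 255)), dim(out))
}

#' @rdname readRGB
#' @export
writeRGB <- function(image, path) {
  assertRGB(image)
  dat <- aperm(image / 255, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(dat, colormode = "Color"), path)
  invisible(path)
}

#' Serialize tissue label maps as grayscale PNG
#'
#' Label maps are stored as single-channel 8-bit PNG with the fixed coding
#' 0 = BACKGROUND, 128 = NORMAL, 255 = ABNORMAL; `readLabelMap()` decodes
#' by nearest code, so the round trip is exact.
#'
#' @param labels a [TissueLabelMap-class].
#' @param path PNG file path.
#' @return `writeLabelMap()` returns `path` invisibly; `readLabelMap()`
#'   returns a [TissueLabelMap-class].
#' @export
writeLabelMap <- function(labels, path) {
  stopifnot(is(labels, "TissueLabelMap"))
  code <- c(0, 128, 255)[labels@labels + 1L] / 255
  EBImage::writeImage(EBImage::Image(t(matrix(code, nrow(labels@labels)))),
                      path)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- dat[, , 1L]
  v <- t(dat) * 255
  lab <- apply(abs(outer(as.numeric(v), c(0, 128, 255), "-")), 1L, which.min) - 1L
  newTissueLabelMap(matrix(lab, nrow(v), ncol(v)))
}

#' Overlay segmentation results on an image
#'
#' `overlayBoundaries()` paints the boundaries of abnormal tissue regions
#' onto an image (default yellow), reproducing the usual contour-on-slide
#' rendering. `overlayNuclei()` paints nucleus contours, red for normal
#' rod-like nuclei and green for abnormal ones.
#'
#' @param image RGB image array.
#' @param labels a [TissueLabelMap-class] matching the image size.
#' @param color length-3 RGB vector used for the contour.
#' @return the annotated RGB image array.
#' @export
overlayBoundaries <- function(image, labels, color = c(255, 255, 0)) {
  assertRGB(image)
  b <- extractBoundaries(labels)
  for (ch in 1:3) {
    pl <- image[, , ch]
    pl[b] <- color[ch]
    image[, , ch] <- pl
  }
  image
}

#' @rdname overlayBoundaries
#' @param nuclei a [NucleiResult-class] matching the image size.
#' @export
overlayNuclei <- function(image, nuclei) {
  assertRGB(image)
  stopifnot(is(nuclei, "NucleiResult"))
  feats <- nuclei@features
  if (nrow(feats) == 0L) return(image)
  normalIds <- feats$id[feats$label == "NORMAL_ROD"]
  mask <- nuclei@mask
  edge <- innerBoundary(mask > 0L)
  colSel <- ifelse(matrix(mask %in% normalIds, nrow(mask)), 1L, 2L)
  cols <- rbind(c(255, 0, 0), c(0, 255, 0))   # red = normal, green = abnormal
  for (ch in 1:3) {
    pl <- image[, , ch]
    pl[edge] <- cols[colSel[edge], ch]
    image[, , ch] <- pl
  }
  image
}
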