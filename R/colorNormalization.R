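# Statistics-transfer color normalization in the logarithmic lalphabeta
# space (Reinhard-style transfer; Ruderman decorrelated axes). Microscopic
# slides from different staining batches and acquisition sessions differ in
# global color and illumination; matching per-channel first and second
# moments in lalphabeta maps every image onto a common color distribution
# before segmentation.

# RGB -> LMS cone response matrix and its printed (rounded) inverse.
.RGB2LMS <- matrix(c(0.3811, 0.5783, 0.0402,
                     0.1967, 0.7244, 0.0782,
                     0.0241, 0.1288, 0.8444), 3, 3, byrow = TRUE)

.LMS2RGB <- matrix(c( 4.4679, -3.5873,  0.1193,
                     -1.2186,  2.3809, -0.1624,
                      0.0497, -0.2439,  1.2045), 3, 3, byrow = TRUE)

# log-LMS -> lalphabeta: diagonal scaling times the decorrelating mixing
# matrix, and its exact inverse.
.LMS2LAB <- diag(c(1 / sqrt(3), 1 / sqrt(6), 1 / sqrt(2))) %*%
  matrix(c(1,  1,  1,
           1,  1, -2,
           1, -1,  0), 3, 3, byrow = TRUE)

.LAB2LMS <- matrix(c(1,  1,  1,
                     1,  1, -1,
                     1, -2,  0), 3, 3, byrow = TRUE) %*%
  diag(c(sqrt(3) / 3, sqrt(6) / 6, sqrt(2) / 2))

# log clamp: channel values are clamped to >= 1/255 before the logarithm so
# pure black stays finite.
.LOG_EPS <- 1 / 255

#' Convert an RGB image to the logarithmic lalphabeta color space
#'
#' Applies the cone-response (LMS) transform, a natural logarithm with the
#' channel values clamped to at least 1/255 so black pixels remain finite,
#' and the decorrelating rotation onto the luminance (`l`) and two
#' chromatic opponent axes (`alpha`, `beta`).
#'
#' @param image numeric array `height x width x 3` with channel values in
#'   \[0, 255\].
#' @return numeric array `height x width x 3`, planes `l`, `alpha`, `beta`.
#' @examples
#' px <- array(c(255, 255, 255), c(1, 1, 3))
#' rgbToLab(px)        # alpha and beta are ~0 for a neutral pixel
#' @seealso [labToRgb()], [normalizeColors()]
#' @export
rgbToLab <- function(image) {
  assertRGB(image)
  d <- dim(image)
  p <- matrix(as.numeric(image), ncol = 3L)     # n x (R,G,B)
  lms <- p %*% t(.RGB2LMS)
  lms <- log(pmax(lms, .LOG_EPS))
  lab <- lms %*% t(.LMS2LAB)
  array(lab, d)
}

#' Convert a lalphabeta image back to 8-bit RGB
#'
#' Inverts [rgbToLab()]: rotates back to log-LMS, exponentiates, applies
#' the inverse cone-response matrix, clips to \[0, 255\] and rounds
#' half-up to integers. The forward/backward matrices are a rounded
#' inverse pair, so a round trip reproduces the input to within a few
#' 8-bit levels.
#'
#' @param lab numeric array `height x width x 3` (planes `l`, `alpha`,
#'   `beta`).
#' @return numeric array `height x width x 3` of integers in \[0, 255\].
#' @export
labToRgb <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("'lab' must be a height x width x 3 array")
  d <- dim(lab)
  p <- matrix(as.numeric(lab), ncol = 3L)
  lms <- exp(p %*% t(.LAB2LMS))
  rgb <- lms %*% t(.LMS2RGB)
  array(roundHalfUp(clamp(rgb, 0, 255)), d)
}

#' Per-channel mean and standard deviation of a lalphabeta image
#'
#' @param lab numeric array `height x width x 3` as returned by
#'   [rgbToLab()].
#' @return list with numeric vectors `means` and `sds`, each named
#'   (`l`, `alpha`, `beta`). Standard deviations use the sample (n - 1)
#'   convention; a constant channel has sd 0.
#' @export
channelStats <- function(lab) {
  if (!is.array(lab) || length(dim(lab)) != 3L || dim(lab)[3] != 3L)
    stop("'lab' must be a height x width x 3 array")
  p <- matrix(as.numeric(lab), ncol = 3L)
  n <- nrow(p)
  m <- colMeans(p)
  s <- if (n > 1L) apply(p, 2L, stats::sd) else c(0, 0, 0)
  names(m) <- names(s) <- c("l", "alpha", "beta")
  list(means = m, sds = s)
}

#' Build a target color profile from a set of standard images
#'
#' Computes the lalphabeta channel statistics of each target image and
#' averages each of the six statistics arithmetically across images.
#' Target images are chosen by the operator for high contrast and dark
#' blue nuclei; the profile is computed once and reused for every input.
#'
#' @param targets a list of RGB image arrays, or a character vector of
#'   image file paths (read with [readRGB()]).
#' @return a [TargetProfile-class] object.
#' @examples
#' img <- array(rep(c(200, 120, 140), each = 16), c(4, 4, 3))
#' img[1, 1, ] <- c(90, 60, 120)
#' buildTargetProfile(list(img))
#' @export
buildTargetProfile <- function(targets) {
  if (is.character(targets)) targets <- lapply(targets, readRGB)
  if (!is.list(targets) || length(targets) == 0L)
    stop("'targets' must be a non-empty list of images or file paths")
  stats <- lapply(targets, function(img) channelStats(rgbToLab(img)))
  m <- rowMeans(vapply(stats, `[[`, numeric(3), "means"))
  s <- rowMeans(vapply(stats, `[[`, numeric(3), "sds"))
  if (any(s <= 0))
    stop("degenerate target set: averaged standard deviation is zero on ",
         "channel(s) ", paste(c("l", "alpha", "beta")[s <= 0], collapse = ", "))
  new("TargetProfile", means = m, sds = s, nTargets = length(targets))
}

#' Moment matching in lalphabeta space (pre-inversion)
#'
#' The core of the statistics transfer: subtracts the source-image channel
#' means, rescales each channel's spread to the target, and adds the
#' target means. The returned lalphabeta image has channel statistics
#' exactly equal to the profile (up to floating point); [normalizeColors()]
#' is this operation followed by the lossy inversion to 8-bit RGB.
#'
#' @inheritParams normalizeColors
#' @return numeric array `height x width x 3` in lalphabeta space.
#' @export
normalizeLab <- function(image, profile,
                         onZeroSd = c("error", "identity")) {
  onZeroSd <- match.arg(onZeroSd)
  stopifnot(is(profile, "TargetProfile"))
  validObject(profile)
  lab <- rgbToLab(image)
  st <- channelStats(lab)
  scale <- profile@sds / st$sds
  if (any(!is.finite(scale))) {
    if (onZeroSd == "error")
      stop("source image has zero spread on channel(s) ",
           paste(c("l", "alpha", "beta")[st$sds == 0], collapse = ", "),
           "; pass onZeroSd = \"identity\" to keep such channels unscaled")
    scale[!is.finite(scale)] <- 1
  }
  d <- dim(lab)
  p <- matrix(as.numeric(lab), ncol = 3L)
  p <- sweep(p, 2L, st$means, "-")
  p <- sweep(p, 2L, scale, "*")
  p <- sweep(p, 2L, profile@means, "+")
  array(p, d)
}

#' Normalize an image to a target color profile
#'
#' Statistics transfer in lalphabeta space: the image is mapped so that,
#' before the inversion back to RGB, its per-channel mean and standard
#' deviation equal the target profile exactly. The result is clipped to
#' \[0, 255\] and quantized to 8-bit levels.
#'
#' A constant channel in the source image has zero spread and cannot be
#' rescaled; by default this is an error, while `onZeroSd = "identity"`
#' leaves such channels unscaled (shift only).
#'
#' @inheritParams rgbToLab
#' @param profile a [TargetProfile-class].
#' @param onZeroSd `"error"` (default) or `"identity"`; behaviour when a
#'   source channel has zero standard deviation.
#' @return normalized RGB image array (integers in \[0, 255\]).
#' @seealso [buildTargetProfile()]
#' @export
normalizeColors <- function(image, profile,
                            onZeroSd = c("error", "identity")) {
  labToRgb(normalizeLab(image, profile, onZeroSd))
}

#' Read and write target profiles
#'
#' A [TargetProfile-class] serializes to a small YAML document (six
#' statistics plus the number of target images) so that a profile built
#' once can be reused across runs.
#'
#' @param profile a [TargetProfile-class].
#' @param path file path of the YAML document.
#' @return `writeTargetProfile()` returns `path` invisibly;
#'   `readTargetProfile()` returns the [TargetProfile-class].
#' @export
writeTargetProfile <- function(profile, path) {
  stopifnot(is(profile, "TargetProfile"))
  yaml::write_yaml(list(
    means = as.list(profile@means),
    sds = as.list(profile@sds),
    nTargets = profile@nTargets), path)
  invisible(path)
}

#' @rdname writeTargetProfile
#' @export
readTargetProfile <- function(path) {
  x <- yaml::read_yaml(path)
  new("TargetProfile",
      means = unlist(x$means)[c("l", "alpha", "beta")],
      sds = unlist(x$sds)[c("l", "alpha", "beta")],
      nTargets = as.integer(x$nTargets))
}
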