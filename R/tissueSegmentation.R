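# Three-step color segmentation of normalized pulley images. Normal
# collagenous tissue is pink (low hue), metaplastic tissue blue/purple
# (high hue), the empty slide near-white. Step 1 thresholds the hue
# histogram (Otsu) into rough foreground and background; step 2 recovers
# residual purple pixels from the rough background via a G-channel Otsu;
# step 3 splits the complete foreground into normal and abnormal tissue on
# hue; a 9 x 9 majority rank filter removes fragmented boundary labels.

#' Hue channel of an RGB image
#'
#' Computes the HSI hue angle per pixel,
#' \deqn{\theta = \arccos\frac{\frac12[(R-G)+(R-B)]}{\sqrt{(R-G)^2+(R-B)(G-B)}}}
#' with \eqn{H = \theta} when \eqn{B \le G} and \eqn{H = 360 - \theta}
#' otherwise. Achromatic pixels (R = G = B) have no defined hue and are
#' returned as `NA`.
#'
#' @inheritParams rgbToLab
#' @return numeric matrix of hue angles in degrees \[0, 360), `NA` where
#'   undefined.
#' @examples
#' rgbToHue(array(c(255, 0, 0), c(1, 1, 3)))   # pure red: 0
#' rgbToHue(array(c(0, 0, 255), c(1, 1, 3)))   # pure blue: 240
#' @export
rgbToHue <- function(image) {
  assertRGB(image)
  d <- dim(image)
  R <- matrix(image[, , 1], d[1], d[2])
  G <- matrix(image[, , 2], d[1], d[2])
  B <- matrix(image[, , 3], d[1], d[2])
  num <- 0.5 * ((R - G) + (R - B))
  den2 <- (R - G)^2 + (R - B) * (G - B)
  H <- matrix(NA_real_, nrow(R), ncol(R))
  ok <- den2 > 0
  theta <- acos(clamp(num[ok] / sqrt(den2[ok]), -1, 1)) * 180 / pi
  H[ok] <- ifelse(B[ok] <= G[ok], theta, 360 - theta)
  H[H >= 360] <- 0
  H
}

# hue angle [0, 360) -> integer level [0, 255] for histogram thresholding
hueToLevel <- function(h) as.integer(roundHalfUp(h * 255 / 360))

#' Otsu threshold of an 8-bit value population
#'
#' Exhaustive scan of every threshold k = 0..255 maximizing the interclass
#' variance \eqn{\sigma_B^2(k) = \omega_0\omega_1(\mu_0-\mu_1)^2}, where
#' class 0 collects values `<= k`. Ties are broken towards the smallest k.
#'
#' @param values integer vector with values in \[0, 255\] (`NA` dropped).
#' @return list with `kStar` (optimal threshold), `sigmaBSq` (interclass
#'   variance at the optimum), `omega0`, `omega1` (class probabilities)
#'   and `mu0`, `mu1` (class means).
#' @examples
#' otsuThreshold(c(rep(10, 100), rep(200, 100)))$kStar   # 10 (tie-break)
#' @export
otsuThreshold <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no values to threshold")
  values <- as.integer(roundHalfUp(values))
  if (min(values) < 0L || max(values) > 255L)
    stop("values must lie in [0, 255]")
  if (length(unique(values)) < 2L)
    stop("all values identical: no separating threshold exists")
  cnt <- tabulate(values + 1L, nbins = 256L)
  p <- cnt / sum(cnt)
  levels <- 0:255
  w0 <- cumsum(p)                       # P(value <= k)
  mcum <- cumsum(p * levels)
  mT <- mcum[256L]
  valid <- w0 > 0 & w0 < 1
  sigma <- rep(-Inf, 256L)
  sigma[valid] <- (mT * w0[valid] - mcum[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  kStar <- which.max(sigma) - 1L        # which.max takes the first maximum
  i <- kStar + 1L
  list(kStar = kStar,
       sigmaBSq = sigma[i],
       omega0 = w0[i], omega1 = 1 - w0[i],
       mu0 = mcum[i] / w0[i],
       mu1 = (mT - mcum[i]) / (1 - w0[i]))
}

# Low class of an Otsu split with an orientation guard: the biological
# expectation is that the class of interest (pink+purple tissue on hue,
# purple on G) is the LOW class; if the low class swallows > 95% of the
# population the split is assumed inverted and is flipped.
.lowClass <- function(values, guard = 0.95) {
  ot <- otsuThreshold(values)
  low <- as.integer(roundHalfUp(values)) <= ot$kStar
  if (mean(low) > guard) low <- !low
  list(mask = low, kStar = ot$kStar)
}

#' Foreground (tissue) mask of a normalized image
#'
#' Step 1 applies Otsu thresholding to the hue histogram (hue scaled
#' linearly to \[0, 255\]); the low-hue class is the rough foreground
#' (pink tissue plus most of the purple). Pixels with undefined hue join
#' the rough background. Step 2 restricts attention to the rough
#' background and applies a second Otsu threshold on the G channel; the
#' low-G class there is residual purple tissue and is merged into the
#' foreground. If either split would place more than 95% of its
#' population in the low class the orientation is assumed inverted and
#' flipped. If the step-2 population carries fewer than two distinct
#' values nothing is recovered.
#'
#' @inheritParams rgbToLab
#' @param hue hue matrix from [rgbToHue()] computed on `image`; computed
#'   on the fly if missing.
#' @return logical matrix, `TRUE` = tissue foreground. Attributes
#'   `kHue` and `kG` record the chosen thresholds (`kG` is `NA` when
#'   step 2 was skipped).
#' @export
segmentForeground <- function(image, hue = rgbToHue(image)) {
  assertRGB(image)
  lev <- hueToLevel(hue)
  defined <- !is.na(lev)
  if (sum(!duplicated(lev[defined])) < 2L)
    stop("degenerate hue histogram: all defined hues identical")
  s1 <- .lowClass(lev[defined])
  fg <- matrix(FALSE, nrow(hue), ncol(hue))
  fg[which(defined)[s1$mask]] <- TRUE
  roughBg <- !fg
  g <- matrix(image[, , 2], nrow(fg))[roughBg]
  kG <- NA_integer_
  if (length(unique(as.integer(roundHalfUp(g)))) >= 2L) {
    s2 <- .lowClass(g)
    recovered <- roughBg
    recovered[roughBg] <- s2$mask
    fg <- fg | recovered
    kG <- s2$kStar
  }
  structure(fg, kHue = s1$kStar, kG = kG)
}

#' Split the tissue foreground into normal and abnormal regions
#'
#' Applies Otsu thresholding to the scaled hue values of foreground pixels
#' only: normal pink tissue has low hue, abnormal blue/purple tissue high
#' hue. Foreground pixels at or below the threshold become NORMAL, the
#' rest ABNORMAL; non-foreground pixels stay BACKGROUND. Foreground pixels
#' with undefined hue enter the histogram at level 0. If the foreground
#' carries fewer than two distinct hue levels the whole foreground is
#' NORMAL (an all-normal specimen is not an error).
#'
#' @param hue hue matrix from [rgbToHue()].
#' @param foreground logical tissue mask from [segmentForeground()].
#' @return a [TissueLabelMap-class].
#' @export
segmentAbnormal <- function(hue, foreground) {
  stopifnot(identical(dim(hue), dim(foreground)))
  if (!any(foreground)) stop("empty foreground")
  lev <- hueToLevel(hue)
  lev[is.na(lev)] <- 0L
  fgLev <- lev[foreground]
  lab <- matrix(.BACKGROUND, nrow(hue), ncol(hue))
  k <- NA_integer_
  if (length(unique(fgLev)) < 2L) {
    lab[foreground] <- .NORMAL
  } else {
    k <- otsuThreshold(fgLev)$kStar
    lab[foreground] <- ifelse(fgLev <= k, .NORMAL, .ABNORMAL)
  }
  newTissueLabelMap(lab, thresholds = list(kAbnormal = k))
}

#' Majority rank filter on a label map
#'
#' Replaces every pixel by the modal label over an odd `window` x `window`
#' neighbourhood (the window is cropped at the image borders, no padding),
#' removing fragmented labels along region boundaries. Ties are broken by
#' the fixed priority BACKGROUND > NORMAL > ABNORMAL.
#'
#' @param labels a [TissueLabelMap-class].
#' @param window odd window side length (default 9).
#' @return the filtered [TissueLabelMap-class].
#' @export
rankFilter <- function(labels, window = 9L) {
  stopifnot(is(labels, "TissueLabelMap"))
  if (window %% 2L != 1L || window < 3L)
    stop("'window' must be an odd integer >= 3")
  r <- (window - 1L) %/% 2L
  m <- labels@labels
  cB <- boxSum((m == .BACKGROUND) * 1, r)
  cN <- boxSum((m == .NORMAL) * 1, r)
  cA <- boxSum((m == .ABNORMAL) * 1, r)
  out <- matrix(.ABNORMAL, nrow(m), ncol(m))
  out[cN >= cA] <- .NORMAL
  out[cB >= pmax(cN, cA)] <- .BACKGROUND
  newTissueLabelMap(out, thresholds = labels@thresholds)
}

#' Boundary pixels of abnormal tissue regions
#'
#' A pixel is on the boundary if it is labeled ABNORMAL and at least one
#' of its 4-neighbours is not ABNORMAL (pixels on the image frame count
#' as boundary).
#'
#' @param labels a [TissueLabelMap-class].
#' @return logical matrix of boundary pixels.
#' @export
extractBoundaries <- function(labels) {
  stopifnot(is(labels, "TissueLabelMap"))
  innerBoundary(labels@labels == .ABNORMAL)
}

#' Full three-step tissue segmentation
#'
#' Runs hue conversion, the two-step foreground extraction, the
#' normal/abnormal split and the majority rank filter on a
#' color-normalized image, producing the final three-class label map.
#' The chosen thresholds of every step are recorded in the result for
#' audit.
#'
#' @inheritParams rgbToLab
#' @param window rank filter window (odd, default 9).
#' @return a [TissueLabelMap-class].
#' @seealso [segmentForeground()], [segmentAbnormal()], [rankFilter()]
#' @export
segmentTissue <- function(image, window = 9L) {
  hue <- rgbToHue(image)
  fg <- segmentForeground(image, hue)
  lab <- segmentAbnormal(hue, fg)
  lab@thresholds <- c(list(kHue = attr(fg, "kHue"), kG = attr(fg, "kG")),
                      lab@thresholds)
  rankFilter(lab, window)
}
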