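# Nuclei segmentation and shape-based classification. Nuclei are the
# darkest structures of the R channel of a normalized image; an adaptive
# ("active") double threshold segments them by hysteresis region growing,
# and simple shape rules separate normal rod-like fibroblast nuclei from
# abnormal round chondrocyte-like nuclei and multinucleus clusters.

#' Parameters of the active double threshold
#'
#' The base intensity of an image is the mean of its `nLowest` smallest
#' R-channel values. Seed pixels lie at or below base + `offsetSeed`;
#' region growing from the seeds is restricted to pixels at or below
#' base + `offsetGrow`. The two offsets are empirical intensity margins
#' calibrated on normalized images.
#'
#' @param nLowest number of lowest-intensity pixels averaged into the
#'   base intensity (default 10).
#' @param offsetSeed seed threshold offset above the base (default 30).
#' @param offsetGrow growth restriction offset above the base
#'   (default 45); must exceed `offsetSeed`.
#' @return a named list of validated parameters.
#' @export
doubleThresholdParams <- function(nLowest = 10L, offsetSeed = 30,
                                  offsetGrow = 45) {
  if (nLowest < 1L) stop("'nLowest' must be >= 1")
  if (!(offsetSeed > 0 && offsetGrow > offsetSeed))
    stop("offsets must satisfy 0 < offsetSeed < offsetGrow")
  list(nLowest = as.integer(nLowest), offsetSeed = offsetSeed,
       offsetGrow = offsetGrow)
}

#' Shape rules of the nucleus classifier
#'
#' A region is a normal rod-like nucleus iff its circularity is below
#' `circularityMax`, its centroid-to-boundary distance ratio exceeds
#' `elongationMin`, and its area is below `areaMax`. Any other region is
#' abnormal: a single round nucleus when smaller than `areaMax`, else a
#' multinucleus cluster. The defaults were tuned for 2560 x 1920 pulley
#' acquisitions.
#'
#' @param circularityMax maximum circularity of a rod (default 0.95).
#' @param elongationMin minimum dMax/dMin ratio of a rod (default 3).
#' @param areaMax area bound separating single nuclei from clusters,
#'   in pixels (default 2000).
#' @return a named list of validated rules.
#' @export
classifierRules <- function(circularityMax = 0.95, elongationMin = 3,
                            areaMax = 2000) {
  if (any(c(circularityMax, elongationMin, areaMax) <= 0))
    stop("all classifier rules must be strictly positive")
  list(circularityMax = circularityMax, elongationMin = elongationMin,
       areaMax = areaMax)
}

#' Active double-threshold nuclei segmentation
#'
#' Computes the adaptive base intensity (mean of the `nLowest` darkest
#' pixels), thresholds seed pixels at base + `offsetSeed`, and grows
#' 8-connected regions from the seeds into pixels at or below
#' base + `offsetGrow`. The returned mask is the union of all grown
#' regions; with no seed pixels the mask is empty (not an error).
#'
#' @param channel single-channel numeric matrix (the R channel of a
#'   normalized image), values in \[0, 255\].
#' @param params parameter list from [doubleThresholdParams()].
#' @return logical matrix; attribute `base` records the base intensity.
#' @export
activeDoubleThreshold <- function(channel, params = doubleThresholdParams()) {
  if (!is.matrix(channel) || !is.numeric(channel))
    stop("'channel' must be a numeric matrix")
  if (length(channel) < params$nLowest)
    stop("image has fewer pixels than 'nLowest'")
  base <- mean(sort(as.numeric(channel),
                    partial = params$nLowest)[seq_len(params$nLowest)])
  seeds <- channel <= base + params$offsetSeed
  grow <- channel <= base + params$offsetGrow
  out <- matrix(FALSE, nrow(channel), ncol(channel))
  if (any(seeds)) {
    comp <- labelComponents8(grow)
    keep <- unique(comp[seeds])
    out <- matrix(comp %in% keep[keep > 0L], nrow(channel))
  }
  structure(out, base = base)
}

#' Shape features of nucleus regions
#'
#' Labels the 8-connected components of a segmentation mask and measures,
#' for every component of at least `minArea` pixels: area, perimeter
#' (Moore-traced outer contour with diagonal steps weighted sqrt(2)),
#' circularity \eqn{4\pi A / P^2}, centroid, and the maximum/minimum
#' Euclidean distance from the centroid to the inner boundary pixels.
#' Regions so concave that the centroid falls outside the pixel set are
#' measured as stated and flagged in `concaveCentroid`.
#'
#' @param mask logical matrix (segmentation mask) or an integer label
#'   matrix of precomputed components.
#' @param minArea smallest component retained, in pixels (default 5);
#'   smaller components are noise and carry no meaningful shape.
#' @return list with `labels` (integer component matrix) and `features`
#'   (data.frame: `id`, `area`, `perimeter`, `circularity`, `centroidX`,
#'   `centroidY`, `dMax`, `dMin`, `concaveCentroid`).
#' @export
shapeFeatures <- function(mask, minArea = 5L) {
  lab <- if (is.logical(mask)) labelComponents8(mask) else {
    storage.mode(mask) <- "integer"; mask
  }
  ids <- sort(unique(lab[lab > 0L]))
  bnd <- innerBoundary(lab > 0L)
  rows <- row(lab)[lab > 0L]; cols <- col(lab)[lab > 0L]
  labv <- lab[lab > 0L]; bndv <- bnd[lab > 0L]
  feat <- lapply(ids, function(id) {
    sel <- labv == id
    r <- rows[sel]; cc <- cols[sel]
    area <- length(r)
    if (area < minArea) return(NULL)
    cy <- mean(r); cx <- mean(cc)
    onB <- bndv[sel]
    d <- sqrt((r[onB] - cy)^2 + (cc[onB] - cx)^2)
    per <- tracePerimeter(r, cc)
    concave <- !any(r == round(cy) & cc == round(cx))
    data.frame(id = id, area = area, perimeter = per,
               circularity = 4 * pi * area / per^2,
               centroidX = cx, centroidY = cy,
               dMax = max(d), dMin = max(min(d), .Machine$double.eps),
               concaveCentroid = concave)
  })
  feat <- do.call(rbind, feat)
  if (is.null(feat))
    feat <- data.frame(id = integer(), area = numeric(),
                       perimeter = numeric(), circularity = numeric(),
                       centroidX = numeric(), centroidY = numeric(),
                       dMax = numeric(), dMin = numeric(),
                       concaveCentroid = logical())
  keepIds <- feat$id
  lab[!(lab %in% keepIds)] <- 0L
  rownames(feat) <- NULL
  list(labels = lab, features = feat)
}

#' Rule-based nucleus classification
#'
#' Applies the shape rules to a feature table: a region is `NORMAL_ROD`
#' iff circularity < `circularityMax`, dMax/dMin > `elongationMin` and
#' area < `areaMax`; otherwise `ABNORMAL_ROUND` when area < `areaMax`,
#' else `ABNORMAL_CLUSTER`. Cluster regions receive an estimated nucleus
#' count: the region area divided by the mean area of the single round
#' nuclei of the same image, rounded half-up with a floor of 1. When an
#' image has no single round nucleus each cluster counts as 1, with a
#' warning.
#'
#' @param features feature data.frame from [shapeFeatures()].
#' @param rules rule list from [classifierRules()].
#' @return the feature data.frame with columns `label` and `nNuclei`
#'   added.
#' @export
classifyNuclei <- function(features, rules = classifierRules()) {
  f <- features
  if (nrow(f) == 0L) {
    f$label <- character(); f$nNuclei <- integer(); return(f)
  }
  isRod <- f$circularity < rules$circularityMax &
    f$dMax / f$dMin > rules$elongationMin &
    f$area < rules$areaMax
  f$label <- ifelse(isRod, "NORMAL_ROD",
                    ifelse(f$area < rules$areaMax,
                           "ABNORMAL_ROUND", "ABNORMAL_CLUSTER"))
  meanRound <- mean(f$area[f$label == "ABNORMAL_ROUND"])
  f$nNuclei <- 1L
  cl <- f$label == "ABNORMAL_CLUSTER"
  if (any(cl)) {
    if (is.nan(meanRound)) {
      warning("no single round nuclei found; counting each cluster as 1 nucleus")
    } else {
      f$nNuclei[cl] <- countClusterNuclei(f$area[cl], meanRound)
    }
  }
  attr(f, "meanRoundArea") <- if (is.nan(meanRound)) NA_real_ else meanRound
  f
}

#' Nucleus count of a multinucleus cluster
#'
#' @param area cluster area(s) in pixels.
#' @param meanSingleRoundArea mean area of the single abnormal round
#'   nuclei of the same image; must be > 0.
#' @return integer count(s): `area / meanSingleRoundArea` rounded
#'   half-up, never below 1.
#' @examples
#' countClusterNuclei(5000, 500)   # 10
#' countClusterNuclei(1250, 500)   # 3 (round half-up)
#' @export
countClusterNuclei <- function(area, meanSingleRoundArea) {
  if (!is.finite(meanSingleRoundArea) || meanSingleRoundArea <= 0)
    stop("'meanSingleRoundArea' must be > 0")
  pmax(1L, as.integer(roundHalfUp(area / meanSingleRoundArea)))
}

#' Summarize classified nuclei
#'
#' @param features classified feature data.frame from [classifyNuclei()].
#' @return named integer vector `c(normal, abnormal)`: normal counts the
#'   `NORMAL_ROD` regions; abnormal counts the `ABNORMAL_ROUND` regions
#'   plus the expanded `nNuclei` of every cluster.
#' @export
summarizeNuclei <- function(features) {
  if (nrow(features) == 0L) return(c(normal = 0L, abnormal = 0L))
  c(normal = sum(features$label == "NORMAL_ROD"),
    abnormal = sum(features$label == "ABNORMAL_ROUND") +
      sum(features$nNuclei[features$label == "ABNORMAL_CLUSTER"]))
}

#' Segment and classify the nuclei of one image
#'
#' Convenience wrapper running [activeDoubleThreshold()] on the R channel,
#' [shapeFeatures()] and [classifyNuclei()], returning a
#' [NucleiResult-class].
#'
#' @param image a normalized RGB image array, or a single-channel numeric
#'   matrix (a standalone grayscale input) used directly.
#' @param params double-threshold parameters
#'   ([doubleThresholdParams()]).
#' @param rules classifier rules ([classifierRules()]).
#' @param minArea smallest retained component (pixels).
#' @return a [NucleiResult-class].
#' @export
analyzeNuclei <- function(image, params = doubleThresholdParams(),
                          rules = classifierRules(), minArea = 5L) {
  channel <- if (is.matrix(image)) image else {
    assertRGB(image)
    matrix(image[, , 1], dim(image)[1], dim(image)[2])
  }
  mask <- activeDoubleThreshold(channel, params)
  sf <- shapeFeatures(mask, minArea)
  f <- classifyNuclei(sf$features, rules)
  cnt <- summarizeNuclei(f)
  new("NucleiResult", mask = sf$labels, features = f,
      nNormal = as.integer(cnt[["normal"]]),
      nAbnormal = as.integer(cnt[["abnormal"]]),
      meanRoundArea = if (is.null(attr(f, "meanRoundArea"))) NA_real_
                      else attr(f, "meanRoundArea"),
      baseIntensity = attr(mask, "base"))
}

#' Write a per-nucleus feature table to CSV
#'
#' @param nuclei a [NucleiResult-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeNucleiCSV <- function(nuclei, path) {
  stopifnot(is(nuclei, "NucleiResult"))
  utils::write.csv(nuclei@features, path, row.names = FALSE)
  invisible(path)
}
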