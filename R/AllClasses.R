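#' @import methods
NULL

#' Target color profile for statistics-transfer normalization
#'
#' Per-channel mean and standard deviation in the logarithmic lalphabeta
#' color space, averaged over an operator-chosen set of target images. A
#' profile is computed once and then reused to normalize every input image.
#'
#' @slot means named numeric vector (\code{l}, \code{alpha}, \code{beta}):
#'   averaged channel means.
#' @slot sds named numeric vector (\code{l}, \code{alpha}, \code{beta}):
#'   averaged channel standard deviations; all strictly positive.
#' @slot nTargets number of target images averaged.
#'
#' @seealso [buildTargetProfile()], [normalizeColors()],
#'   [writeTargetProfile()]
#' @export
setClass("TargetProfile",
  representation(means = "numeric", sds = "numeric", nTargets = "integer"),
  validity = function(object) {
    nm <- c("l", "alpha", "beta")
    if (!identical(names(object@means), nm) ||
        !identical(names(object@sds), nm))
      return("'means' and 'sds' must be named numeric vectors (l, alpha, beta)")
    if (anyNA(object@means) || anyNA(object@sds) ||
        any(!is.finite(c(object@means, object@sds))))
      return("profile statistics must be finite")
    if (any(object@sds <= 0))
      return("degenerate profile: all channel standard deviations must be > 0")
    if (length(object@nTargets) != 1L || object@nTargets < 1L)
      return("'nTargets' must be a positive integer")
    TRUE
  })

#' Three-class tissue label map
#'
#' Per-pixel classification of a pulley section into empty background,
#' normal (pink, collagenous) tissue and abnormal (blue/purple,
#' fibrocartilaginous metaplastic) tissue. Every pixel carries exactly one
#' of the three labels.
#'
#' @slot labels integer matrix; 0 = BACKGROUND, 1 = NORMAL, 2 = ABNORMAL.
#' @slot thresholds list of the automatically chosen thresholds (scaled-hue
#'   Otsu cut for foreground, G-channel Otsu cut for purple recovery,
#'   scaled-hue Otsu cut for the normal/abnormal split), kept for audit.
#'
#' @seealso [segmentTissue()], [classAreas()], [labelMatrix()]
#' @export
setClass("TissueLabelMap",
  representation(labels = "matrix", thresholds = "list"),
  validity = function(object) {
    v <- object@labels
    if (!is.numeric(v) || anyNA(v))
      return("'labels' must be a numeric matrix without NAs")
    if (!all(v %in% 0:2))
      return("labels must be 0 (BACKGROUND), 1 (NORMAL) or 2 (ABNORMAL)")
    TRUE
  })

#' Segmented and classified nuclei of one image
#'
#' Result of active double-threshold nuclei segmentation followed by the
#' rule-based shape classifier. Each connected component is one region;
#' multinucleus clusters carry an estimated nucleus count derived from the
#' mean single round-nucleus area.
#'
#' @slot mask integer matrix of region ids (0 = background), 8-connected
#'   components of the segmentation mask.
#' @slot features data.frame with one row per retained region: \code{id},
#'   \code{area}, \code{perimeter}, \code{circularity}, \code{centroidX},
#'   \code{centroidY}, \code{dMax}, \code{dMin}, \code{concaveCentroid},
#'   \code{label}, \code{nNuclei}.
#' @slot nNormal total count of normal rod-like nuclei.
#' @slot nAbnormal total count of abnormal nuclei (round singles plus
#'   cluster-expanded counts).
#' @slot meanRoundArea mean area of single abnormal round nuclei
#'   (\code{NA} if none were found).
#' @slot baseIntensity the adaptive base intensity (mean of the lowest
#'   R-channel order statistics) used by the double threshold.
#'
#' @seealso [analyzeNuclei()], [nucleiCounts()]
#' @export
setClass("NucleiResult",
  representation(mask = "matrix", features = "data.frame",
                 nNormal = "integer", nAbnormal = "integer",
                 meanRoundArea = "numeric", baseIntensity = "numeric"),
  validity = function(object) {
    if (object@nNormal < 0L || object@nAbnormal < 0L)
      return("nucleus counts must be non-negative")
    TRUE
  })

#' @export
setMethod("show", "TargetProfile", function(object) {
  cat("TargetProfile (lalphabeta statistics over", object@nTargets,
      "target image(s))\n")
  m <- rbind(mean = object@means, sd = object@sds)
  print(round(m, 4))
})

#' @export
setMethod("show", "TissueLabelMap", function(object) {
  d <- dim(object@labels)
  cat(sprintf("TissueLabelMap %d x %d\n", d[1], d[2]))
  a <- classAreas(object)
  f <- a / sum(a)
  for (i in seq_along(a))
    cat(sprintf("  %-10s %10d px (%.1f%%)\n", names(a)[i], a[i], 100 * f[i]))
  if (length(object@thresholds))
    cat("  thresholds:", paste(names(object@thresholds),
        unlist(object@thresholds), sep = "=", collapse = ", "), "\n")
})

#' @export
setMethod("show", "NucleiResult", function(object) {
  cat(sprintf("NucleiResult: %d region(s), %d normal rod-like, %d abnormal nuclei\n",
              nrow(object@features), object@nNormal, object@nAbnormal))
  cat(sprintf("  base intensity %.1f, mean single round area %s px^2\n",
              object@baseIntensity,
              ifelse(is.na(object@meanRoundArea), "NA",
                     sprintf("%.1f", object@meanRoundArea))))
})

#' Accessors for pipeline objects
#'
#' `labelMatrix()` returns the integer label matrix of a
#' [TissueLabelMap-class] (0 = BACKGROUND, 1 = NORMAL, 2 = ABNORMAL);
#' `classAreas()` returns the named pixel counts of the three classes;
#' `nucleiFeatures()` returns the per-region feature table of a
#' [NucleiResult-class]; `nucleiCounts()` returns the named vector
#' `c(normal, abnormal)`; `profileMeans()` / `profileSds()` return the
#' channel statistics of a [TargetProfile-class].
#'
#' @param x the object.
#' @return See the description per accessor.
#' @name accessors
#' @aliases labelMatrix classAreas nucleiFeatures nucleiCounts profileMeans
#'   profileSds
NULL

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))
#' @rdname accessors
#' @export
setMethod("labelMatrix", "TissueLabelMap", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("classAreas", function(x) standardGeneric("classAreas"))
#' @rdname accessors
#' @export
setMethod("classAreas", "TissueLabelMap", function(x) {
  v <- tabulate(as.integer(x@labels) + 1L, nbins = 3L)
  names(v) <- .tissueLevels
  v
})

#' @rdname accessors
#' @export
setGeneric("nucleiFeatures", function(x) standardGeneric("nucleiFeatures"))
#' @rdname accessors
#' @export
setMethod("nucleiFeatures", "NucleiResult", function(x) x@features)

#' @rdname accessors
#' @export
setGeneric("nucleiCounts", function(x) standardGeneric("nucleiCounts"))
#' @rdname accessors
#' @export
setMethod("nucleiCounts", "NucleiResult", function(x)
  c(normal = x@nNormal, abnormal = x@nAbnormal))

#' @rdname accessors
#' @export
setGeneric("profileMeans", function(x) standardGeneric("profileMeans"))
#' @rdname accessors
#' @export
setMethod("profileMeans", "TargetProfile", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("profileSds", function(x) standardGeneric("profileSds"))
#' @rdname accessors
#' @export
setMethod("profileSds", "TargetProfile", function(x) x@sds)

# internal constructor for TissueLabelMap from an integer matrix
newTissueLabelMap <- function(labels, thresholds = list()) {
  storage.mode(labels) <- "integer"
  new("TissueLabelMap", labels = labels, thresholds = thresholds)
}
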