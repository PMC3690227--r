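# Seeded synthetic H&E-like pulley slides with exact ground truth. The
# generator emulates the appearance the pipeline relies on: a pink
# collagenous fiber background with banding, purple elliptical
# metaplastic patches, dark blue rod-shaped and round nuclei, a white
# empty-slide margin, plus acquisition nuisances (illumination gradient,
# global color cast, Gaussian noise). Ground-truth label maps and nucleus
# masks are consistent with the rendered image by construction.

#' Configuration of the synthetic slide generator
#'
#' Defaults render a 640 x 480 field. Base colors follow H&E conventions
#' with hue relationships as on stained slides: pink fibers at low hue
#' (more green than blue), purple metaplastic patches and the faintly
#' blue-tinted empty slide at high hue, nuclei dark blue. All values are
#' overridable.
#'
#' @param width,height image size in pixels.
#' @param abnormalFraction target abnormal (metaplastic) fraction of the
#'   tissue area, in \[0, 1\].
#' @param nRod,nRound numbers of planted rod-like and round nuclei.
#' @param rodAxes ranges of the rod semi-axes, `c(majorMin, majorMax,
#'   minorMin, minorMax)` in pixels.
#' @param roundRadius range of the round-nucleus radius, pixels.
#' @param colorPink,colorPurple,colorBackground,colorNucleus base RGB
#'   triples.
#' @param illuminationAmplitude relative amplitude of the horizontal
#'   illumination gradient (0 disables it).
#' @param colorCast RGB offset added to every pixel (a staining/camera
#'   cast; `c(0, 0, 0)` disables it).
#' @param noiseSd standard deviation of the additive Gaussian pixel
#'   noise, in 8-bit intensity levels.
#' @param seed integer seed; identical configurations with identical
#'   seeds render bitwise-identical images.
#' @return a validated configuration list.
#' @export
syntheticConfig <- function(width = 640L, height = 480L,
                            abnormalFraction = 0.2,
                            nRod = 40L, nRound = 20L,
                            rodAxes = c(18, 28, 1.8, 2.8),
                            roundRadius = c(8, 12),
                            colorPink = c(235, 170, 150),
                            colorPurple = c(150, 95, 175),
                            colorBackground = c(232, 235, 250),
                            colorNucleus = c(60, 50, 110),
                            illuminationAmplitude = 0.08,
                            colorCast = c(0, 0, 0),
                            noiseSd = 3,
                            seed = 1L) {
  stopifnot(width >= 32L, height >= 32L,
            abnormalFraction >= 0, abnormalFraction <= 1,
            nRod >= 0L, nRound >= 0L,
            all(rodAxes > 0), rodAxes[1] <= rodAxes[2],
            rodAxes[3] <= rodAxes[4],
            all(roundRadius > 0), roundRadius[1] <= roundRadius[2],
            noiseSd >= 0, illuminationAmplitude >= 0)
  as.list(environment())
}

# pixel set of an axis-aligned-from-rotated ellipse, clipped to the image
.ellipsePixels <- function(cx, cy, a, b, phi, W, H, pad = 0) {
  ae <- a + pad; be <- b + pad
  ext <- ceiling(max(ae, be))
  xs <- max(1L, floor(cx - ext)):min(W, ceiling(cx + ext))
  ys <- max(1L, floor(cy - ext)):min(H, ceiling(cy + ext))
  if (!length(xs) || !length(ys)) return(NULL)
  g <- expand.grid(y = ys, x = xs)
  dx <- g$x - cx; dy <- g$y - cy
  u <- dx * cos(phi) + dy * sin(phi)
  v <- -dx * sin(phi) + dy * cos(phi)
  inside <- (u / ae)^2 + (v / be)^2 <= 1
  cbind(row = g$y[inside], col = g$x[inside])
}

#' Generate one synthetic pulley image with ground truth
#'
#' Renders pink fiber bands inside an elliptical tissue region, adds
#' purple elliptical metaplastic patches until the requested abnormal
#' fraction of the tissue is covered (the patch size bounds the
#' overshoot), plants non-overlapping rod and round nuclei (rods in
#' normal tissue, rounds preferentially inside patches), then applies
#' the illumination gradient, color cast and Gaussian noise.
#'
#' In the ground-truth label map a nucleus pixel carries the label of its
#' host region, so the true abnormal fraction is the fraction of
#' metaplastic tissue.
#'
#' @param config configuration from [syntheticConfig()].
#' @return list with `image` (RGB array), `truth` (list: `labels`
#'   [TissueLabelMap-class], `nucleusMask` integer matrix of nucleus ids,
#'   `nucleusClass` character vector (`"rod"`/`"round"`) indexed by id,
#'   `abnormalFraction` realized true fraction, `nRod`, `nRound`).
#' @export
simulateImage <- function(config = syntheticConfig()) {
  withSeed(config$seed, .renderImage(config))
}

.renderImage <- function(cfg) {
  W <- cfg$width; H <- cfg$height
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), W), H, W)
  # elliptical tissue region with a white margin all around
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  tissue <- ((xs - cx) / (0.52 * W))^2 + ((ys - cy) / (0.52 * H))^2 <= 1
  tissueArea <- sum(tissue)

  # purple metaplastic patches
  abnormal <- matrix(FALSE, H, W)
  if (cfg$abnormalFraction > 0) {
    rmin <- 0.035 * min(W, H); rmax <- 0.07 * min(W, H)
    for (i in seq_len(5000L)) {
      if (sum(abnormal) / tissueArea >= cfg$abnormalFraction) break
      px <- .ellipsePixels(runif(1, 1, W), runif(1, 1, H),
                           runif(1, rmin, rmax), runif(1, rmin, rmax),
                           runif(1, 0, pi), W, H)
      if (is.null(px)) next
      keep <- tissue[px]
      abnormal[px[keep, , drop = FALSE]] <- TRUE
    }
  }

  # nuclei: rejection-sampled, non-overlapping (2 px clearance), inside
  # the tissue; rods in normal tissue, rounds inside patches when present
  nucleusMask <- matrix(0L, H, W)
  occupied <- matrix(FALSE, H, W)
  nucleusClass <- character(0)
  nid <- 0L
  plant <- function(class) {
    for (try in seq_len(500L)) {
      x <- runif(1, 1, W); y <- runif(1, 1, H)
      if (class == "rod") {
        a <- runif(1, cfg$rodAxes[1], cfg$rodAxes[2])
        b <- runif(1, cfg$rodAxes[3], cfg$rodAxes[4])
        phi <- runif(1, 0, pi)
        hostOk <- tissue[round(y), round(x)] && !abnormal[round(y), round(x)]
      } else {
        a <- b <- runif(1, cfg$roundRadius[1], cfg$roundRadius[2])
        phi <- 0
        # rounds prefer metaplastic hosts; after half the attempts fall
        # back to any tissue so sparse patches cannot deadlock placement
        hostOk <- tissue[round(y), round(x)] &&
          (try > 250L || !any(abnormal) || abnormal[round(y), round(x)])
      }
      if (!hostOk) next
      clear <- .ellipsePixels(x, y, a, b, phi, W, H, pad = 2)
      if (is.null(clear) || any(occupied[clear]) || !all(tissue[clear]))
        next
      px <- .ellipsePixels(x, y, a, b, phi, W, H)
      nid <<- nid + 1L
      nucleusMask[px] <<- nid
      occupied[clear] <<- TRUE
      nucleusClass[nid] <<- class
      return(invisible(NULL))
    }
    stop("could not place a ", class,
         " nucleus without overlap after 500 attempts; ",
         "reduce nucleus counts or sizes")
  }
  for (i in seq_len(cfg$nRod)) plant("rod")
  for (i in seq_len(cfg$nRound)) plant("round")

  # paint: background, pink fibers with banding, purple patches, nuclei
  img <- array(0, c(H, W, 3))
  band <- 1 + 0.05 * sin(2 * pi * ys / runif(1, 28, 40) + runif(1, 0, 2 * pi))
  jitter <- matrix(rnorm(H * W, 0, 2), H, W)
  for (ch in 1:3) {
    pl <- matrix(cfg$colorBackground[ch], H, W)
    pink <- clamp(cfg$colorPink[ch] * band + jitter, 0, 255)
    pl[tissue] <- pink[tissue]
    pl[abnormal] <- cfg$colorPurple[ch]
    pl[nucleusMask > 0L] <- cfg$colorNucleus[ch]
    img[, , ch] <- pl
  }

  # acquisition nuisances
  illum <- 1 + cfg$illuminationAmplitude * (xs / W - 0.5)
  for (ch in 1:3) {
    pl <- img[, , ch] * illum + cfg$colorCast[ch]
    pl <- pl + rnorm(H * W, 0, cfg$noiseSd)
    img[, , ch] <- roundHalfUp(clamp(pl, 0, 255))
  }

  labels <- matrix(.BACKGROUND, H, W)
  labels[tissue] <- .NORMAL
  labels[abnormal] <- .ABNORMAL
  list(image = img,
       truth = list(labels = newTissueLabelMap(labels),
                    nucleusMask = nucleusMask,
                    nucleusClass = nucleusClass,
                    abnormalFraction = sum(abnormal) / tissueArea,
                    nRod = sum(nucleusClass == "rod"),
                    nRound = sum(nucleusClass == "round")))
}

#' Generate a graded multi-specimen synthetic study
#'
#' Assigns each specimen a severity stage (round-robin over the supplied
#' stage names), draws per-image abnormal fractions from the
#' stage-specific range, and couples the nucleus mix to the stage: the
#' round-nucleus share of each image is drawn from `roundShare[[stage]]`.
#' Stage ranges must be ordered (each stage's fractions above the next).
#'
#' @param nSpecimens total number of specimens.
#' @param imagesPerSpecimen images rendered per specimen.
#' @param stageRanges named list of `c(min, max)` abnormal-fraction
#'   ranges, ordered from most to least severe, e.g.
#'   `list(H = c(0.24, 0.28), M = c(0.18, 0.22), L = c(0.06, 0.16))`.
#' @param seed integer seed for the whole set.
#' @param width,height image size.
#' @param nNuclei total nuclei planted per image.
#' @param roundShare named list of `c(min, max)` round-nucleus share
#'   ranges per stage; defaults mirror the severity ordering.
#' @param ... further arguments forwarded to [syntheticConfig()].
#' @return list with `specimens` (list of lists: `id`, `stage`, `images`,
#'   each image as returned by [simulateImage()]) and `manifest`
#'   (data.frame: specimen, stage, image index, true fraction, true
#'   counts).
#' @export
simulateSpecimenSet <- function(nSpecimens, imagesPerSpecimen,
                                stageRanges = list(H = c(0.24, 0.28),
                                                   M = c(0.18, 0.22),
                                                   L = c(0.06, 0.16)),
                                seed = 1L, width = 640L, height = 480L,
                                nNuclei = 50L,
                                roundShare = list(H = c(0.65, 0.78),
                                                  M = c(0.56, 0.68),
                                                  L = c(0.46, 0.58),
                                                  N = c(0.33, 0.45)),
                                ...) {
  stages <- names(stageRanges)
  if (is.null(stages) || any(stages == ""))
    stop("'stageRanges' must be a named list")
  los <- vapply(stageRanges, min, numeric(1))
  his <- vapply(stageRanges, max, numeric(1))
  if (any(diff(los) > 0) || any(his > c(Inf, los[-length(los)] + 1e-12)))
    stop("'stageRanges' must be ordered from most to least severe ",
         "with non-overlapping decreasing ranges")
  withSeed(seed, {
    specimens <- vector("list", nSpecimens)
    rows <- list()
    for (i in seq_len(nSpecimens)) {
      st <- stages[(i - 1L) %% length(stages) + 1L]
      imgs <- vector("list", imagesPerSpecimen)
      for (j in seq_len(imagesPerSpecimen)) {
        frac <- runif(1, stageRanges[[st]][1], stageRanges[[st]][2])
        share <- if (!is.null(roundShare[[st]]))
          runif(1, roundShare[[st]][1], roundShare[[st]][2]) else 0.5
        nRound <- as.integer(roundHalfUp(nNuclei * share))
        cfg <- syntheticConfig(width = width, height = height,
                               abnormalFraction = frac,
                               nRod = nNuclei - nRound, nRound = nRound,
                               seed = sample.int(.Machine$integer.max, 1),
                               ...)
        imgs[[j]] <- simulateImage(cfg)
        tr <- imgs[[j]]$truth
        rows[[length(rows) + 1L]] <- data.frame(
          specimen = sprintf("S%02d", i), stage = st, image = j,
          trueFraction = tr$abnormalFraction,
          nRod = tr$nRod, nRound = tr$nRound)
      }
      specimens[[i]] <- list(id = sprintf("S%02d", i), stage = st,
                             images = imgs)
    }
    list(specimens = specimens, manifest = do.call(rbind, rows))
  })
}

#' Write a synthetic specimen set to disk
#'
#' Writes each image as PNG together with its ground-truth label map and
#' a manifest CSV (paths, stage, true fraction, true counts), producing a
#' directory layout the pipeline can consume directly.
#'
#' @param set result of [simulateSpecimenSet()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame (with `path` column), invisibly.
#' @export
writeSpecimenSet <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- set$manifest
  man$path <- NA_character_
  man$truthPath <- NA_character_
  k <- 0L
  for (sp in set$specimens) {
    for (j in seq_along(sp$images)) {
      k <- k + 1L
      p <- file.path(dir, sprintf("%s_img%02d.png", sp$id, j))
      tp <- file.path(dir, sprintf("%s_img%02d_truth.png", sp$id, j))
      writeRGB(sp$images[[j]]$image, p)
      writeLabelMap(sp$images[[j]]$truth$labels, tp)
      man$path[k] <- p
      man$truthPath[k] <- tp
    }
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
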