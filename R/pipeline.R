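# End-to-end pipeline: color normalization -> tissue segmentation ->
# nuclei analysis per image, sum-then-ratio aggregation per specimen, and
# the stage-level statistics across specimens. The R functions are the
# primary interface; `inst/scripts/pulleyquant` wraps them for shell use.

#' Pipeline configuration
#'
#' Collects everything one run needs: the normalization target (either a
#' prebuilt [TargetProfile-class] / its YAML path, or the target image
#' paths to build one from), the manifest assigning images to specimens,
#' and the stage parameters.
#'
#' @param manifest data.frame (or CSV path) with columns `path`,
#'   `specimen` and optionally `stage`; one row per image.
#' @param profile a [TargetProfile-class], or the path of a profile YAML.
#' @param targets character vector of target image paths used to build
#'   the profile when `profile` is missing.
#' @param params double-threshold parameters
#'   ([doubleThresholdParams()]).
#' @param rules nucleus classifier rules ([classifierRules()]).
#' @param window rank-filter window (odd, >= 3).
#' @param outputDir directory for CSV reports and overlays (`NULL`
#'   disables writing).
#' @param writeOverlays write abnormal-boundary and nuclei overlay PNGs
#'   per image (requires `outputDir`).
#' @param variant t-test variant for group comparisons.
#' @return a validated configuration list.
#' @export
pipelineConfig <- function(manifest, profile = NULL, targets = NULL,
                           params = doubleThresholdParams(),
                           rules = classifierRules(), window = 9L,
                           outputDir = NULL, writeOverlays = FALSE,
                           variant = "welch") {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  if (!all(c("path", "specimen") %in% names(manifest)))
    stop("manifest needs columns 'path' and 'specimen'")
  if (window %% 2L != 1L || window < 3L)
    stop("'window' must be odd and >= 3")
  if (is.null(profile) && is.null(targets))
    stop("provide a 'profile' (object or YAML path) or 'targets' image paths")
  if (is.character(profile)) profile <- readTargetProfile(profile)
  missing <- manifest$path[!file.exists(manifest$path)]
  if (length(missing))
    stop("image file(s) not found: ", paste(missing, collapse = ", "))
  list(manifest = manifest, profile = profile, targets = targets,
       params = params, rules = rules, window = as.integer(window),
       outputDir = outputDir, writeOverlays = isTRUE(writeOverlays),
       variant = variant)
}

# Measure one image: returns the per-image measurement row plus the
# chosen thresholds for the run log.
measureImage <- function(image, profile, params, rules, window) {
  norm <- normalizeColors(image, profile)
  seg <- segmentTissue(norm, window)
  areas <- classAreas(seg)
  nuc <- analyzeNuclei(norm, params, rules)
  cnt <- nucleiCounts(nuc)
  list(measurement = data.frame(
         areaNormal = areas[["NORMAL"]], areaAbnormal = areas[["ABNORMAL"]],
         nNormal = cnt[["normal"]], nAbnormal = cnt[["abnormal"]]),
       thresholds = c(seg@thresholds, list(base = nuc@baseIntensity)),
       normalized = norm, segmentation = seg, nuclei = nuc)
}

#' Run the full quantification pipeline
#'
#' For every manifest image: normalize to the target profile, segment
#' tissue, segment and classify nuclei. Per specimen the image
#' measurements are summed and the two severity parameters computed; when
#' the manifest carries H/M/L stage labels the stage statistics (group
#' summaries, midpoint cuts, predicted stages, pairwise Welch tests) are
#' added for both parameters. Each returned table is recomputable from
#' the one below it; an internal integrity check asserts this on every
#' run. Per-image thresholds (Otsu cuts and double-threshold base) are
#' collected in `thresholds` and logged via `message()` when `verbose`.
#'
#' @param config configuration from [pipelineConfig()].
#' @param verbose log each image's chosen thresholds.
#' @return list with `images` (per-image measurements), `specimens`
#'   (summed areas/counts and both parameters, plus predicted stages when
#'   available), `analysis1`/`analysis2` (stage analyses of parameters 1
#'   and 2, see [stageAnalysis()], `NULL` without stage labels) and
#'   `thresholds`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  man <- config$manifest
  profile <- config$profile
  if (is.null(profile)) profile <- buildTargetProfile(config$targets)
  outDir <- config$outputDir
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  imgRows <- list(); thrRows <- list()
  for (i in seq_len(nrow(man))) {
    img <- tryCatch(readRGB(man$path[i]),
                    error = function(e) stop("failed to read '", man$path[i],
                                             "': ", conditionMessage(e)))
    r <- measureImage(img, profile, config$params, config$rules,
                      config$window)
    imgRows[[i]] <- cbind(data.frame(path = man$path[i],
                                     specimen = man$specimen[i]),
                          r$measurement)
    thrRows[[i]] <- cbind(data.frame(path = man$path[i]),
                          as.data.frame(r$thresholds))
    if (verbose)
      message(sprintf("%s: kHue=%s kG=%s kAbnormal=%s base=%.1f",
                      basename(man$path[i]), r$thresholds$kHue,
                      r$thresholds$kG, r$thresholds$kAbnormal,
                      r$thresholds$base))
    if (!is.null(outDir) && config$writeOverlays) {
      stem <- tools::file_path_sans_ext(basename(man$path[i]))
      writeRGB(overlayBoundaries(r$normalized, r$segmentation),
               file.path(outDir, paste0(stem, "_tissue.png")))
      writeRGB(overlayNuclei(r$normalized, r$nuclei),
               file.path(outDir, paste0(stem, "_nuclei.png")))
    }
  }
  images <- do.call(rbind, imgRows)
  thresholds <- do.call(rbind, thrRows)

  specIds <- unique(man$specimen)
  specimens <- do.call(rbind, lapply(specIds, function(id) {
    agg <- aggregateSpecimen(images[images$specimen == id, , drop = FALSE])
    cbind(data.frame(specimen = id), agg)
  }))
  if ("stage" %in% names(man)) {
    specimens$stage <- man$stage[match(specimens$specimen, man$specimen)]
  }

  # integrity: every specimen number must be recomputable from the
  # per-image table
  chk <- stats::aggregate(images[c("areaNormal", "areaAbnormal",
                                   "nNormal", "nAbnormal")],
                          by = list(specimen = images$specimen), FUN = sum)
  chk <- chk[match(specimens$specimen, chk$specimen), ]
  stopifnot(all(abs(chk$areaNormal - specimens$areaNormal) < 1e-9),
            all(abs(chk$nAbnormal - specimens$nAbnormal) < 1e-9))

  analysis1 <- analysis2 <- NULL
  if ("stage" %in% names(specimens) &&
      all(c("H", "M", "L") %in% specimens$stage) &&
      all(table(specimens$stage[specimens$stage %in% c("H", "M", "L")]) >= 2)) {
    analysis1 <- stageAnalysis(data.frame(specimen = specimens$specimen,
                                          stage = specimens$stage,
                                          ratio = specimens$parameter1),
                               variant = config$variant)
    analysis2 <- stageAnalysis(data.frame(specimen = specimens$specimen,
                                          stage = specimens$stage,
                                          ratio = specimens$parameter2),
                               variant = config$variant)
    specimens$predicted1 <- analysis1$predictions$predicted[
      match(specimens$specimen, analysis1$predictions$specimen)]
    specimens$predicted2 <- analysis2$predictions$predicted[
      match(specimens$specimen, analysis2$predictions$specimen)]
  }

  if (!is.null(outDir)) {
    utils::write.csv(images, file.path(outDir, "images.csv"),
                     row.names = FALSE)
    utils::write.csv(specimens, file.path(outDir, "specimens.csv"),
                     row.names = FALSE)
    utils::write.csv(thresholds, file.path(outDir, "thresholds.csv"),
                     row.names = FALSE)
    if (!is.null(analysis1)) {
      g <- rbind(cbind(parameter = "parameter1", analysis1$groups),
                 cbind(parameter = "parameter2", analysis2$groups))
      utils::write.csv(g, file.path(outDir, "group_summary.csv"),
                       row.names = FALSE)
      cmp <- rbind(cbind(parameter = "parameter1", analysis1$comparisons),
                   cbind(parameter = "parameter2", analysis2$comparisons))
      utils::write.csv(cmp, file.path(outDir, "comparisons.csv"),
                       row.names = FALSE)
    }
  }
  list(images = images, specimens = specimens,
       analysis1 = analysis1, analysis2 = analysis2,
       thresholds = thresholds)
}

#' Quantify a pre-measured cohort
#'
#' Runs only the aggregation/statistics stage on measurement tables (for
#' example the bundled [referenceCohort()]), bypassing the imaging
#' stages: per-specimen parameters, stage statistics, midpoint cuts,
#' predictions and pairwise comparisons.
#'
#' @param tissue data.frame with `specimen`, `stage`, `areaNormal`,
#'   `areaAbnormal` (already summed per specimen).
#' @param nuclei data.frame with `specimen`, `stage`, `nNormal`,
#'   `nAbnormal`; optional.
#' @param variant t-test variant.
#' @return list with `specimens` and stage analyses `analysis1` (and
#'   `analysis2` when `nuclei` is given).
#' @examples
#' rc <- referenceCohort()
#' q <- quantifyCohort(rc$tissue, rc$nuclei)
#' subset(q$analysis1$comparisons, pair == "M vs L")$p   # ~0.004
#' @export
quantifyCohort <- function(tissue, nuclei = NULL,
                           variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  specimens <- data.frame(specimen = tissue$specimen, stage = tissue$stage,
                          areaNormal = tissue$areaNormal,
                          areaAbnormal = tissue$areaAbnormal,
                          parameter1 = parameter1(tissue$areaNormal,
                                                  tissue$areaAbnormal))
  a1 <- stageAnalysis(data.frame(specimen = specimens$specimen,
                                 stage = specimens$stage,
                                 ratio = specimens$parameter1),
                      variant = variant)
  a2 <- NULL
  if (!is.null(nuclei)) {
    i <- match(specimens$specimen, nuclei$specimen)
    specimens$nNormal <- nuclei$nNormal[i]
    specimens$nAbnormal <- nuclei$nAbnormal[i]
    specimens$parameter2 <- parameter2(specimens$nNormal,
                                       specimens$nAbnormal)
    a2 <- stageAnalysis(data.frame(specimen = specimens$specimen,
                                   stage = specimens$stage,
                                   ratio = specimens$parameter2),
                        variant = variant)
  }
  list(specimens = specimens, analysis1 = a1, analysis2 = a2)
}
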