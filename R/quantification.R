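# Severity indices and stage discrimination. Two ratios summarize a
# specimen: parameter 1, the abnormal-tissue area fraction, and
# parameter 2, the abnormal-nucleus number fraction. Specimens are
# aggregated sum-then-ratio over their images; severity stages are
# discriminated by midpoints of adjacent stage means, and group
# differences are tested with Welch's two-sample t-test.

#' Severity parameters
#'
#' `parameter1()` is the size ratio of abnormal tissue regions,
#' `abnormal / (abnormal + normal)` on pixel areas. `parameter2()` is the
#' number ratio of abnormal nuclei, with the same form on nucleus counts.
#' Both lie in \[0, 1\].
#'
#' @param areaNormal,areaAbnormal pixel areas of normal and abnormal
#'   tissue.
#' @param nNormal,nAbnormal counts of normal and abnormal nuclei.
#' @return the ratio (vectorized).
#' @examples
#' parameter1(31791895, 12495997)   # 0.282 to 3 dp
#' parameter2(271, 660)             # 0.709 to 3 dp
#' @export
parameter1 <- function(areaNormal, areaAbnormal) {
  if (any(areaNormal < 0 | areaAbnormal < 0))
    stop("areas must be non-negative")
  tot <- areaNormal + areaAbnormal
  if (any(tot <= 0)) stop("total tissue area is zero")
  areaAbnormal / tot
}

#' @rdname parameter1
#' @export
parameter2 <- function(nNormal, nAbnormal) {
  if (any(nNormal < 0 | nAbnormal < 0))
    stop("counts must be non-negative")
  tot <- nNormal + nAbnormal
  if (any(tot <= 0)) stop("total nucleus count is zero")
  nAbnormal / tot
}

#' Aggregate per-image measurements into a specimen report
#'
#' Sums areas and counts over the images of one specimen and applies the
#' two ratio definitions to the sums (sum-then-ratio, not mean of
#' per-image ratios).
#'
#' @param measurements data.frame with columns `areaNormal`,
#'   `areaAbnormal`, `nNormal`, `nAbnormal`; one row per image.
#' @return one-row data.frame with the summed fields and `parameter1`,
#'   `parameter2`.
#' @export
aggregateSpecimen <- function(measurements) {
  need <- c("areaNormal", "areaAbnormal", "nNormal", "nAbnormal")
  if (!is.data.frame(measurements) || nrow(measurements) == 0L ||
      !all(need %in% names(measurements)))
    stop("'measurements' must be a non-empty data.frame with columns ",
         paste(need, collapse = ", "))
  s <- colSums(measurements[need])
  data.frame(areaNormal = s[["areaNormal"]],
             areaAbnormal = s[["areaAbnormal"]],
             nNormal = s[["nNormal"]], nAbnormal = s[["nAbnormal"]],
             parameter1 = parameter1(s[["areaNormal"]], s[["areaAbnormal"]]),
             parameter2 = parameter2(s[["nNormal"]], s[["nAbnormal"]]))
}

#' Mean and sample standard deviation of a group of ratios
#'
#' @param ratios numeric vector.
#' @return named vector `c(mean, sd, n)`; `sd` uses the n - 1
#'   denominator and is `NA` for a single observation.
#' @export
groupSummary <- function(ratios) {
  if (length(ratios) == 0L) stop("empty group")
  c(mean = mean(ratios),
    sd = if (length(ratios) > 1L) stats::sd(ratios) else NA_real_,
    n = length(ratios))
}

#' Midpoint stage thresholds
#'
#' The two discrimination cuts are the midpoints of the mean parameter
#' values of adjacent severity stages: `cutHM = (meanH + meanM) / 2` and
#' `cutML = (meanM + meanL) / 2`. The stage means must be strictly
#' decreasing from High to Low.
#'
#' @param meanH,meanM,meanL stage mean parameter values.
#' @return named vector `c(cutHM, cutML)`.
#' @export
stageThresholds <- function(meanH, meanM, meanL) {
  if (!(meanH > meanM && meanM > meanL))
    stop("stage means must be strictly decreasing (H > M > L)")
  c(cutHM = (meanH + meanM) / 2, cutML = (meanM + meanL) / 2)
}

#' Classify a severity stage from a parameter value
#'
#' `H` when the ratio is at or above `cutHM`, `M` when at or above
#' `cutML` but below `cutHM`, `L` otherwise. A value exactly at a cut
#' goes to the higher stage.
#'
#' @param ratio parameter value(s).
#' @param cuts thresholds from [stageThresholds()].
#' @return character vector of stages in `c("H", "M", "L")`.
#' @export
classifyStage <- function(ratio, cuts) {
  if (!(cuts[["cutHM"]] > cuts[["cutML"]]))
    stop("invalid cuts: cutHM must exceed cutML")
  ifelse(ratio >= cuts[["cutHM"]], "H",
         ifelse(ratio >= cuts[["cutML"]], "M", "L"))
}

#' Two-sample comparison of severity groups
#'
#' Two-tailed two-sample t-test between the parameter values of two
#' stages. The default is Welch's unequal-variance test with
#' Satterthwaite degrees of freedom; `variant = "pooled"` gives the
#' classical equal-variance test. Two constant groups with equal means
#' are reported as no difference (t = 0, p = 1); two constant groups
#' with different means as a certain difference (p = 0).
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return list with `t`, `df`, `p`.
#' @export
compareGroups <- function(groupA, groupB, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 observations")
  if (stats::sd(groupA) == 0 && stats::sd(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = length(groupA) + length(groupB) - 2, p = 1))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf,
                df = length(groupA) + length(groupB) - 2, p = 0))
  }
  ht <- stats::t.test(groupA, groupB, var.equal = (variant == "pooled"))
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Stage-level analysis of specimen parameter values
#'
#' Given one parameter value per specimen with pathologist stage labels,
#' computes per-stage summaries, the midpoint discrimination cuts from
#' the H/M/L stage means, the predicted stage of every H/M/L specimen,
#' and pairwise group comparisons. Normal (`N`) specimens are summarized
#' but excluded from threshold fitting and prediction.
#'
#' @param specimens data.frame with columns `specimen`, `stage` (in
#'   `c("H", "M", "L", "N")`) and `ratio`.
#' @param variant t-test variant passed to [compareGroups()].
#' @return list with `groups` (stage, n, mean, sd), `cuts`,
#'   `predictions` (specimen, stage, ratio, predicted), `misclassified`
#'   (data.frame of from/to transitions with counts) and `comparisons`
#'   (pair, t, df, p).
#' @export
stageAnalysis <- function(specimens, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  need <- c("specimen", "stage", "ratio")
  if (!all(need %in% names(specimens)))
    stop("'specimens' needs columns ", paste(need, collapse = ", "))
  stages <- intersect(c("H", "M", "L", "N"), unique(specimens$stage))
  groups <- do.call(rbind, lapply(stages, function(s) {
    g <- groupSummary(specimens$ratio[specimens$stage == s])
    data.frame(stage = s, n = g[["n"]], mean = g[["mean"]], sd = g[["sd"]])
  }))
  if (!all(c("H", "M", "L") %in% stages))
    stop("stage analysis requires specimens in each of H, M and L")
  mn <- function(s) groups$mean[groups$stage == s]
  cuts <- stageThresholds(mn("H"), mn("M"), mn("L"))
  hml <- specimens[specimens$stage %in% c("H", "M", "L"), , drop = FALSE]
  pred <- data.frame(specimen = hml$specimen, stage = hml$stage,
                     ratio = hml$ratio,
                     predicted = classifyStage(hml$ratio, cuts))
  mis <- pred[pred$stage != pred$predicted, , drop = FALSE]
  misTab <- if (nrow(mis)) stats::aggregate(
    list(n = mis$specimen), by = list(from = mis$stage, to = mis$predicted),
    FUN = length) else data.frame(from = character(), to = character(),
                                  n = integer())
  pairs <- list(c("H", "M"), c("M", "L"))
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    cg <- compareGroups(specimens$ratio[specimens$stage == pr[1]],
                        specimens$ratio[specimens$stage == pr[2]], variant)
    data.frame(pair = paste(pr, collapse = " vs "),
               t = cg$t, df = cg$df, p = cg$p)
  }))
  list(groups = groups, cuts = cuts, predictions = pred,
       misclassified = misTab, comparisons = comparisons)
}

#' Reference cohort of graded pulley specimens
#'
#' Bundled per-specimen measurements of a 29-specimen pulley cohort
#' graded H (high), M (middle), L (low) and N (normal) by a pathologist:
#' summed normal/abnormal tissue pixel areas and summed normal/abnormal
#' nucleus counts over the 10 analyzed images of each specimen. These
#' tables drive the worked examples and the reproduction of the published
#' stage statistics.
#'
#' @return list of two data.frames, `tissue` (`specimen`, `stage`,
#'   `areaNormal`, `areaAbnormal`) and `nuclei` (`specimen`, `stage`,
#'   `nNormal`, `nAbnormal`).
#' @examples
#' rc <- referenceCohort()
#' round(parameter1(rc$tissue$areaNormal, rc$tissue$areaAbnormal)[1], 3)
#' @export
referenceCohort <- function() {
  dir <- system.file("extdata", package = "pulleyQuant", mustWork = TRUE)
  tissue <- utils::read.csv(file.path(dir, "reference_cohort_tissue_areas.csv"),
                            stringsAsFactors = FALSE)
  nuclei <- utils::read.csv(file.path(dir, "reference_cohort_nuclei_counts.csv"),
                            stringsAsFactors = FALSE)
  list(tissue = tissue, nuclei = nuclei)
}
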