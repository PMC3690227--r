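# Hue conversion, Otsu thresholding and the three-step tissue segmentation.

test_that("hue conversion matches the HSI definition", {
  expect_equal(rgbToHue(array(c(255, 0, 0), c(1, 1, 3)))[1, 1], 0)
  expect_equal(rgbToHue(array(c(0, 0, 255), c(1, 1, 3)))[1, 1], 240)
  # direct evaluation: theta = acos(30 / sqrt(1200)) ~ 30 deg, B <= G
  h <- rgbToHue(array(c(120, 100, 80), c(1, 1, 3)))[1, 1]
  expect_equal(h, acos(30 / sqrt(1200)) * 180 / pi, tolerance = 1e-9)
  # achromatic pixels have no hue
  expect_true(is.na(rgbToHue(flatImage(1, 1, c(77, 77, 77)))[1, 1]))
  # range invariant over random colors
  set.seed(1)
  img <- array(sample(0:255, 900, TRUE), c(10, 30, 3))
  h <- rgbToHue(img)
  expect_true(all(is.na(h) | (h >= 0 & h < 360)))
})

test_that("otsuThreshold equals the brute-force interclass maximizer", {
  # two-mass histogram: every cut between the masses is optimal, the
  # tie-break picks the smallest
  r <- otsuThreshold(c(rep(10, 100), rep(200, 100)))
  expect_identical(r$kStar, 10L)
  # symmetric extreme histogram: sigma_B^2 = 0.25 * 255^2
  r2 <- otsuThreshold(c(rep(0, 50), rep(255, 50)))
  expect_equal(r2$sigmaBSq, 0.25 * 255^2, tolerance = 1e-9)
  expect_equal(r2$omega0 + r2$omega1, 1)
  expect_equal(r2$sigmaBSq, r2$omega0 * r2$omega1 * (r2$mu0 - r2$mu1)^2,
               tolerance = 1e-9)
  # random histograms against the from-definition oracle
  set.seed(99)
  for (i in 1:30) {
    v <- sample(0:255, 500, TRUE,
                prob = stats::dnorm(0:255, sample(40:200, 1),
                                    sample(10:70, 1)) + 1e-4)
    got <- otsuThreshold(v)
    want <- bruteOtsu(v)
    expect_identical(got$kStar, want$kStar)
    expect_equal(got$sigmaBSq, want$sigmaBSq, tolerance = 1e-9)
  }
  expect_error(otsuThreshold(rep(7, 10)), "identical")
})

test_that("foreground extraction recovers purple tissue from the rough background", {
  # two-tone slide: pink tissue block on a constant empty background;
  # step 2 has nothing to recover
  img <- flatImage(60, 80, c(232, 235, 250))
  img <- paintRect(img, 10:50, 10:70, c(235, 170, 150))
  tissueTruth <- matrix(FALSE, 60, 80); tissueTruth[10:50, 10:70] <- TRUE
  fg <- segmentForeground(img)
  expect_equal(unclass(fg)[, ], tissueTruth, ignore_attr = TRUE)
  expect_true(is.na(attr(fg, "kG")))
  # three-tone slide: purple hue is above the background's, so step 1
  # misses it and the G-channel step must pull it back
  img2 <- paintRect(img, 20:35, 30:55, c(150, 95, 175))
  purple <- matrix(FALSE, 60, 80); purple[20:35, 30:55] <- TRUE
  fg2 <- segmentForeground(img2)
  expect_false(is.na(attr(fg2, "kG")))
  expect_equal(unclass(fg2)[, ], tissueTruth | purple, ignore_attr = TRUE)
  # recovered pixels are by construction a subset of the step-1 background
  hue <- rgbToHue(img2)
  step1 <- matrix(FALSE, 60, 80)
  lev <- as.integer(round(hue * 255 / 360))
  ok <- !is.na(lev)
  k1 <- attr(fg2, "kHue")
  step1[ok] <- lev[ok] <= k1
  recovered <- fg2 & !step1
  expect_true(all(!step1[recovered]))
  expect_identical(unclass(recovered) & step1,
                   matrix(FALSE, nrow(recovered), ncol(recovered)))
})

test_that("the abnormal split works on the foreground only", {
  # two pure hue populations inside the foreground
  img <- flatImage(40, 40, c(232, 235, 250))
  img <- paintRect(img, 5:35, 5:20, c(235, 170, 150))   # pink, hue ~ 14
  img <- paintRect(img, 5:35, 21:35, c(150, 95, 175))   # purple, hue ~ 282
  hue <- rgbToHue(img)
  fg <- matrix(FALSE, 40, 40); fg[5:35, 5:35] <- TRUE
  seg <- segmentAbnormal(hue, fg)
  lab <- labelMatrix(seg)
  # the cut agrees with the brute-force Otsu on the foreground hue levels
  lev <- as.integer(round(hue * 255 / 360)); lev[is.na(lev)] <- 0L
  kOracle <- bruteOtsu(lev[fg])$kStar
  expect_identical(seg@thresholds$kAbnormal, kOracle)
  expect_true(all(lab[5:35, 5:20] == 1L))
  expect_true(all(lab[5:35, 21:35] == 2L))
  # background pixels are never relabeled
  expect_true(all(lab[!fg] == 0L))
  # an all-normal foreground (single hue) yields zero abnormal, no error
  img3 <- paintRect(flatImage(20, 20, c(232, 235, 250)), 5:15, 5:15,
                    c(235, 170, 150))
  hue3 <- rgbToHue(img3)
  fg3 <- matrix(FALSE, 20, 20); fg3[5:15, 5:15] <- TRUE
  seg3 <- segmentAbnormal(hue3, fg3)
  expect_equal(unname(classAreas(seg3)[["ABNORMAL"]]), 0)
  expect_error(segmentAbnormal(hue3, matrix(FALSE, 20, 20)), "empty")
})

test_that("the majority rank filter matches a naive counting oracle", {
  # constant map: unchanged
  u <- pulleyQuant:::newTissueLabelMap(matrix(1L, 12, 12))
  expect_identical(labelMatrix(rankFilter(u)), matrix(1L, 12, 12))
  # an isolated abnormal pixel in a normal field is absorbed
  m <- matrix(1L, 15, 15); m[8, 8] <- 2L
  f <- rankFilter(pulleyQuant:::newTissueLabelMap(m))
  expect_identical(labelMatrix(f), matrix(1L, 15, 15))
  # random three-label map against the per-pixel oracle
  set.seed(5)
  r <- matrix(sample(0:2, 32 * 32, TRUE), 32, 32)
  got <- labelMatrix(rankFilter(pulleyQuant:::newTissueLabelMap(r)))
  expect_identical(got, naiveRankFilter(r, 9L))
  # never introduces a label absent from the input
  r2 <- matrix(sample(c(0L, 2L), 32 * 32, TRUE), 32, 32)
  got2 <- labelMatrix(rankFilter(pulleyQuant:::newTissueLabelMap(r2)))
  expect_true(all(got2 %in% c(0L, 2L)))
  expect_error(rankFilter(u, window = 4), "odd")
})

test_that("abnormal boundaries follow the 4-neighbour definition", {
  m <- matrix(1L, 30, 30); m[11:20, 11:20] <- 2L
  b <- extractBoundaries(pulleyQuant:::newTissueLabelMap(m))
  expect_equal(sum(b), 36)                     # perimeter ring of a 10x10 block
  expect_true(all(which(b, arr.ind = TRUE) >= 11) &&
              all(which(b, arr.ind = TRUE) <= 20))
  expect_equal(sum(extractBoundaries(
    pulleyQuant:::newTissueLabelMap(matrix(1L, 10, 10)))), 0)
  # all-abnormal image: only the frame is boundary
  bAll <- extractBoundaries(pulleyQuant:::newTissueLabelMap(matrix(2L, 8, 9)))
  expect_equal(sum(bAll), 2 * 8 + 2 * 9 - 4)
})

test_that("segmentation of synthetic slides recovers the ground truth", {
  sim <- simulateImage(syntheticConfig(width = 320, height = 240,
                                       abnormalFraction = 0.22,
                                       nRod = 15, nRound = 10, seed = 31))
  prof <- buildTargetProfile(
    list(simulateImage(syntheticConfig(width = 320, height = 240,
                                       nRod = 15, nRound = 10,
                                       seed = 32))$image))
  seg <- segmentTissue(normalizeColors(sim$image, prof))
  gt <- labelMatrix(sim$truth$labels)
  pd <- labelMatrix(seg)
  # partition invariant
  expect_equal(sum(classAreas(seg)), length(pd))
  # pixelwise agreement >= 95% outside a 4-pixel band around true label
  # boundaries
  edge <- matrix(FALSE, nrow(gt), ncol(gt))
  edge[-1, ] <- edge[-1, ] | gt[-1, ] != gt[-nrow(gt), ]
  edge[-nrow(gt), ] <- edge[-nrow(gt), ] | gt[-1, ] != gt[-nrow(gt), ]
  edge[, -1] <- edge[, -1] | gt[, -1] != gt[, -ncol(gt)]
  edge[, -ncol(gt)] <- edge[, -ncol(gt)] | gt[, -1] != gt[, -ncol(gt)]
  band <- EBImage::dilate(edge * 1, EBImage::makeBrush(9, "box")) > 0
  expect_gte(mean(gt[!band] == pd[!band]), 0.95)
})
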