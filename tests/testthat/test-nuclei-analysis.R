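# Active double-threshold segmentation, shape features and the rod/round
# classifier.

test_that("double thresholding grows from seeds under the upper restriction", {
  # three-level image: background 100, blob core 20 (16 px), rim 60.
  # base = 20, seeds = core (<= 50), growth absorbs the rim (<= 65).
  m <- matrix(100, 20, 20)
  m[8:11, 8:11] <- 20
  rim <- matrix(FALSE, 20, 20); rim[7:12, 7:12] <- TRUE
  rim[8:11, 8:11] <- FALSE
  m[rim] <- 60
  mask <- activeDoubleThreshold(m)
  expect_equal(attr(mask, "base"), 20)
  want <- matrix(FALSE, 20, 20); want[7:12, 7:12] <- TRUE
  expect_equal(unclass(mask)[, ], want, ignore_attr = TRUE)
  # a dark pixel surrounded by too-bright pixels stays alone
  m2 <- matrix(80, 9, 9); m2[5, 5] <- 20
  mask2 <- activeDoubleThreshold(m2, doubleThresholdParams(nLowest = 1))
  expect_equal(sum(mask2), 1)
  expect_true(mask2[5, 5])
  # constant image: every pixel is a seed -> full mask (nuclei-free tiles
  # must be excluded upstream)
  m3 <- matrix(200, 6, 6)
  expect_true(all(activeDoubleThreshold(m3)))
  # growth never crosses the upper restriction into distant bright areas
  m4 <- matrix(c(rep(0, 10), rep(120, 90)), 10, 10)
  mask4 <- activeDoubleThreshold(m4)
  expect_true(all(!mask4[m4 == 120]))
  expect_true(all(mask4[m4 == 0]))
  expect_error(doubleThresholdParams(offsetSeed = 50, offsetGrow = 40),
               "offsetSeed < offsetGrow")
})

test_that("segmentation mask invariants hold on rough random images", {
  set.seed(8)
  base <- matrix(150, 40, 40)
  for (k in 1:5) {
    i <- sample(5:35, 1); j <- sample(5:35, 1)
    base[i:(i + 3), j:(j + 3)] <- sample(10:40, 1)
  }
  base <- base + matrix(rnorm(1600, 0, 5), 40, 40)
  base <- pmin(pmax(base, 0), 255)
  params <- doubleThresholdParams()
  mask <- activeDoubleThreshold(base, params)
  b <- attr(mask, "base")
  expect_true(all(base[mask] <= b + params$offsetGrow))
  seeds <- base <= b + params$offsetSeed
  expect_true(all(mask[seeds]))               # every seed is in the mask
  # every mask component contains at least one seed
  sf <- shapeFeatures(unclass(mask)[, ], minArea = 1L)
  for (id in sf$features$id)
    expect_true(any(seeds[sf$labels == id]))
})

test_that("shape features agree with analytic disc and ellipse oracles", {
  # disc, radius 15: area ~ pi r^2, circularity ~ 1, dMax/dMin ~ 1
  f <- shapeFeatures(rasterDisc(15))$features
  expect_equal(f$area, pi * 15^2, tolerance = 0.02)
  expect_equal(f$circularity, 1, tolerance = 0.15)
  expect_lt(f$dMax / f$dMin, 1.15)
  # elongated ellipse, semi-axes 30 x 4: area ~ pi a b, circularity well
  # below the rod cut, strong elongation
  f2 <- shapeFeatures(rasterEllipse(30, 4))$features
  expect_equal(f2$area, pi * 30 * 4, tolerance = 0.08)
  expect_lt(f2$circularity, 0.5)
  expect_gt(f2$dMax / f2$dMin, 3)
  # 3x3 solid square: exact hand-computed values
  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  f3 <- shapeFeatures(sq)$features
  expect_equal(f3$area, 9)
  expect_equal(f3$perimeter, 8)
  expect_equal(f3$dMax, sqrt(2))
  expect_equal(f3$dMin, 1)
  # sub-minArea components are dropped
  tiny <- matrix(FALSE, 6, 6); tiny[2, 2:3] <- TRUE
  expect_equal(nrow(shapeFeatures(tiny)$features), 0)
})

test_that("the rule-based classifier follows the three shape gates", {
  rules <- classifierRules()
  feats <- data.frame(
    id = 1:4,
    area = c(377, 707, 2500, 150),
    perimeter = c(123, 97, 400, 60),
    circularity = c(0.31, 0.95, 0.2, 0.96),
    centroidX = 0, centroidY = 0,
    dMax = c(30, 15, 50, 20), dMin = c(4, 15, 5, 2),
    concaveCentroid = FALSE)
  got <- classifyNuclei(feats, rules)
  # rod: circ < 0.95, ratio > 3, area < 2000
  expect_equal(got$label[1], "NORMAL_ROD")
  # disc: ratio 1 fails the elongation gate
  expect_equal(got$label[2], "ABNORMAL_ROUND")
  # area >= 2000 is a cluster regardless of shape
  expect_equal(got$label[3], "ABNORMAL_CLUSTER")
  # high circularity fails the rod gate even when elongated enough
  expect_equal(got$label[4], "ABNORMAL_ROUND")
  # the cluster count uses the mean single-round area of the same image
  meanRound <- mean(c(707, 150))
  expect_equal(got$nNuclei[3],
               countClusterNuclei(2500, meanRound))
  # with no single rounds, clusters count 1 with a warning
  lonely <- feats[3, , drop = FALSE]
  expect_warning(gotL <- classifyNuclei(lonely, rules), "no single round")
  expect_equal(gotL$nNuclei, 1L)
})

test_that("cluster nucleus counts round half-up with a floor of one", {
  expect_identical(countClusterNuclei(5000, 500), 10L)
  expect_identical(countClusterNuclei(600, 500), 1L)
  expect_identical(countClusterNuclei(1250, 500), 3L)   # half-up
  expect_identical(countClusterNuclei(100, 500), 1L)    # floor
  expect_error(countClusterNuclei(1000, 0), "> 0")
})

test_that("summaries count rods, rounds and expanded clusters", {
  f <- data.frame(label = c(rep("NORMAL_ROD", 3), rep("ABNORMAL_ROUND", 2),
                            "ABNORMAL_CLUSTER"),
                  nNuclei = c(1, 1, 1, 1, 1, 4))
  expect_equal(summarizeNuclei(f), c(normal = 3L, abnormal = 6L))
  empty <- data.frame(label = character(), nNuclei = integer())
  expect_equal(summarizeNuclei(empty), c(normal = 0L, abnormal = 0L))
})

test_that("planted rods and discs are recovered and classified exactly", {
  field <- plantedField(nRod = 50L, nRound = 30L)
  res <- analyzeNuclei(field$channel)
  expect_equal(unname(nucleiCounts(res)),
               c(field$nRod, field$nRound))
  tab <- table(nucleiFeatures(res)$label)
  expect_equal(unname(tab[["NORMAL_ROD"]]), 50)
  expect_equal(unname(tab[["ABNORMAL_ROUND"]]), 30)
})
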