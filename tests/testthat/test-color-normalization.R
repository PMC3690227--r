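# Statistics-transfer color normalization in lalphabeta space.

test_that("lalphabeta transform handles neutral, black and constant inputs", {
  # a neutral pixel has (almost) no chroma: the cone-response matrix rows
  # sum to ~1, so both opponent channels vanish
  lab <- rgbToLab(array(c(255, 255, 255), c(1, 1, 3)))
  expect_lt(abs(lab[1, 1, 2]), 0.005)
  expect_lt(abs(lab[1, 1, 3]), 0.005)
  # black: the log clamp keeps every channel finite
  labB <- rgbToLab(array(0, c(2, 2, 3)))
  expect_true(all(is.finite(labB)))
  # a constant-color image maps to identical lalphabeta triples
  img <- flatImage(5, 7, c(180, 90, 120))
  labC <- rgbToLab(img)
  for (ch in 1:3) expect_equal(max(labC[, , ch]) - min(labC[, , ch]), 0)
  expect_error(rgbToLab(array(300, c(2, 2, 3))), "0, 255")
})

test_that("channel statistics match a direct summation oracle", {
  set.seed(42)
  img <- array(sample(0:255, 8 * 8 * 3, TRUE), c(8, 8, 3))
  lab <- rgbToLab(img)
  st <- channelStats(lab)
  for (ch in 1:3) {
    v <- as.numeric(lab[, , ch])
    m <- sum(v) / length(v)
    s <- sqrt(sum((v - m)^2) / (length(v) - 1))
    expect_equal(unname(st$means[ch]), m, tolerance = 1e-12)
    expect_equal(unname(st$sds[ch]), s, tolerance = 1e-12)
  }
  # constant image: sd exactly zero, mean is the pixel value
  stC <- channelStats(rgbToLab(flatImage(3, 3, c(10, 20, 30))))
  expect_equal(unname(stC$sds), c(0, 0, 0))
})

test_that("target profiles average per-image statistics", {
  set.seed(7)
  a <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
  b <- array(sample(0:255, 48, TRUE), c(4, 4, 3))
  pa <- buildTargetProfile(list(a))
  sa <- channelStats(rgbToLab(a))
  expect_equal(profileMeans(pa), sa$means)
  expect_equal(profileSds(pa), sa$sds)
  # duplicated target changes nothing
  paa <- buildTargetProfile(list(a, a))
  expect_equal(profileMeans(paa), profileMeans(pa))
  # two distinct targets: every field is the midpoint
  pab <- buildTargetProfile(list(a, b))
  sb <- channelStats(rgbToLab(b))
  expect_equal(profileMeans(pab), (sa$means + sb$means) / 2)
  expect_equal(profileSds(pab), (sa$sds + sb$sds) / 2)
  expect_error(buildTargetProfile(list()), "non-empty")
  expect_error(buildTargetProfile(list(flatImage(3, 3, c(9, 9, 9)))),
               "degenerate")
})

test_that("normalization matches target statistics exactly before inversion", {
  set.seed(3)
  img <- array(sample(0:255, 20 * 30 * 3, TRUE), c(20, 30, 3))
  tgt <- array(sample(0:255, 300, TRUE), c(10, 10, 3))
  prof <- buildTargetProfile(list(tgt))
  lab <- normalizeLab(img, prof)
  st <- channelStats(lab)
  expect_equal(st$means, profileMeans(prof), tolerance = 1e-9)
  expect_equal(st$sds, profileSds(prof), tolerance = 1e-9)
})

test_that("self-normalization is a fixed point and normalization idempotent", {
  sim <- simulateImage(syntheticConfig(width = 160, height = 120,
                                       nRod = 8, nRound = 5, seed = 5))
  img <- sim$image
  prof <- buildTargetProfile(list(img))
  out <- normalizeColors(img, prof)
  expect_lte(mean(abs(out - img)), 2)        # quantization tolerance
  # idempotence against an unrelated profile
  prof2 <- buildTargetProfile(
    list(simulateImage(syntheticConfig(width = 160, height = 120,
                                       nRod = 8, nRound = 5,
                                       seed = 6))$image))
  once <- normalizeColors(img, prof2)
  twice <- normalizeColors(once, prof2)
  expect_lte(mean(abs(twice - once)), 2)
})

test_that("RGB -> lalphabeta -> RGB round trip is tight away from black", {
  set.seed(11)
  n <- 10000
  px <- array(sample(10:255, n * 3, TRUE), c(100, n %/% 100, 3))
  rt <- labToRgb(rgbToLab(px))
  expect_lte(max(abs(rt - px)), 3)
})

test_that("zero source spread errors by default, identity scaling on request", {
  img <- flatImage(4, 4, c(100, 150, 200))
  prof <- buildTargetProfile(
    list(array(sample(0:255, 48, TRUE), c(4, 4, 3))))
  expect_error(normalizeColors(img, prof), "zero spread")
  out <- normalizeColors(img, prof, onZeroSd = "identity")
  expect_true(all(out >= 0 & out <= 255))
  # shift-only transfer maps the constant image onto the profile means
  stOut <- channelStats(normalizeLab(img, prof, onZeroSd = "identity"))
  expect_equal(stOut$means, profileMeans(prof), tolerance = 1e-9)
})

test_that("a global color cast is reduced by normalization", {
  base <- syntheticConfig(width = 200, height = 150, seed = 21,
                          nRod = 10, nRound = 6, colorCast = c(0, 0, 0))
  cast <- syntheticConfig(width = 200, height = 150, seed = 21,
                          nRod = 10, nRound = 6, colorCast = c(18, -10, 8))
  prof <- buildTargetProfile(list(simulateImage(base)$image))
  castImg <- simulateImage(cast)$image
  before <- channelStats(rgbToLab(castImg))
  after <- channelStats(rgbToLab(normalizeColors(castImg, prof)))
  dBefore <- abs(before$means - profileMeans(prof))
  dAfter <- abs(after$means - profileMeans(prof))
  expect_true(all(dAfter <= dBefore))
})

test_that("target profiles round-trip through YAML", {
  prof <- buildTargetProfile(
    list(simulateImage(syntheticConfig(width = 80, height = 60,
                                       nRod = 3, nRound = 2,
                                       seed = 2))$image))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeTargetProfile(prof, path)
  back <- readTargetProfile(path)
  expect_equal(profileMeans(back), profileMeans(prof), tolerance = 1e-6)
  expect_equal(profileSds(back), profileSds(prof), tolerance = 1e-6)
  expect_equal(back@nTargets, 1L)
})
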