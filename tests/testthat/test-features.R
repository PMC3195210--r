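# Colour indices, erosion width, Waddle Disk Ratio, texture statistics.

test_that("pixel colour indices match hand-computed values", {
  # achromatic pixel: all factors equal, all contrasts vanish
  a <- pixelColourIndices(100, 100, 100)
  expect_equal(a$r_i, 1 / 0.9999, tolerance = 1e-12)
  expect_equal(a$r_i, a$g_i)
  expect_equal(a$RBI, 0)
  expect_equal(c(a$ERI, a$EGI, a$EBI), c(0, 0, 0))
  # generic pixel, frozen from direct evaluation of the definitions
  b <- pixelColourIndices(60, 120, 40)
  I <- 0.2989 * 60 + 0.5870 * 120 + 0.1140 * 40
  expect_equal(I, 92.934)
  expect_equal(b$r_i, 60 / I)
  expect_equal(round(c(b$r_i, b$g_i, b$b_i), 4), c(0.6456, 1.2912, 0.4304))
  expect_equal(b$RBI, 0.2, tolerance = 1e-4)
  expect_equal(round(c(b$ERI, b$EGI, b$EBI), 4), c(-0.1389, 0.5558, 0.1853))
  # pure green: RBI singular, flagged zero
  g <- pixelColourIndices(0, 255, 0)
  expect_equal(g$g_i, 1 / 0.587, tolerance = 1e-12)
  expect_equal(round(g$EGI, 4), 2.9022)
  expect_true(g$flagRBI)
  expect_equal(g$RBI, 0)
  # black pixel flagged
  expect_true(pixelColourIndices(0, 0, 0)$flagZeroIntensity)
})

test_that("colour indices are invariant to a common illumination factor", {
  base <- pixelColourIndices(60, 120, 40)
  for (f in c(0.5, 2, 3.5)) {
    scaled <- pixelColourIndices(60 * f, 120 * f, 40 * f)
    for (col in c("r_i", "g_i", "b_i", "RBI", "ERI", "EGI", "EBI"))
      expect_equal(scaled[[col]], base[[col]], tolerance = 1e-12)
  }
})

test_that("region colour features are flag-skipping means over mask pixels", {
  # two-pixel region: mean of the two per-pixel values, by brute force
  img <- array(0L, c(1, 2, 3))
  img[1, 1, ] <- c(60L, 120L, 40L); img[1, 2, ] <- c(100L, 100L, 100L)
  region <- new("PlantRegion", mask = matrix(1L, 1, 2), colour = img,
                gray = matrix(c(93L, 100L), 1, 2))
  got <- regionColourFeatures(region)
  px <- pixelColourIndices(c(60, 100), c(120, 100), c(40, 100))
  for (col in c("r_i", "g_i", "b_i", "RBI", "ERI", "EGI", "EBI"))
    expect_equal(unname(got[col]), mean(px[[col]]))
  expect_true(got["r_i"] >= min(px$r_i) && got["r_i"] <= max(px$r_i))
  # uniform region reduces to the per-pixel value
  uni <- segmentPlant(uniformImage(c(60, 120, 40), 6, 6),
                      segmentationConfig(minRegionPx = 0))
  expect_equal(unname(regionColourFeatures(uni)["RBI"]), 0.2, tolerance = 1e-4)
})

test_that("erosion width matches structured-bar arithmetic", {
  line <- matrix(0L, 5, 44); line[3, 3:42] <- 1L
  expect_equal(erosionWidth(line), 2L)
  bar6 <- matrix(0L, 10, 44); bar6[3:8, 3:42] <- 1L
  expect_equal(erosionWidth(bar6), 6L)
  bar7 <- matrix(0L, 11, 34); bar7[3:9, 3:32] <- 1L
  expect_equal(erosionWidth(bar7), 8L)   # width w vanishes in ceil(w/2) steps
  # bars flush with the image border erode from the border inwards too
  flush <- matrix(1L, 6, 40)
  expect_equal(erosionWidth(flush), 6L)
  expect_error(erosionWidth(matrix(0L, 4, 4)),
               class = "grassID_emptySegmentation")
})

test_that("erosion width equals the brute-force pixel-set oracle on random masks", {
  set.seed(42)
  for (rep in 1:25) {
    m <- randomMask(32L)
    expect_identical(erosionWidth(m), bruteErosionWidth(m))
  }
})

test_that("Waddle Disk Ratio follows its closed form and is scale-stable", {
  bar6 <- matrix(0L, 10, 44); bar6[3:8, 3:42] <- 1L
  expect_equal(waddleDiskRatio(bar6), 6 / (2 * sqrt(240 / pi)), tolerance = 1e-12)
  expect_equal(round(waddleDiskRatio(bar6), 3), 0.343)
  # rasterized disk: the 3x3 square kernel erodes in the Chebyshev metric,
  # so a Euclidean disk of radius r vanishes in about r/sqrt(2) steps and
  # WDR sits near 1/sqrt(2), not 1 (checked against the brute-force oracle)
  disk <- matrix(0L, 50, 50)
  for (i in 1:50) for (j in 1:50)
    if ((i - 25)^2 + (j - 25)^2 <= 20^2) disk[i, j] <- 1L
  expect_identical(erosionWidth(disk), bruteErosionWidth(disk))
  wdr <- waddleDiskRatio(disk)
  expect_gte(wdr, 0.65); expect_lte(wdr, 0.85)
  # doubling linear dimensions leaves WDR within discretization tolerance
  for (w in c(4, 6, 10)) {
    m1 <- matrix(0L, w + 4, 44); m1[3:(w + 2), 3:42] <- 1L
    m2 <- matrix(0L, 2 * w + 4, 84); m2[3:(2 * w + 2), 3:82] <- 1L
    expect_lt(abs(waddleDiskRatio(m2) - waddleDiskRatio(m1)), 0.1)
  }
})

test_that("texture statistics hit the degenerate and uniform histogram limits", {
  # constant region
  g <- matrix(0L, 6, 6); g[2:5, 2:5] <- 150L
  t1 <- textureFeatures(g, (g > 0) * 1L)
  expect_equal(t1$uniformity, 1)
  expect_equal(t1$entropy, 0)
  # two equally frequent levels
  g2 <- matrix(c(100L, 200L), 4, 4)
  t2 <- textureFeatures(g2, matrix(1L, 4, 4))
  expect_equal(t2$uniformity, 0.5)
  expect_equal(t2$entropy, 1)
  # flat histogram over all 256 levels
  g3 <- matrix(0:255, 16, 16)
  t3 <- textureFeatures(g3, matrix(1L, 16, 16))
  expect_equal(t3$uniformity, 1 / 256)
  expect_equal(t3$entropy, 8)
  expect_equal(sum(t3$proportions), 1, tolerance = 1e-12)
})

test_that("uniformity and entropy move oppositely as mass concentrates", {
  set.seed(9)
  levels <- sample(0:255, 64, replace = TRUE)
  spread <- textureFeatures(matrix(levels, 8, 8), matrix(1L, 8, 8))
  onelev <- textureFeatures(matrix(77L, 8, 8), matrix(1L, 8, 8))
  expect_gt(onelev$uniformity, spread$uniformity)
  expect_lt(onelev$entropy, spread$entropy)
})

test_that("extractFeatures composes the per-feature operations", {
  img <- array(0L, c(12, 46, 3))
  for (ch in 1:3) img[4:9, 4:43, ch] <- c(60L, 120L, 40L)[ch]
  region <- segmentPlant(img, segmentationConfig(minRegionPx = 0))
  fv <- extractFeatures(region)
  expect_named(fv, featureNames())
  expect_equal(unname(fv["W"]), 6)
  expect_equal(unname(fv["WDR"]), 6 / (2 * sqrt(240 / pi)), tolerance = 1e-12)
  expect_equal(unname(fv["U_t"]), 1)
  expect_equal(unname(fv["E_t"]), 0)
  expect_equal(unname(fv["RBI"]), 0.2, tolerance = 1e-4)
  # surrounding background pixels play no role
  bigger <- array(0L, c(30, 60, 3))
  for (ch in 1:3) bigger[10:15, 10:49, ch] <- c(60L, 120L, 40L)[ch]
  fv2 <- extractFeatures(segmentPlant(bigger, segmentationConfig(minRegionPx = 0)))
  expect_equal(fv2, fv)
})

test_that("feature tables round-trip through CSV", {
  ds <- cachedFixture("tinyDataset", makeDataset(nPerSpecies = 4L, seed = 99))
  tab <- extractFeatureTable(ds$plants)
  expect_equal(nrow(tab), 12)
  expect_true(all(featureNames() %in% names(tab)))
  expect_setequal(unique(tab$species), c("wheat", "brome", "ryegrass"))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(tab, f)
  back <- readFeatureTable(f)
  expect_equal(back$W, tab$W)
  expect_equal(back$U_t, tab$U_t, tolerance = 1e-12)
})
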