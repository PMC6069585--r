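test_that("thresholding follows the boundary convention f >= T is background", {
  u100 <- matrix(100, 8, 8)
  seg <- segmentImage(u100, T = 120)
  expect_true(all(seg$F == 0L))          # all nucleus
  u120 <- matrix(120, 8, 8)
  expect_true(all(segmentImage(u120, T = 120)$F == 1L))  # boundary is background
  # partition invariant
  img <- matrix(c(rep(50, 30), rep(200, 34)), 8, 8)
  segp <- segmentImage(img, T = 128)
  expect_equal(sum(segp$F == 1L) + sum(segp$F == 0L), 64L)
})

test_that("valley threshold separates two-delta histograms", {
  img <- matrix(c(rep(50, 200), rep(250, 200)), 20, 20)
  T <- valleyThreshold(img)
  expect_gt(T, 50); expect_lt(T, 250)
  expect_equal(attr(T, "method"), "valley")
})

test_that("valley threshold separates nucleus from background on fixtures", {
  nuc <- cleanNucleus(a = 20, b = 20, centerGray = 80, backgroundGray = 200)
  T <- valleyThreshold(nuc$image)
  expect_gt(T, 80); expect_lt(T, 200)
  seg <- segmentImage(nuc$image, T)
  expect_identical(seg$F == 0L, nuc$truthMask)
})

test_that("unimodal images fall back to Otsu and are flagged", {
  gen <- LCG(8)
  img <- matrix(round(lcgUniform(gen, 400, 100, 160)), 20, 20)
  T <- valleyThreshold(img)
  # fallback may or may not trigger on a flat histogram; force unimodality
  img2 <- matrix(round(lcgNormal(gen, 2500, 128, 3)), 50, 50)
  T2 <- valleyThreshold(img2)
  expect_true(attr(T2, "method") %in% c("otsu", "valley"))
  tri <- matrix(c(rep(120, 50), rep(121, 100), rep(122, 50)), 10, 20)
  expect_equal(attr(valleyThreshold(tri), "method"), "otsu")
  expect_error(valleyThreshold(matrix(7, 4, 4)), "no-contrast")
})

test_that("region extraction keeps the largest component and fills holes", {
  img <- matrix(200, 30, 40)
  img[5:22, 3:22] <- 60            # large blob, area 360
  img[10:14, 10:14] <- 200         # bright hole inside it
  img[25:28, 30:35] <- 60          # small blob, area 24
  seg <- segmentImage(img, T = 128)
  reg <- extractRegion(img, seg)
  expect_equal(regionArea(reg), 18L * 20L)   # hole filled, small blob dropped
  expect_equal(regionBBox(reg), c(2, 4, 22, 22))
  expect_lte(regionArea(reg), sum(seg$F == 0L) + 25)  # hole pixels re-added
  # patch background is the white sentinel
  expect_true(all(regionPatch(reg)[!regionMask(reg)] == 255))
})

test_that("single-pixel region has the documented bbox and centroid", {
  mask <- matrix(FALSE, 12, 12)
  mask[8, 6] <- TRUE               # (x, y) = (5, 7) 0-based
  reg <- regionFromMask(mask)
  expect_equal(regionBBox(reg), c(5, 7, 6, 8))
  # centroid is patch-local; add the bbox origin for source coordinates
  expect_equal(regionCentroid(reg) + regionBBox(reg)[1:2], c(x = 5, y = 7))
})

test_that("fixture centroid is recovered within half a pixel", {
  nuc <- cleanNucleus(a = 20, b = 20)
  reg <- extractRegion(nuc$image, segmentImage(nuc$image))
  center <- (dim(nuc$image)[1] - 1) / 2   # ellipse drawn at canvas center
  global <- regionCentroid(reg) + regionBBox(reg)[1:2]
  expect_lt(max(abs(global - center)), 0.5)
})

test_that("recovered masks reach Dice 0.99 on noise-free fixtures", {
  for (ab in list(c(20, 20), c(24, 12), c(15, 9))) {
    nuc <- cleanNucleus(a = ab[1], b = ab[2], orientation = 40)
    reg <- extractRegion(nuc$image, segmentImage(nuc$image))
    full <- matrix(FALSE, nrow(nuc$image), ncol(nuc$image))
    bb <- regionBBox(reg)
    full[(bb[2] + 1):bb[4], (bb[1] + 1):bb[3]] <- regionMask(reg)
    expect_gte(diceOverlap(full, nuc$truthMask), 0.99)
  }
})
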