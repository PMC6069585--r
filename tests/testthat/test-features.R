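test_that("normalized central moments follow mask symmetry", {
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  s1 <- regionStats(regionFromMask(one))
  expect_equal(c(s1$M11, s1$M20, s1$M02), c(0, 0, 0))
  sq <- matrix(FALSE, 20, 20); sq[5:14, 5:14] <- TRUE
  expect_equal(regionStats(regionFromMask(sq))$M11, 0)
  # 45-degree bar: positive cross-moment, Ia > Ib; brute-force check
  bar <- matrix(FALSE, 30, 30)
  for (i in 0:14) bar[8 + i + (-1:1), 8 + i] <- TRUE
  sb <- regionStats(regionFromMask(bar))
  idx <- which(bar, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  expect_equal(sb$M11, sum((x - mean(x)) * (y - mean(y))) / length(x)^2)
  expect_gt(abs(sb$M11), 0)
  inertia <- inertiaFeatures(sb)
  expect_gt(inertia[["Ia"]], inertia[["Ib"]])
})

test_that("intensity spread features match hand evaluation", {
  disk <- diskRegion(10, gray = 100)
  expect_equal(unname(intensityShapeFeatures(disk)), c(0, 0, 1))
  # half gray 100, half gray 200: g0=150, all deviations 50 -> sigma 0
  mask <- matrix(TRUE, 4, 10)
  gray <- matrix(rep(c(100, 200), each = 20), 4, 10)
  reg <- regionFromMask(mask, ifelse(mask, gray, 255))
  f <- intensityShapeFeatures(reg)
  expect_equal(unname(f), c(0, 50, 1))
  st <- regionStats(reg)
  expect_equal(st$g0, 150)
  # sigma is never negative
  syn <- diskRegion(8, gray = 60)
  expect_gte(intensityShapeFeatures(syn)[["sigma"]], 0)
})

test_that("inertia features are moment-matrix eigenvalues", {
  st <- structure(list(M20 = 4, M02 = 1, M11 = 0, area = 1, g0 = 0),
                  class = "RegionStats")
  f <- inertiaFeatures(st)
  expect_equal(unname(f), c(2.5, 4, 1))
  iso <- structure(list(M20 = 3, M02 = 3, M11 = 0), class = "RegionStats")
  expect_equal(unname(inertiaFeatures(iso))[2:3], c(3, 3))
  # eigenvalue identities on random masks
  gen <- LCG(6)
  for (rep in 1:10) {
    mask <- matrix(lcgNext(gen, 400) < 0.4, 20, 20)
    if (!any(mask)) next
    st <- regionStats(regionFromMask(mask))
    f <- inertiaFeatures(st)
    expect_gte(f[["Ia"]], f[["Ib"]])
    expect_equal(f[["Ia"]] * f[["Ib"]], st$M20 * st$M02 - st$M11^2,
                 tolerance = 1e-12)
  }
})

test_that("normalized gray mean and deviation are bounded", {
  disk <- diskRegion(9, gray = 128)
  md <- textureMeanDeviation(disk)
  expect_equal(md[["mean"]], 128 / 255)
  expect_equal(md[["deviation"]], 0)
  mask <- matrix(TRUE, 2, 10)
  reg <- regionFromMask(mask, matrix(rep(c(0, 255), each = 10), 2, 10))
  md2 <- textureMeanDeviation(reg)
  expect_equal(unname(md2), c(0.5, 0.5))
  gen <- LCG(3)
  noisy <- regionFromMask(mask, matrix(round(lcgUniform(gen, 20, 0, 255)), 2, 10))
  expect_lte(textureMeanDeviation(noisy)[["deviation"]], 0.5)
})

test_that("co-occurrence statistics match enumeration on degenerate patterns", {
  disk <- diskRegion(8, gray = 100)
  g <- glcmTexture(disk)
  expect_equal(g[["contrast"]], 0)
  expect_equal(g[["energy"]], 1)
  expect_gte(g[["entropy"]], 0)
  # checkerboard of two levels: horizontal distance-1 pairs always differ
  mask <- matrix(TRUE, 8, 8)
  gray <- matrix(ifelse((row(mask) + col(mask)) %% 2 == 0, 0, 255), 8, 8)
  reg <- regionFromMask(mask, gray)
  gh <- glcmTexture(reg, levels = 32, offsets = cbind(dx = 1L, dy = 0L))
  q0 <- floor(0 * 32 / 256) + 1; q1 <- floor(255 * 32 / 256) + 1
  expect_equal(gh[["contrast"]], (q1 - q0)^2)
  # entropy nonnegative on random fixtures
  gen <- LCG(14)
  rnd <- regionFromMask(mask, matrix(round(lcgUniform(gen, 64, 0, 255)), 8, 8))
  expect_gte(glcmTexture(rnd)[["entropy"]], 0)
  # single pixel degenerates with a warning
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_warning(gpx <- glcmTexture(regionFromMask(px)), "too small")
  expect_true(all(is.finite(gpx)))
})

test_that("morphology features match analytic geometry", {
  disk <- diskRegion(20)
  m <- morphologyFeatures(disk)
  expect_lt(abs(m[["circularity"]] - 1), 0.05)
  expect_lt(abs(m[["rectangularity"]] - pi / 4), 0.05 * pi / 4)
  # a digitized disk is not exactly convex as a pixel set (corner cuts)
  expect_lt(abs(m[["convexity"]] - 1), 0.05)
  expect_lt(abs(m[["bulkiness"]] - 1), 0.05)
  expect_lt(abs(m[["radius"]] - 20), 1)
  expect_lt(abs(m[["diameter"]] - 40), 1.5)
  sq <- regionFromMask(rbind(matrix(FALSE, 2, 24),
                             cbind(matrix(FALSE, 20, 2),
                                   matrix(TRUE, 20, 20),
                                   matrix(FALSE, 20, 2)),
                             matrix(FALSE, 2, 24)))
  msq <- morphologyFeatures(sq)
  expect_lt(abs(msq[["rectangularity"]] - 1), 0.02)
  expect_lt(abs(msq[["convexity"]] - 1), 0.02)
  # compactness is the reciprocal of circularity
  expect_equal(m[["compactness"]] * m[["circularity"]], 1, tolerance = 1e-9)
})

test_that("the assembled vector has the frozen length and order", {
  disk <- diskRegion(12, gray = 90)
  fv <- extractFeatures(disk)
  expect_equal(length(fv), 28L)
  expect_identical(names(fv), featureNames())
  fe <- extractFeatures(disk, extended = TRUE)
  expect_equal(length(fe), 30L)
  expect_identical(names(fe), featureNames(extended = TRUE))
  expect_true(all(is.finite(fv)), all(is.finite(fe)))
  expect_identical(fv, extractFeatures(diskRegion(12, gray = 90)))
})

test_that("features respond correctly to scaling and rotation", {
  small <- diskRegion(10); big <- diskRegion(20)
  fs <- extractFeatures(small); fb <- extractFeatures(big)
  expect_lt(abs(fb[["area"]] / fs[["area"]] - 4), 4 * 0.05)
  for (nm in c("circularity", "roundness", "rectangularity"))
    expect_lt(abs(fb[[nm]] - fs[[nm]]) / abs(fs[[nm]]), 0.05)
  # 90-degree rotation of a gray ellipse leaves rotation-invariant features
  nuc <- cleanNucleus(18, 11)
  r0 <- extractRegion(nuc$image, segmentImage(nuc$image))
  r90 <- rotateRegion(r0, 90)
  f0 <- extractFeatures(r0); f90 <- extractFeatures(r90)
  for (nm in c("area", "circularity", "convexity", "mean", "deviation"))
    expect_lt(abs(f90[[nm]] - f0[[nm]]) / max(abs(f0[[nm]]), 1e-9), 0.01)
})
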