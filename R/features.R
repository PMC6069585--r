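#' Build a CellRegion directly from a mask
#'
#' Test/analysis convenience: wraps a full-frame binary mask (and
#' optionally a gray image) into a [CellRegion-class] with contour,
#' centroid and bounding box computed, without running segmentation.
#'
#' @param mask logical matrix, TRUE on nucleus pixels.
#' @param image optional gray matrix of the same dimensions; default is a
#'   flat gray 100 nucleus on white.
#' @param label,cells label and nucleus count to attach.
#' @return a \code{CellRegion}.
#' @export
regionFromMask <- function(mask, image = NULL, label = NA_integer_,
                           cells = 1L) {
  mask <- mask > 0
  if (is.null(image)) {
    image <- matrix(255, nrow = nrow(mask), ncol = ncol(mask))
    image[mask] <- 100
  }
  .makeRegion(image, mask, label = label, cells = cells)
}

#' First- and second-order region statistics
#'
#' \code{g0} is the mean gray over the mask; \code{M11}, \code{M20},
#' \code{M02} are the normalized second-order central moments of the
#' mask-pixel coordinate distribution,
#' \eqn{M_{pq} = \sum (x-\bar x)^p (y-\bar y)^q / area^2}
#' (scale-invariant; about 1/(4\eqn{\pi}) \eqn{\approx} 0.08 for a disk).
#'
#' @param region a [CellRegion-class] with non-empty mask.
#' @return list of class \code{RegionStats}: \code{g0}, \code{area},
#'   \code{M11}, \code{M20}, \code{M02}.
#' @export
regionStats <- function(region) {
  idx <- which(region@mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  area <- nrow(idx)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  dx <- x - mean(x); dy <- y - mean(y)
  structure(list(
    g0 = mean(region@patch[region@mask]),
    area = area,
    M11 = sum(dx * dy) / area^2,
    M20 = sum(dx^2) / area^2,
    M02 = sum(dy^2) / area^2
  ), class = "RegionStats")
}

#' Intensity spread features: distance, sigma, roundness
#'
#' \code{distance} is the mean absolute deviation of gray from the region
#' mean \eqn{g_0}; \code{sigma} is the standard deviation of those
#' absolute deviations; \code{roundness = 1 - sigma/distance}.  A
#' constant-gray region has \code{distance = sigma = 0} and roundness is
#' defined as 1.
#'
#' @param region a [CellRegion-class].
#' @param stats optional precomputed [regionStats()].
#' @return named numeric: \code{sigma}, \code{distance}, \code{roundness}.
#' @export
intensityShapeFeatures <- function(region, stats = regionStats(region)) {
  g <- region@patch[region@mask]
  dev <- abs(stats$g0 - g)
  distance <- sum(dev) / stats$area
  sigma <- sqrt(sum((dev - distance)^2) / stats$area)
  roundness <- if (distance == 0) 1 else 1 - sigma / distance
  c(sigma = sigma, distance = distance, roundness = roundness)
}

#' Inertia (principal second-moment) features
#'
#' From the normalized central moments: \eqn{h = (M_{20} + M_{02}) / 2},
#' \eqn{I_a = h + \sqrt{h^2 - M_{20} M_{02} + M_{11}^2}},
#' \eqn{I_b = h - \sqrt{\cdot}} - the two eigenvalues of the second-moment
#' matrix, so \eqn{I_a \ge I_b} and
#' \eqn{I_a I_b = M_{20} M_{02} - M_{11}^2}.  The discriminant equals
#' \eqn{((M_{20} - M_{02})/2)^2 + M_{11}^2} and is never negative.
#'
#' @param stats a [regionStats()] result.
#' @return named numeric: \code{h}, \code{Ia}, \code{Ib}.
#' @export
inertiaFeatures <- function(stats) {
  h <- (stats$M20 + stats$M02) / 2
  disc <- ((stats$M20 - stats$M02) / 2)^2 + stats$M11^2
  s <- sqrt(disc)
  c(h = h, Ia = h + s, Ib = h - s)
}

#' Normalized gray mean and deviation
#'
#' On gray normalized to [0, 1] (g / 255): the mean and the population
#' standard deviation over the mask pixels.
#'
#' @param region a [CellRegion-class].
#' @return named numeric: \code{mean}, \code{deviation} (both in [0, 1],
#'   deviation at most 0.5).
#' @export
textureMeanDeviation <- function(region) {
  g <- region@patch[region@mask] / 255
  m <- mean(g)
  c(mean = m, deviation = sqrt(mean((g - m)^2)))
}

#' Gray-level co-occurrence texture features
#'
#' Builds a symmetric gray-level co-occurrence matrix (GLCM) restricted to
#' pixel pairs that both lie in the mask, quantized to \code{levels} gray
#' levels, at distance 1 in the four directions 0/45/90/135 degrees
#' (averaged), and computes the standard Haralick statistics.  The sixth
#' value, \code{anisotropy_tex}, is the histogram-entropy anisotropy: the
#' fraction of the gray-histogram entropy contributed by levels at or
#' below the median level (a signed quantity near -0.5 for symmetric
#' histograms).
#'
#' Degenerate conventions keeping all values finite: a constant region has
#' contrast 0, energy 1, homogeneity 1, correlation 1, entropy 0; a
#' single-pixel region returns those values with a warning (no pixel
#' pairs).
#'
#' @param region a [CellRegion-class].
#' @param levels number of quantized gray levels.
#' @param offsets integer matrix with columns (dx, dy), the co-occurrence
#'   displacement vectors to average over.
#' @return named numeric: \code{contrast}, \code{energy},
#'   \code{homogeneity}, \code{correlation}, \code{entropy},
#'   \code{anisotropy_tex}.
#' @export
glcmTexture <- function(region, levels = 32L,
                        offsets = cbind(dx = c(1L, 1L, 0L, -1L),
                                        dy = c(0L, 1L, 1L, 1L))) {
  mask <- region@mask
  q <- matrix(pmin(floor(region@patch * levels / 256) + 1L, levels),
              nrow = nrow(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  counts <- matrix(0, levels, levels)
  for (k in seq_len(nrow(offsets))) {
    dx <- offsets[k, 1]; dy <- offsets[k, 2]
    if (max(1, 1 - dy) > min(nr, nr - dy) ||
        max(1, 1 - dx) > min(nc, nc - dx)) next
    r1 <- max(1, 1 - dy):min(nr, nr - dy)
    c1 <- max(1, 1 - dx):min(nc, nc - dx)
    m1 <- mask[r1, c1, drop = FALSE] & mask[r1 + dy, c1 + dx, drop = FALSE]
    if (!any(m1)) next
    i <- q[r1, c1, drop = FALSE][m1]
    j <- q[r1 + dy, c1 + dx, drop = FALSE][m1]
    tab <- tabulate(c(i + (j - 1L) * levels, j + (i - 1L) * levels),
                    nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels)
  }
  if (sum(counts) == 0) {
    warning("region too small for co-occurrence pairs; returning degenerate texture")
    out <- c(contrast = 0, energy = 1, homogeneity = 1, correlation = 1,
             entropy = 0)
  } else {
    p <- counts / sum(counts)
    ii <- row(p); jj <- col(p)
    mi <- sum(ii * p); mj <- sum(jj * p)
    si <- sqrt(sum((ii - mi)^2 * p)); sj <- sqrt(sum((jj - mj)^2 * p))
    corr <- if (si * sj < 1e-12) 1 else
      sum((ii - mi) * (jj - mj) * p) / (si * sj)
    pn <- p[p > 0]
    out <- c(contrast = sum((ii - jj)^2 * p),
             energy = sum(p^2),
             homogeneity = sum(p / (1 + (ii - jj)^2)),
             correlation = corr,
             entropy = -sum(pn * log2(pn)))
  }
  # histogram-entropy anisotropy over the 256-level gray histogram
  g <- round(region@patch[mask])
  hp <- tabulate(pmin(pmax(g, 0), 255) + 1L, nbins = 256L)
  hp <- hp / sum(hp)
  H <- -sum(hp[hp > 0] * log2(hp[hp > 0]))
  if (H == 0) {
    aniso <- 0
  } else {
    k0 <- which(cumsum(hp) >= 0.5)[1]
    lower <- hp[seq_len(k0)]
    aniso <- sum(lower[lower > 0] * log2(lower[lower > 0])) / H
  }
  c(out, anisotropy_tex = aniso)
}

# corner-corrected chain-code perimeter (Vossepoel-Smeulders weights)
.contourPerimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(0)
  nxt <- rbind(contour[-1, , drop = FALSE], contour[1, , drop = FALSE])
  step <- sqrt(rowSums((nxt - contour)^2))
  axial <- sum(step < 1.2)
  diag <- sum(step >= 1.2)
  0.948 * axial + 1.340 * diag
}

#' Region morphology features
#'
#' The remaining shape features: \code{area}; \code{contlength} (contour
#' perimeter, chain-code corrected); \code{circularity} =
#' \eqn{4\pi area / P^2}; \code{compactness} = \eqn{P^2 / (4\pi area)};
#' \code{convexity} = area / convex-hull area (hull taken over pixel
#' corners so a convex region scores 1); \code{rectangularity} = area /
#' bounding-box area; \code{diameter} (maximum pairwise contour distance);
#' \code{radius} (mean centroid-to-contour distance); the moment-ellipse
#' features \code{anisotropy} (anisometry, ratio of ellipse semi-axes
#' \eqn{R_a / R_b}), \code{bulkiness} (\eqn{\pi R_a R_b / area}) and
#' \code{structurefactor} (anisometry \eqn{\times} bulkiness - 1), where
#' \eqn{R_a, R_b} come from the unnormalized central moments;
#' \code{sides}, the side count of the regular polygon whose isoperimetric
#' ratio \eqn{P^2/A = 4 n \tan(\pi/n)} matches the region's; and in the
#' extended set \code{iod} (integrated optical density
#' \eqn{\sum \lg(I_0/g)} over the mask), \code{numruns} and
#' \code{meanlength} from horizontal run-length encoding of the mask.
#'
#' @param region a [CellRegion-class].
#' @param I0 background reference gray for the integrated optical density.
#' @return named numeric vector.
#' @export
morphologyFeatures <- function(region, I0 = 255) {
  mask <- region@mask
  area <- sum(mask)
  P <- .contourPerimeter(region@contour)
  circularity <- if (P > 0) 4 * pi * area / P^2 else 1
  compactness <- if (circularity > 0) 1 / circularity else Inf
  # convex hull over pixel corners
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  pts <- cbind(c(x - 0.5, x - 0.5, x + 0.5, x + 0.5),
               c(y - 0.5, y + 0.5, y - 0.5, y + 0.5))
  hullArea <- if (nrow(pts) >= 3L) {
    h <- grDevices::chull(pts)
    hx <- pts[h, 1]; hy <- pts[h, 2]
    abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  } else area
  convexity <- area / max(hullArea, area)
  bboxArea <- ncol(mask) * nrow(mask)
  rectangularity <- area / bboxArea
  ct <- region@contour
  diameter <- if (nrow(ct) >= 2L) max(stats::dist(ct)) else 0
  radius <- if (nrow(ct) >= 1L)
    mean(sqrt((ct[, 1] - region@centroid[1])^2 +
              (ct[, 2] - region@centroid[2])^2)) else 0
  # moment ellipse (unnormalized central moments)
  dx <- x - mean(x); dy <- y - mean(y)
  m20 <- mean(dx^2); m02 <- mean(dy^2); m11 <- mean(dx * dy)
  hh <- (m20 + m02) / 2
  s <- sqrt(((m20 - m02) / 2)^2 + m11^2)
  Ra <- 2 * sqrt(max(hh + s, 0)); Rb <- 2 * sqrt(max(hh - s, 0))
  anisometry <- if (Rb > 1e-9) Ra / Rb else 1
  bulkiness <- pi * Ra * Rb / area
  structurefactor <- anisometry * bulkiness - 1
  sides <- .polygonSides(P^2 / area)
  # extended set
  iod <- integratedOD(region@patch, I0, mask)
  runs <- mask & !cbind(FALSE, mask[, -ncol(mask), drop = FALSE])
  numruns <- sum(runs)
  meanlength <- if (numruns > 0) area / numruns else 0
  c(area = area, contlength = P, circularity = circularity,
    compactness = compactness, convexity = convexity,
    rectangularity = rectangularity, diameter = diameter, radius = radius,
    anisotropy = anisometry, bulkiness = bulkiness,
    structurefactor = structurefactor, sides = sides,
    iod = iod, numruns = numruns, meanlength = meanlength)
}

# invert 4 n tan(pi/n) = ratio for the equivalent regular-polygon side count
.polygonSides <- function(ratio) {
  f <- function(n) 4 * n * tan(pi / n) - ratio
  lo <- 2.05; hi <- 60
  if (!is.finite(ratio)) return(lo)
  flo <- 4 * lo * tan(pi / lo); fhi <- 4 * hi * tan(pi / hi)
  if (ratio >= flo) return(lo)
  if (ratio <= fhi) return(hi)
  stats::uniroot(f, c(lo, hi))$root
}

#' Frozen feature-name order
#'
#' The selected 28-feature set: 20 morphologic names followed by 8 texture
#' names; or the extended 30-name set (adds integrated optical density and
#' the run-length pair, and collapses the two anisotropies to the texture
#' one).  The order is frozen and is the CSV column order.
#'
#' @param extended logical.
#' @return character vector of length 28 or 30.
#' @export
featureNames <- function(extended = FALSE) {
  if (extended) {
    c("iod", "area", "circularity", "roundness", "radius", "deviation",
      "mean", "sigma", "contrast", "convexity", "bulkiness",
      "structurefactor", "Ia", "Ib", "M11", "M20", "M02", "energy",
      "correlation", "homogeneity", "entropy", "anisotropy_tex",
      "compactness", "contlength", "diameter", "rectangularity",
      "distance", "sides", "numruns", "meanlength")
  } else {
    c("area", "circularity", "distance", "sigma", "sides", "roundness",
      "convexity", "Ia", "Ib", "M11", "M02", "M20", "compactness",
      "contlength", "diameter", "radius", "rectangularity", "anisotropy",
      "bulkiness", "structurefactor",
      "contrast", "energy", "homogeneity", "correlation", "entropy",
      "anisotropy_tex", "mean", "deviation")
  }
}

#' Extract the per-region feature vector
#'
#' Assembles the selected 28 features (20 morphologic + 8 texture) in the
#' frozen [featureNames()] order, or the extended 30-name set.
#'
#' @param region a [CellRegion-class].
#' @param extended emit the extended 30-name set.
#' @param I0 reference background gray for the integrated optical density
#'   (extended set only).
#' @param glcmLevels gray quantization levels for the co-occurrence
#'   features.
#' @return named numeric vector of length 28 (or 30), all values finite.
#' @export
extractFeatures <- function(region, extended = FALSE, I0 = 255,
                            glcmLevels = 32L) {
  st <- regionStats(region)
  all <- c(
    morphologyFeatures(region, I0 = I0),
    intensityShapeFeatures(region, st),
    inertiaFeatures(st),
    M11 = st$M11, M20 = st$M20, M02 = st$M02,
    glcmTexture(region, levels = glcmLevels),
    textureMeanDeviation(region)
  )
  all[featureNames(extended)]
}

#' Feature table for a dataset
#'
#' Segments each image (valley threshold), extracts its nucleus region and
#' feature vector, and returns one row per image with the label column
#' appended.
#'
#' @param dataset a \code{FixtureDataset} from [generateDataset()], or a
#'   list of gray matrices.
#' @param labels integer labels (taken from the dataset when omitted).
#' @param extended,glcmLevels passed to [extractFeatures()].
#' @return data.frame: the feature columns in [featureNames()] order plus
#'   \code{label}.
#' @export
featureTable <- function(dataset, labels = NULL, extended = FALSE,
                         glcmLevels = 32L) {
  images <- if (inherits(dataset, "FixtureDataset")) dataset$images else dataset
  if (is.null(labels) && inherits(dataset, "FixtureDataset"))
    labels <- dataset$labels
  rows <- lapply(images, function(im) {
    seg <- segmentImage(im)
    region <- extractRegion(im, seg)
    extractFeatures(region, extended = extended, I0 = seg$threshold,
                    glcmLevels = glcmLevels)
  })
  df <- as.data.frame(do.call(rbind, rows))
  if (!is.null(labels)) df$label <- as.integer(labels)
  df
}
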