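#' Synthesis configuration
#'
#' Collects the tunables of the overlap synthesis chain.
#'
#' @param I0 background gray used for optical-density conversion, in
#'   1..255, or \code{NULL} to use the segmentation threshold of the first
#'   source image (the background mean and the threshold coincide for a
#'   valley threshold between the nucleus and background modes).
#' @param angleRange rotation-angle interval in degrees; both source
#'   regions draw their angle uniformly from it.
#' @param overlapFractionRange sub-interval of [0, 1] restricting the drawn
#'   overlap length to \code{range * R_min/2}; the default keeps the full
#'   admissible interval \eqn{0 \le d \le R_{min}/2}.
#' @return a list of class \code{SynthesisConfig}.
#' @export
synthesisConfig <- function(I0 = NULL, angleRange = c(0, 360),
                            overlapFractionRange = c(0, 1)) {
  if (!is.null(I0) && (I0 <= 0 || I0 > 255)) stop("I0 must be in (0, 255]")
  stopifnot(length(angleRange) == 2L, angleRange[1] <= angleRange[2],
            length(overlapFractionRange) == 2L,
            overlapFractionRange[1] >= 0, overlapFractionRange[2] <= 1,
            overlapFractionRange[1] <= overlapFractionRange[2])
  structure(list(I0 = I0, angleRange = angleRange,
                 overlapFractionRange = overlapFractionRange),
            class = "SynthesisConfig")
}

#' Rotate a region about its centroid
#'
#' Rotates patch and mask with bilinear interpolation on an expanded canvas
#' (nothing clips), re-binarizes the mask at 0.5, sets pixels outside the
#' rotated mask back to the white sentinel, and recomputes contour,
#' centroid and bounding box.  Rotating about the patch center and
#' re-deriving the centroid is equivalent to rotating about the centroid up
#' to a translation, which the later placement step absorbs.
#'
#' @param region a [CellRegion-class].
#' @param angle rotation angle in degrees.
#' @return the rotated \code{CellRegion}.
#' @export
rotateRegion <- function(region, angle) {
  if (angle %% 360 == 0) return(region)
  rp <- .fromEB(EBImage::rotate(.asEB(region@patch / 255), angle,
                                bg.col = "white")) * 255
  rm <- .fromEB(EBImage::rotate(.asEB(region@mask * 1), angle,
                                bg.col = "black")) >= 0.5
  if (!any(rm)) stop("rotation produced an empty mask")
  rp <- round(pmin(pmax(rp, 0), 255))
  .makeRegion(rp, rm, label = region@label, cells = region@cellCount)
}

#' Draw a random overlap length
#'
#' The overlap length \eqn{d} between the two regions' bounding rectangles
#' is drawn uniformly on \eqn{[0, R_{min}/2]}, where \eqn{R_{min}} is the
#' minimum bounding-box side (width or height) over the two nuclear
#' regions.
#'
#' @param gen an [LCG-class] generator.
#' @param region1,region2 the two [CellRegion-class] objects.
#' @param fractionRange optional sub-interval of [0, 1] restricting the
#'   draw to \code{fractionRange * R_min/2}.
#' @return a list of class \code{OverlapSpec} with fields \code{d} (real,
#'   pixels) and \code{Rmin}.
#' @export
sampleOverlapLength <- function(gen, region1, region2,
                                fractionRange = c(0, 1)) {
  dims <- function(r) c(ncol(r@mask), nrow(r@mask))
  Rmin <- min(c(dims(region1), dims(region2)))
  f <- lcgUniform(gen, 1L, fractionRange[1], fractionRange[2])
  structure(list(d = f * Rmin / 2, Rmin = Rmin), class = "OverlapSpec")
}

#' Place two regions on a shared background canvas
#'
#' Region 1 is anchored on a canvas large enough to hold both; region 2 is
#' positioned along the horizontal axis through region 1's centroid so the
#' two bounding rectangles overlap by exactly \code{round(d)} pixels along
#' that axis (\code{d = 0} gives tangent rectangles), and is centered
#' vertically on that axis.
#'
#' @param region1,region2 [CellRegion-class] objects.
#' @param d overlap length in pixels (rounded to the pixel grid).
#' @param margin background margin around the union, in pixels.
#' @return a list of class \code{Placement}: \code{size = c(width, height)}
#'   of the canvas, and \code{offset1}, \code{offset2}: 0-based
#'   \code{(a, b)} top-left anchors of each region's patch in background
#'   coordinates.
#' @export
placeRegions <- function(region1, region2, d, margin = 2L) {
  d <- round(d)
  w1 <- ncol(region1@mask); h1 <- nrow(region1@mask)
  w2 <- ncol(region2@mask); h2 <- nrow(region2@mask)
  if (d > min(w1, w2)) stop("geometry error: overlap exceeds region width")
  a1 <- c(0, 0)
  a2x <- w1 - d
  a2y <- round(region1@centroid[2] - h2 / 2)
  a2 <- c(a2x, a2y)
  shift <- c(margin, margin) - pmin(a1, a2)
  a1 <- a1 + shift; a2 <- a2 + shift
  size <- c(max(a1[1] + w1, a2[1] + w2) + margin,
            max(a1[2] + h1, a2[2] + h2) + margin)
  structure(list(size = unname(size), offset1 = unname(a1),
                 offset2 = unname(a2), d = d),
            class = "Placement")
}

#' Background-to-local coordinate transformation
#'
#' Maps a background-canvas position \code{(X, Y)} to the local position in
#' a source patch anchored at \code{(a, b)}: \code{x = X - a, y = Y - b}.
#' \code{toGlobal} is the inverse.  Vectorized.
#'
#' @param X,Y background coordinates (0-based).
#' @param anchor length-2 \code{(a, b)} patch anchor in background
#'   coordinates.
#' @return two-column matrix of (x, y) local (resp. global) coordinates.
#' @export
toLocal <- function(X, Y, anchor) {
  cbind(x = X - anchor[1], y = Y - anchor[2])
}

#' @rdname toLocal
#' @param x,y local coordinates (0-based).
#' @export
toGlobal <- function(x, y, anchor) {
  cbind(X = x + anchor[1], Y = y + anchor[2])
}

#' Locate the overlap pixel set
#'
#' Intersects the two bounding rectangles in background coordinates, widens
#' the intersection by 2 pixels along its width to form the search
#' rectangle, and traverses every non-white pixel in it, keeping positions
#' that fall inside both region masks.  These are the pixels whose gray
#' values must be reconstructed.
#'
#' @param region1,region2 [CellRegion-class] objects.
#' @param placement a \code{Placement} from [placeRegions()].
#' @return integer matrix with columns \code{X}, \code{Y} (0-based
#'   background coordinates); zero rows when the rectangles are disjoint.
#' @export
findOverlapPixels <- function(region1, region2, placement) {
  empty <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("X", "Y")))
  b1 <- c(placement$offset1, placement$offset1 +
            c(ncol(region1@mask), nrow(region1@mask)))
  b2 <- c(placement$offset2, placement$offset2 +
            c(ncol(region2@mask), nrow(region2@mask)))
  ix <- c(max(b1[1], b2[1]), min(b1[3], b2[3]))
  iy <- c(max(b1[2], b2[2]), min(b1[4], b2[4]))
  if (ix[1] >= ix[2] || iy[1] >= iy[2]) return(empty)
  # search rectangle: intersection width plus one pixel each side
  sx <- c(ix[1] - 1, ix[2] + 1)
  Xs <- seq.int(sx[1], sx[2] - 1L)
  Ys <- seq.int(iy[1], iy[2] - 1L)
  grid <- cbind(X = rep(Xs, times = length(Ys)),
                Y = rep(Ys, each = length(Xs)))
  inMask <- function(region, anchor) {
    l <- toLocal(grid[, 1], grid[, 2], anchor)
    ok <- l[, 1] >= 0 & l[, 1] < ncol(region@mask) &
      l[, 2] >= 0 & l[, 2] < nrow(region@mask)
    res <- logical(nrow(grid))
    res[ok] <- region@mask[cbind(l[ok, 2] + 1L, l[ok, 1] + 1L)]
    res
  }
  keep <- inMask(region1, placement$offset1) &
    inMask(region2, placement$offset2)
  if (!any(keep)) return(empty)
  grid[keep, , drop = FALSE]
}

#' Beer-Lambert pixel reconstruction
#'
#' Converts the two overlapping gray values to optical densities
#' \eqn{A_i = \lg(I_0/I_i)}, adds them (absorbing material stacks), and
#' converts back: \eqn{I_s = I_1 I_2 / I_0}.  Gray zeros are clamped to 1
#' before conversion (the optical density of 0 diverges).  Vectorized.
#'
#' @param I1,I2 gray values of the pixel in the first and second cell.
#' @param I0 background gray (> 0) used as the blank reference.
#' @param round if TRUE (default), round half-up to an integer gray and
#'   clip to [0, 255]; FALSE returns the unrounded value (useful for
#'   checking the optical-density identity exactly).
#' @return reconstructed gray value(s) \eqn{I_s}.
#' @export
reconstructPixel <- function(I1, I2, I0, round = TRUE) {
  if (any(I0 <= 0)) stop("invalid model error: I0 must be positive")
  I1 <- pmax(I1, 1)
  I2 <- pmax(I2, 1)
  v <- I1 * I2 / I0
  if (round) pmin(pmax(floor(v + 0.5), 0), 255) else v
}

#' Optical density and integrated optical density
#'
#' \code{opticalDensity} converts gray to OD, \eqn{\lg(I_0/I)} with zeros
#' clamped to 1.  \code{integratedOD} sums the OD over a set of nucleus
#' pixels (a mask on an image, or a region), the standard DNA-content proxy
#' in ploidy analysis.
#'
#' @param I gray value(s).
#' @param I0 background gray (> 0).
#' @return numeric OD value(s) / their sum.
#' @export
opticalDensity <- function(I, I0) {
  if (any(I0 <= 0)) stop("invalid model error: I0 must be positive")
  log10(I0 / pmax(I, 1))
}

#' @rdname opticalDensity
#' @param image gray matrix.
#' @param mask logical matrix selecting nucleus pixels; \code{NULL} sums
#'   over pixels darker than \code{I0}.
#' @export
integratedOD <- function(image, I0, mask = NULL) {
  if (is.null(mask)) mask <- image < I0
  sum(opticalDensity(image[mask], I0))
}

#' Composite two placed regions into one image
#'
#' Fills the background canvas with \code{I0}, copies each region's
#' non-overlap nucleus pixels unchanged, and sets every overlap-set pixel
#' to the Beer-Lambert reconstruction of the two source gray values read
#' through the coordinate transformation.
#'
#' @param region1,region2 [CellRegion-class] objects.
#' @param placement a \code{Placement}.
#' @param overlap overlap pixel set from [findOverlapPixels()].
#' @param I0 background gray for the canvas and the OD conversion.
#' @param roundGray round reconstructed overlap grays to integers (the
#'   normal image output); FALSE keeps them real-valued, on which the
#'   optical-density conservation is exact.
#' @return numeric gray matrix (the synthesized image).
#' @export
compositeRegions <- function(region1, region2, placement, overlap, I0,
                             roundGray = TRUE) {
  canvas <- matrix(I0, nrow = placement$size[2], ncol = placement$size[1])
  paste1 <- function(region, anchor) {
    idx <- which(region@mask, arr.ind = TRUE)
    gx <- idx[, 2] - 1L + anchor[1]
    gy <- idx[, 1] - 1L + anchor[2]
    canvas[cbind(gy + 1L, gx + 1L)] <<- region@patch[idx]
  }
  paste1(region1, placement$offset1)
  paste1(region2, placement$offset2)
  if (nrow(overlap) > 0) {
    l1 <- toLocal(overlap[, 1], overlap[, 2], placement$offset1)
    l2 <- toLocal(overlap[, 1], overlap[, 2], placement$offset2)
    m1 <- region1@mask[cbind(l1[, 2] + 1L, l1[, 1] + 1L)]
    m2 <- region2@mask[cbind(l2[, 2] + 1L, l2[, 1] + 1L)]
    if (!all(m1 & m2))
      stop("internal consistency error: overlap pixel outside a region mask")
    I1 <- region1@patch[cbind(l1[, 2] + 1L, l1[, 1] + 1L)]
    I2 <- region2@patch[cbind(l2[, 2] + 1L, l2[, 1] + 1L)]
    canvas[cbind(overlap[, 2] + 1L, overlap[, 1] + 1L)] <-
      reconstructPixel(I1, I2, I0, round = roundGray)
  }
  canvas
}

#' Synthesize an overlapping-nucleus image from two source images
#'
#' The full chain: segment both sources (valley threshold), extract their
#' nucleus regions, rotate each by a random angle, draw a random overlap
#' length, place the regions, locate the overlap pixel set, and composite
#' with Beer-Lambert reconstruction.  An i-cell and a j-cell source yield
#' an (i+j)-cell image.
#'
#' @param imageA,imageB source gray matrices (i-cell and j-cell images).
#' @param gen an [LCG-class] generator (drives angles and overlap length).
#' @param config a [synthesisConfig()].
#' @param cellsA,cellsB nucleus counts of the two sources.
#' @return a list of class \code{SynthesisResult}: \code{image} (gray
#'   matrix), \code{cellCount = cellsA + cellsB}, and \code{meta} (angles,
#'   d, Rmin, I0, overlap pixel count, source thresholds).
#' @export
synthesizeOverlap <- function(imageA, imageB, gen,
                              config = synthesisConfig(),
                              cellsA = 1L, cellsB = 1L) {
  step <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  segA <- step("segment A", segmentImage(imageA))
  segB <- step("segment B", segmentImage(imageB))
  rA <- step("extract A", extractRegion(imageA, segA, cells = cellsA))
  rB <- step("extract B", extractRegion(imageB, segB, cells = cellsB))
  angles <- lcgUniform(gen, 2L, config$angleRange[1], config$angleRange[2])
  rA <- step("rotate A", rotateRegion(rA, angles[1]))
  rB <- step("rotate B", rotateRegion(rB, angles[2]))
  spec <- sampleOverlapLength(gen, rA, rB, config$overlapFractionRange)
  placement <- step("place", placeRegions(rA, rB, spec$d))
  overlap <- step("overlap", findOverlapPixels(rA, rB, placement))
  I0 <- if (is.null(config$I0)) segA$threshold else config$I0
  img <- step("composite",
              compositeRegions(rA, rB, placement, overlap, I0))
  structure(list(
    image = img,
    cellCount = as.integer(cellsA + cellsB),
    meta = list(angles = angles, d = spec$d, Rmin = spec$Rmin, I0 = I0,
                overlapCount = nrow(overlap),
                thresholdA = segA$threshold, thresholdB = segB$threshold)
  ), class = "SynthesisResult")
}
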