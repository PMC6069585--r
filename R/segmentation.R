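# EBImage stores pixel arrays with dim1 = x; package matrices are [y, x],
# so every call into EBImage transposes on the way in and out.
.asEB <- function(m) EBImage::Image(t(m))
.fromEB <- function(img) t(EBImage::imageData(img))

#' Valley-point histogram threshold
#'
#' Finds the gray threshold at the deepest local minimum of the smoothed
#' 256-bin histogram strictly between its two highest modes.  Dark-nucleus
#' pixels fall below the threshold; the bright background lies above it.
#' When the histogram has no interior valley (fewer than two modes, or
#' adjacent modes), Otsu's threshold is returned instead and the fallback is
#' flagged.
#'
#' @param image numeric gray matrix in [0, 255]; must not be constant.
#' @param smooth width of the moving-average window applied to the raw
#'   histogram before the valley search (odd integer; small images have
#'   jagged histograms).
#' @return integer threshold in 0..255 with attribute \code{method}, either
#'   \code{"valley"} or \code{"otsu"}.
#' @export
valleyThreshold <- function(image, smooth = 5L) {
  v <- round(as.vector(image))
  if (max(v) == min(v)) stop("no-contrast error: constant image")
  h <- tabulate(pmin(pmax(v, 0), 255) + 1L, nbins = 256L)
  k <- rep(1 / smooth, smooth)
  hs <- stats::filter(h, k, sides = 2)
  hs[is.na(hs)] <- 0
  hs <- as.numeric(hs)
  # interior local maxima; flat runs inherit the preceding slope so a
  # plateau peak counts once
  sf <- sign(diff(hs))
  for (i in seq_along(sf)) if (sf[i] == 0 && i > 1L) sf[i] <- sf[i - 1L]
  peaks <- which(sf[-length(sf)] > 0 & sf[-1] < 0) + 1L
  if (length(peaks) < 2L) return(.otsuFallback(image))
  ord <- order(hs[peaks], decreasing = TRUE)
  p2 <- sort(peaks[ord[1:2]])
  if (p2[2] - p2[1] < 2L) return(.otsuFallback(image))
  between <- (p2[1] + 1L):(p2[2] - 1L)
  valley <- between[which.min(hs[between])]
  T <- as.integer(valley - 1L)  # bin i holds gray level i-1
  attr(T, "method") <- "valley"
  T
}

.otsuFallback <- function(image) {
  T <- as.integer(round(EBImage::otsu(.asEB(image / 255), range = c(0, 1),
                                      levels = 256) * 255))
  attr(T, "method") <- "otsu"
  T
}

#' Threshold segmentation of a nucleus image
#'
#' Binarizes the image at threshold \code{T}: pixels with gray value
#' \eqn{f(x,y) \ge T} are background (\code{F = 1}), pixels below it are
#' nucleus (\code{F = 0}).  Note the boundary case \eqn{f = T} is
#' background.
#'
#' @param image numeric gray matrix in [0, 255].
#' @param T threshold in 0..255; if \code{NULL}, [valleyThreshold()] is used.
#' @return a list of class \code{SegmentationResult}: \code{threshold}
#'   (integer), \code{F} (integer matrix, 1 = background, 0 = nucleus) and
#'   \code{method} ("valley", "otsu" or "given").
#' @export
segmentImage <- function(image, T = NULL) {
  method <- "given"
  if (is.null(T)) {
    T <- valleyThreshold(image)
    method <- attr(T, "method")
  }
  stopifnot(T >= 0, T <= 255)
  F <- matrix(as.integer(image >= T), nrow = nrow(image))
  structure(list(threshold = as.integer(T), F = F, method = method),
            class = "SegmentationResult")
}

# Build a CellRegion from a full-frame mask + image: crop to tight bbox,
# white out background, trace contour, compute centroid.
.makeRegion <- function(image, mask, label = NA_integer_, cells = 1L) {
  if (!any(mask)) stop("no-region error: empty foreground")
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  sub <- mask[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  patch <- image[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  patch[!sub] <- 255
  oc <- EBImage::ocontour(.asEB(matrix(as.integer(sub), nrow = nrow(sub))))[[1]]
  # ocontour returns 0-based (x, y) on the transposed array = (y, x) here
  contour <- cbind(x = oc[, 2], y = oc[, 1])
  idx <- which(sub, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]) - 1, y = mean(idx[, 1]) - 1)
  bbox <- c(cols[1] - 1, rows[1] - 1, cols[2], rows[2])
  new("CellRegion", patch = patch, mask = sub, contour = contour,
      centroid = centroid, bbox = as.numeric(bbox),
      label = as.integer(label), cellCount = as.integer(cells))
}

#' Extract the nucleus region from a segmentation
#'
#' Keeps the largest 4-connected nucleus component of the segmentation,
#' fills interior holes, and returns a [CellRegion-class] with the patch cut
#' to the tight bounding box (background pixels set to the white sentinel
#' 255), the traced boundary contour, the mask centroid, and the bounding
#' box in source coordinates.
#'
#' @param image the source gray matrix.
#' @param seg a \code{SegmentationResult} from [segmentImage()].
#' @param label optional class label to attach.
#' @param cells number of nuclei the region is known to contain.
#' @return a \code{CellRegion}.
#' @export
extractRegion <- function(image, seg, label = NA_integer_, cells = 1L) {
  nucleus <- seg$F == 0L
  if (!any(nucleus)) stop("no-region error: empty foreground")
  lab <- .fromEB(EBImage::bwlabel(.asEB(matrix(as.integer(nucleus),
                                               nrow = nrow(nucleus)))))
  counts <- tabulate(lab[lab > 0])
  keep <- which.max(counts)
  comp <- lab == keep
  comp <- .fromEB(EBImage::fillHull(.asEB(matrix(as.integer(comp),
                                                 nrow = nrow(comp))))) > 0
  .makeRegion(image, comp, label = label, cells = cells)
}

#' Dice overlap of two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return Dice coefficient \eqn{2|a \cap b| / (|a| + |b|)}.
#' @export
diceOverlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  2 * sum(a & b) / (sum(a) + sum(b))
}
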