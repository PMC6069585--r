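#' @import methods
NULL

#' Linear congruential random number generator
#'
#' S4 class holding the state of a linear congruential generator (LCG)
#' with recurrence \eqn{x_n = (\alpha x_{n-1} + c) \bmod M} and emitted
#' uniform values \eqn{\lambda_n = x_n / M \in [0, 1)}.  All stochastic
#' choices in the package (rotation angles, overlap lengths, fixture noise,
#' source-pair sampling) draw from this generator, so a whole pipeline run
#' is reproducible from a single seed.
#'
#' The state is kept in an environment so that draws advance the generator
#' in place; the constants \code{alpha}, \code{inc} and \code{modulus} are
#' fixed at construction.
#'
#' @slot state environment with a single numeric field \code{x}, the current
#'   state \eqn{x_n} (an integer value stored as double; the default modulus
#'   \eqn{2^{32}} exceeds R's integer range but all arithmetic stays exact in
#'   doubles).
#' @slot alpha numeric scalar, the multiplier \eqn{\alpha}.
#' @slot inc numeric scalar, the increment \eqn{c}.
#' @slot modulus numeric scalar, the modulus \eqn{M > 0}.
#'
#' @seealso [LCG()], [lcgNext()], [lcgUniform()]
#' @name LCG-class
#' @rdname LCG-class
#' @exportClass LCG
setClass("LCG",
  representation(
    state = "environment",
    alpha = "numeric",
    inc = "numeric",
    modulus = "numeric"
  )
)

setValidity("LCG", function(object) {
  msg <- character(0)
  a <- object@alpha; cc <- object@inc; M <- object@modulus
  if (length(M) != 1L || !is.finite(M) || M < 1 || M != floor(M))
    msg <- c(msg, "modulus M must be a positive integer")
  if (length(a) != 1L || !is.finite(a) || a < 0 || a != floor(a))
    msg <- c(msg, "multiplier alpha must be a nonnegative integer")
  if (length(cc) != 1L || !is.finite(cc) || cc < 0 || cc != floor(cc))
    msg <- c(msg, "increment c must be a nonnegative integer")
  x <- object@state$x
  if (!is.numeric(x) || length(x) != 1L || x < 0 || (length(M) == 1L && is.finite(M) && x >= M))
    msg <- c(msg, "state x must satisfy 0 <= x < M")
  # products alpha*x must stay exactly representable in doubles
  if (length(a) == 1L && length(M) == 1L && is.finite(a) && is.finite(M) &&
      a * (M - 1) + cc >= 2^53)
    msg <- c(msg, "alpha*(M-1)+c must be below 2^53 for exact arithmetic")
  if (length(msg)) msg else TRUE
})

#' Segmented nucleus region
#'
#' S4 container for one segmented nucleus region: the grayscale patch cut to
#' the region's bounding box (background pixels replaced by the white
#' sentinel 255), the binary mask, the ordered boundary contour, the mask
#' centroid, and the bounding box locating the patch in its source image.
#'
#' Coordinate conventions: images are numeric matrices indexed
#' \code{[row, col]} with row = y and col = x; pixel coordinates are 0-based
#' with \code{(x, y) = (column, row)}.  \code{contour} and \code{centroid}
#' are in patch-local 0-based coordinates; \code{bbox} is
#' \code{(x_min, y_min, x_max, y_max)}, 0-based and half-open on the max
#' edges, in source-image coordinates.
#'
#' @slot patch numeric matrix, grayscale values in [0, 255]; non-mask pixels
#'   are 255 ("background removed").
#' @slot mask logical matrix of the same dimensions, TRUE on nucleus pixels;
#'   a single 4-connected component with interior holes filled.
#' @slot contour numeric matrix with columns (x, y): ordered boundary pixel
#'   coordinates, patch-local, 0-based.
#' @slot centroid numeric length-2 (x, y): mask centroid, patch-local, 0-based.
#' @slot bbox numeric length-4 (x_min, y_min, x_max, y_max) in source
#'   coordinates, half-open.
#' @slot label integer class label (NA if unknown).
#' @slot cellCount integer, number of nuclei the region is known to contain.
#'
#' @seealso [extractRegion()], [rotateRegion()], accessors [regionMask()],
#'   [regionPatch()], [regionContour()], [regionCentroid()], [regionBBox()]
#' @name CellRegion-class
#' @rdname CellRegion-class
#' @exportClass CellRegion
setClass("CellRegion",
  representation(
    patch = "matrix",
    mask = "matrix",
    contour = "matrix",
    centroid = "numeric",
    bbox = "numeric",
    label = "integer",
    cellCount = "integer"
  )
)

setValidity("CellRegion", function(object) {
  msg <- character(0)
  if (!identical(dim(object@patch), dim(object@mask)))
    msg <- c(msg, "patch and mask dimensions differ")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be a logical matrix")
  else if (!any(object@mask))
    msg <- c(msg, "mask is empty")
  if (length(object@centroid) != 2L)
    msg <- c(msg, "centroid must have length 2 (x, y)")
  if (length(object@bbox) != 4L)
    msg <- c(msg, "bbox must have length 4 (x_min, y_min, x_max, y_max)")
  else {
    w <- object@bbox[3] - object@bbox[1]
    h <- object@bbox[4] - object@bbox[2]
    if (w != ncol(object@patch) || h != nrow(object@patch))
      msg <- c(msg, "bbox extent must equal patch dimensions")
  }
  if (length(object@centroid) == 2L && any(object@mask)) {
    if (object@centroid[1] < 0 || object@centroid[1] > ncol(object@patch) - 1 ||
        object@centroid[2] < 0 || object@centroid[2] > nrow(object@patch) - 1)
      msg <- c(msg, "centroid must lie inside the patch")
  }
  if (ncol(object@contour) != 2L)
    msg <- c(msg, "contour must have two columns (x, y)")
  if (length(msg)) msg else TRUE
})

#' @describeIn LCG-class compact display of constants and current state
#' @param object an object of the class
#' @export
setMethod("show", "LCG", function(object) {
  cat("LCG generator: x_n = (", format(object@alpha), " * x + ",
      format(object@inc), ") mod ", format(object@modulus),
      "; current x = ", format(object@state$x), "\n", sep = "")
})

#' @describeIn CellRegion-class compact display of geometry
#' @export
setMethod("show", "CellRegion", function(object) {
  cat("CellRegion: ", sum(object@mask), " px mask in a ",
      ncol(object@patch), "x", nrow(object@patch), " patch; centroid (",
      round(object@centroid[1], 1), ", ", round(object@centroid[2], 1),
      "); label ", object@label, "; cells ", object@cellCount, "\n", sep = "")
})

#' CellRegion accessors
#'
#' Read the components of a [CellRegion-class] without touching slots.
#'
#' @param region a \code{CellRegion}
#' @return \code{regionMask}: logical matrix; \code{regionPatch}: numeric
#'   matrix; \code{regionContour}: two-column matrix of 0-based (x, y);
#'   \code{regionCentroid}: numeric (x, y); \code{regionBBox}: numeric
#'   (x_min, y_min, x_max, y_max); \code{regionArea}: integer pixel count;
#'   \code{cellCount}: integer.
#' @name region-accessors
#' @export
regionMask <- function(region) region@mask

#' @rdname region-accessors
#' @export
regionPatch <- function(region) region@patch

#' @rdname region-accessors
#' @export
regionContour <- function(region) region@contour

#' @rdname region-accessors
#' @export
regionCentroid <- function(region) region@centroid

#' @rdname region-accessors
#' @export
regionBBox <- function(region) region@bbox

#' @rdname region-accessors
#' @export
regionArea <- function(region) sum(region@mask)

#' @rdname region-accessors
#' @export
cellCount <- function(region) region@cellCount
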