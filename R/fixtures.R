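#' Specification of one synthetic nucleus
#'
#' Parameters of a Feulgen-like fixture nucleus: a dark ellipse on a bright
#' background.  Intensity ramps linearly with the normalized elliptical
#' radius from \code{centerGray} at the centroid to
#' \code{centerGray + rimFraction * (backgroundGray - centerGray)} at the
#' rim, so the nucleus blends toward the background while keeping a sharp
#' enough rim that the histogram retains a valley, and so the optical
#' density is positive everywhere inside the nucleus as the Beer-Lambert
#' compositing requires.
#'
#' @param semiaxes length-2 positive pixel semi-axes (a, b).
#' @param orientation ellipse orientation in degrees.
#' @param centerGray dark central gray (e.g. 60..120).
#' @param backgroundGray bright background gray (e.g. 180..220); must
#'   exceed \code{centerGray}.
#' @param noiseSd standard deviation of additive pseudo-Gaussian noise in
#'   gray units.
#' @param classLabel integer class label 1..8.
#' @param rimFraction fraction of the center-to-background gray span
#'   reached at the rim (in (0, 1)).
#' @return a list of class \code{NucleusSpec}.
#' @export
nucleusSpec <- function(semiaxes, orientation = 0, centerGray = 90,
                        backgroundGray = 200, noiseSd = 0,
                        classLabel = 1L, rimFraction = 0.6) {
  if (any(semiaxes <= 0)) stop("semiaxes must be positive")
  if (centerGray >= backgroundGray)
    stop("centerGray must be less than backgroundGray")
  stopifnot(noiseSd >= 0, rimFraction > 0, rimFraction < 1)
  structure(list(semiaxes = semiaxes, orientation = orientation,
                 centerGray = centerGray, backgroundGray = backgroundGray,
                 noiseSd = noiseSd, classLabel = as.integer(classLabel),
                 rimFraction = rimFraction),
            class = "NucleusSpec")
}

#' Generate a synthetic single-nucleus image
#'
#' Renders the elliptical nucleus of a [nucleusSpec()] on a bright
#' background, adds pseudo-Gaussian noise from the package generator
#' (clipped to [0, 255]), and returns the image together with the ground
#' truth mask of the ellipse interior.
#'
#' @param spec a \code{NucleusSpec}.
#' @param gen an [LCG-class] generator (used only when \code{noiseSd > 0}).
#' @param canvas length-2 (width, height) in pixels; default 4x the major
#'   semi-axis so later rotation never clips.
#' @return list with \code{image} (gray matrix) and \code{truthMask}
#'   (logical matrix marking the ellipse interior).
#' @export
generateNucleus <- function(spec, gen = NULL, canvas = NULL) {
  a <- spec$semiaxes[1]; b <- spec$semiaxes[2]
  if (is.null(canvas)) {
    side <- ceiling(4 * max(a, b))
    canvas <- c(side, side)
  }
  w <- canvas[1]; h <- canvas[2]
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  if (max(a, b) * 2 + 2 > min(w, h))
    stop("geometry error: ellipse larger than canvas")
  x <- matrix(rep(0:(w - 1), each = h), nrow = h) - cx
  y <- matrix(rep(0:(h - 1), times = w), nrow = h) - cy
  th <- spec$orientation * pi / 180
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  rho <- sqrt(u^2 + v^2)
  inside <- rho <= 1
  rim <- spec$centerGray +
    spec$rimFraction * (spec$backgroundGray - spec$centerGray)
  img <- matrix(spec$backgroundGray, nrow = h, ncol = w)
  img[inside] <- spec$centerGray + (rim - spec$centerGray) * rho[inside]
  if (spec$noiseSd > 0) {
    if (is.null(gen)) stop("a generator is required when noiseSd > 0")
    img <- img + matrix(lcgNormal(gen, w * h, 0, spec$noiseSd),
                        nrow = h, ncol = w)
  }
  img <- round(pmin(pmax(img, 0), 255))
  list(image = img, truthMask = inside)
}

#' Default per-class fixture parameter ranges
#'
#' One entry per cell class of the 8-class ploidy taxonomy: 1 single
#' typical epithelial, 2 single atypical epithelial, 3 two epithelial, 4
#' three epithelial, 5 four or more epithelial, 6 single lymphocyte, 7
#' single centriole, 8 two or more centrioles.  Composite classes (3, 4,
#' 5, 8) carry the component recipe used by [generateClassImage()];
#' singleton classes carry size and intensity ranges.  Epithelial nuclei
#' are mid-size and moderately dark; lymphocytes small and dark;
#' centrioles small and pale.
#'
#' @param noiseSd common additive noise level in gray units.
#' @param backgroundGray common background gray.
#' @return named list, one sub-list per class \code{"1"}..\code{"8"}.
#' @export
classSpecRanges <- function(noiseSd = 6, backgroundGray = 200) {
  single <- function(axes, gray) list(kind = "single", axes = axes,
                                      gray = gray)
  comp <- function(base, add) list(kind = "composite", base = base,
                                   add = add)
  list(
    "1" = single(c(11, 16), c(90, 115)),
    "2" = single(c(14, 20), c(70, 95)),
    "3" = comp(base = c(1L, 2L), add = c(1L, 2L)),
    "4" = comp(base = 3L, add = c(1L, 2L)),
    "5" = comp(base = 4L, add = c(1L, 2L)),
    "6" = single(c(7, 10), c(70, 90)),
    "7" = single(c(6, 9), c(100, 125)),
    "8" = comp(base = 7L, add = 7L),
    noiseSd = noiseSd, backgroundGray = backgroundGray
  )
}

# Draw a random NucleusSpec for a singleton class.
.sampleSpec <- function(class, ranges, gen) {
  r <- ranges[[as.character(class)]]
  stopifnot(r$kind == "single")
  ax <- lcgUniform(gen, 2L, r$axes[1], r$axes[2])
  nucleusSpec(semiaxes = sort(ax, decreasing = TRUE),
              orientation = lcgUniform(gen, 1L, 0, 180),
              centerGray = lcgUniform(gen, 1L, r$gray[1], r$gray[2]),
              backgroundGray = ranges$backgroundGray,
              noiseSd = ranges$noiseSd, classLabel = class)
}

#' Generate one fixture image of a given class
#'
#' Singleton classes render a fresh random nucleus; composite classes draw
#' a base image (recursively, or from a supplied pool of already generated
#' images) and a single-nucleus add-on, and compose them with
#' [synthesizeOverlap()].
#'
#' @param class integer class label 1..8.
#' @param ranges parameter ranges from [classSpecRanges()].
#' @param gen an [LCG-class] generator.
#' @param pool optional named list of per-class image lists; composite
#'   classes sample their base component from the pool (uniformly, with
#'   replacement) instead of generating it recursively.
#' @return list with \code{image}, \code{cellCount} and (for composites)
#'   \code{meta} from the synthesis chain.
#' @export
generateClassImage <- function(class, ranges, gen, pool = NULL) {
  r <- ranges[[as.character(class)]]
  if (r$kind == "single") {
    nuc <- generateNucleus(.sampleSpec(class, ranges, gen), gen)
    return(list(image = nuc$image, cellCount = 1L))
  }
  pickBase <- function(classes) {
    cls <- classes[lcgInteger(gen, 1L, length(classes))]
    fromPool <- !is.null(pool) && length(pool[[as.character(cls)]]) > 0
    if (fromPool) {
      imgs <- pool[[as.character(cls)]]
      img <- imgs[[lcgInteger(gen, 1L, length(imgs))]]
      list(image = img$image, cellCount = img$cellCount)
    } else {
      generateClassImage(cls, ranges, gen, pool)
    }
  }
  base <- pickBase(r$base)
  addCls <- r$add[lcgInteger(gen, 1L, length(r$add))]
  add <- generateNucleus(.sampleSpec(addCls, ranges, gen), gen)
  syn <- synthesizeOverlap(base$image, add$image, gen,
                           cellsA = base$cellCount, cellsB = 1L)
  list(image = syn$image, cellCount = syn$cellCount, meta = syn$meta)
}

#' Generate a labeled (imbalanced) fixture dataset
#'
#' Emits \code{classCounts[k]} images for each class k: singleton classes
#' as fresh single-nucleus renders, composite classes via the synthesis
#' chain (earlier images of the run serve as the base pool, so 3-cell
#' images build on generated 2-cell images, and so on).  When \code{dir}
#' is given the images are written as 8-bit grayscale PNG with a
#' \code{manifest.csv} (\code{path,label}) and a JSON sidecar echoing the
#' generation parameters; otherwise images stay in memory.
#'
#' @param classCounts integer vector of length 8, images per class
#'   (zeros allowed).
#' @param gen an [LCG-class] generator.
#' @param ranges parameter ranges from [classSpecRanges()].
#' @param dir optional output directory.
#' @return a list of class \code{FixtureDataset}: \code{images} (list of
#'   gray matrices), \code{labels} (integer vector), \code{cellCounts},
#'   and \code{manifest} (data.frame \code{path,label}; paths are empty
#'   strings for in-memory datasets).
#' @export
generateDataset <- function(classCounts, gen, ranges = classSpecRanges(),
                            dir = NULL) {
  stopifnot(length(classCounts) == 8L, all(classCounts >= 0))
  # generation order guarantees composite bases exist in the pool
  order <- c(1L, 2L, 6L, 7L, 3L, 8L, 4L, 5L)
  pool <- stats::setNames(vector("list", 8), as.character(1:8))
  images <- list(); labels <- integer(0); cells <- integer(0)
  for (cls in order) {
    for (i in seq_len(classCounts[cls])) {
      im <- generateClassImage(cls, ranges, gen, pool)
      pool[[as.character(cls)]] <-
        c(pool[[as.character(cls)]], list(im))
      images <- c(images, list(im$image))
      labels <- c(labels, cls)
      cells <- c(cells, im$cellCount)
    }
  }
  # restore manifest to class order 1..8
  ord <- order(labels, method = "radix")
  images <- images[ord]; labels <- labels[ord]; cells <- cells[ord]
  paths <- rep("", length(images))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, sprintf("cell_%04d_class%d.png",
                                    seq_along(images), labels))
    for (i in seq_along(images)) writeGrayImage(images[[i]], paths[i])
    manifest <- data.frame(path = paths, label = labels)
    writeManifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(classCounts = classCounts, noiseSd = ranges$noiseSd,
           backgroundGray = ranges$backgroundGray),
      file.path(dir, "params.json"), auto_unbox = TRUE, digits = NA)
  }
  structure(list(images = images, labels = labels, cellCounts = cells,
                 manifest = data.frame(path = paths, label = labels)),
            class = "FixtureDataset")
}
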