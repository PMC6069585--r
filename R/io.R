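#' Read and write 8-bit grayscale images
#'
#' Images are plain numeric matrices with integer gray values in [0, 255],
#' indexed \code{[row, col]} = \code{[y+1, x+1]} (0 = black, 255 = white).
#' PNG is the on-disk format; RGB(A) files are collapsed to luminance.
#'
#' @param path file path.
#' @return \code{readGrayImage}: a numeric matrix in [0, 255].
#' @export
readGrayImage <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    # luminance of RGB(A)
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  }
  round(px * 255)
}

#' @rdname readGrayImage
#' @param image numeric matrix with values in [0, 255].
#' @export
writeGrayImage <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(pmin(pmax(image, 0), 255) / 255, target = path)
  invisible(path)
}

#' Read and write label manifests
#'
#' A manifest is a CSV with header \code{path,label}: one image file per row
#' with its integer class label.
#'
#' @param path manifest file path.
#' @return \code{readManifest}: a data.frame with columns \code{path}
#'   (character) and \code{label} (integer).
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("path", "label") %in% names(df)))
  df$label <- as.integer(df$label)
  df
}

#' @rdname readManifest
#' @param manifest data.frame with columns \code{path} and \code{label}.
#' @export
writeManifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("path", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Serialize a segmented region
#'
#' Writes \code{<prefix>_patch.png} (grayscale patch, background white),
#' \code{<prefix>_mask.png} (0/255 mask) and \code{<prefix>_meta.json}
#' (bbox, centroid, contour, label, cell count).
#'
#' @param region a [CellRegion-class].
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
saveRegion <- function(region, prefix) {
  p1 <- paste0(prefix, "_patch.png")
  p2 <- paste0(prefix, "_mask.png")
  p3 <- paste0(prefix, "_meta.json")
  writeGrayImage(region@patch, p1)
  writeGrayImage(ifelse(region@mask, 255, 0), p2)
  meta <- list(
    bbox = region@bbox,
    centroid = region@centroid,
    contour = unname(apply(region@contour, 1, as.numeric, simplify = FALSE)),
    label = region@label,
    cell_count = region@cellCount
  )
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}

#' @rdname saveRegion
#' @export
loadRegion <- function(prefix) {
  patch <- readGrayImage(paste0(prefix, "_patch.png"))
  mask <- readGrayImage(paste0(prefix, "_mask.png")) >= 128
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  new("CellRegion",
      patch = patch, mask = mask,
      contour = matrix(unlist(meta$contour), ncol = 2, byrow = TRUE,
                       dimnames = list(NULL, c("x", "y"))),
      centroid = as.numeric(meta$centroid),
      bbox = as.numeric(meta$bbox),
      label = as.integer(meta$label),
      cellCount = as.integer(meta$cell_count))
}
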