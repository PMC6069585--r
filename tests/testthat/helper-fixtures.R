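# Shared fixture builders; everything is generated in code at test time.

# a circular-disk region of radius r on a flat-gray patch
diskRegion <- function(r, gray = 100, pad = 3) {
  side <- 2 * (r + pad) + 1
  c0 <- r + pad
  x <- matrix(rep(0:(side - 1), each = side), nrow = side) - c0
  y <- matrix(rep(0:(side - 1), times = side), nrow = side) - c0
  mask <- x^2 + y^2 <= r^2
  img <- matrix(255, side, side)
  img[mask] <- gray
  regionFromMask(mask, img)
}

# a region from an arbitrary full-frame mask with given in-mask gray values
grayRegion <- function(mask, gray) {
  img <- matrix(255, nrow(mask), ncol(mask))
  img[mask] <- gray
  regionFromMask(mask, img)
}

# a noise-free elliptical fixture nucleus plus its truth mask
cleanNucleus <- function(a = 20, b = 20, centerGray = 80,
                         backgroundGray = 200, orientation = 0) {
  generateNucleus(nucleusSpec(c(a, b), orientation = orientation,
                              centerGray = centerGray,
                              backgroundGray = backgroundGray,
                              noiseSd = 0))
}
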