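#' Mean pairwise distance of a sample set
#'
#' The selection threshold \eqn{T}: the mean Euclidean distance over all
#' unordered pairs of the initial sample set \eqn{P}.
#'
#' @param P numeric matrix, one feature vector per row.
#' @return nonnegative scalar \eqn{T}.
#' @export
meanPairwiseDistance <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) < 2L) stop("insufficient-samples error: |P| < 2")
  mean(stats::dist(P))
}

#' Greedy representative sample selection
#'
#' Scans \eqn{P} in input order: the first sample is always kept; each
#' subsequent sample is kept iff its Euclidean distance to every
#' already-kept sample is strictly greater than the threshold \eqn{T}.
#' This prevents similar images from being used more than once before
#' synthesis: after selection all pairwise distances within the kept set
#' \eqn{Q} exceed \eqn{T}.
#'
#' @param P numeric matrix, one feature vector per row.
#' @param T distance threshold; default the mean pairwise distance of
#'   \eqn{P} (always recomputed from \eqn{P}, not from \eqn{Q}).
#' @return integer vector of kept row indices, with attribute
#'   \code{threshold} carrying the \eqn{T} used.
#' @export
selectRepresentative <- function(P, T = NULL) {
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 1L) stop("insufficient-samples error: |P| < 1")
  if (is.null(T)) T <- if (n >= 2L) meanPairwiseDistance(P) else 0
  keep <- 1L
  for (i in seq_len(n)[-1]) {
    d <- sqrt(colSums((t(P[keep, , drop = FALSE]) - P[i, ])^2))
    if (all(d > T)) keep <- c(keep, i)
  }
  attr(keep, "threshold") <- T
  keep
}

#' Representative selection on a feature table
#'
#' Convenience wrapper for image manifests: z-score standardizes the
#' feature columns (so mixed-unit features contribute comparably to the
#' Euclidean distance), computes the mean-pairwise-distance threshold on
#' the standardized table, and runs the greedy selection.
#'
#' @param features numeric matrix or data.frame of per-image feature
#'   vectors (rows = images).
#' @return list: \code{selected} (kept row indices), \code{threshold},
#'   \code{nInitial}, \code{nSelected}.
#' @export
selectImages <- function(features) {
  X <- as.matrix(features)
  if (nrow(X) >= 2L) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0 | !is.finite(sds)] <- 1
    X <- scale(X, center = colMeans(X), scale = sds)
  }
  keep <- selectRepresentative(X)
  list(selected = as.integer(keep),
       threshold = attr(keep, "threshold"),
       nInitial = nrow(X), nSelected = length(keep))
}
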