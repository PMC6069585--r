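#' Multiclass confusion matrix
#'
#' \code{n[i, j]} counts samples of actual class i predicted as class j.
#'
#' @param actual,predicted integer label vectors of equal length with
#'   values in \code{1..k}.
#' @param k number of classes.
#' @return k x k integer matrix with dimnames \code{C1..Ck}.
#' @export
confusionMatrix <- function(actual, predicted, k) {
  stopifnot(length(actual) == length(predicted))
  actual <- as.integer(actual); predicted <- as.integer(predicted)
  if (length(actual) &&
      (min(actual, predicted) < 1L || max(actual, predicted) > k))
    stop("label out of range 1..k")
  cm <- matrix(0L, k, k,
               dimnames = list(actual = paste0("C", 1:k),
                               predicted = paste0("C", 1:k)))
  for (n in seq_along(actual))
    cm[actual[n], predicted[n]] <- cm[actual[n], predicted[n]] + 1L
  cm
}

#' Overall accuracy
#'
#' Trace of the confusion matrix over the total count.
#'
#' @param cm a confusion matrix.
#' @return accuracy in [0, 1].
#' @export
cmAccuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("undefined: empty confusion matrix")
  sum(diag(cm)) / total
}

#' Per-class recall
#'
#' \eqn{Recall_i = n_{ii} / \sum_j n_{ij}}.  A class with no actual
#' samples (zero row) has undefined recall and raises an error - distinct
#' from a recall of 0, which means the class was present but never
#' predicted correctly.
#'
#' @param cm a confusion matrix.
#' @param i class index; \code{NULL} returns the vector of all recalls.
#' @return recall value(s) in [0, 1].
#' @export
cmRecall <- function(cm, i = NULL) {
  rows <- rowSums(cm)
  if (is.null(i)) {
    if (any(rows == 0)) stop("undefined-recall error: class with zero actual samples")
    return(diag(cm) / rows)
  }
  if (rows[i] == 0) stop("undefined-recall error: class with zero actual samples")
  unname(cm[i, i] / rows[i])
}

#' Geometric mean of per-class recalls
#'
#' \eqn{G = (\prod_i recall_i)^{1/k}}.  Unlike accuracy, a single
#' neglected class drives the G-mean to 0, which is what makes it the
#' metric of choice for imbalanced problems.
#'
#' @param cm a confusion matrix; every class must have at least one actual
#'   sample.
#' @return G-mean in [0, 1].
#' @export
gMean <- function(cm) {
  r <- cmRecall(cm)
  prod(r)^(1 / length(r))
}

#' Imbalance ratio of a training set
#'
#' Largest class count divided by the smallest.
#'
#' @param classCounts positive integer vector of per-class training
#'   counts.
#' @param digits rounding applied for table display (1 decimal, half-up,
#'   as conventionally reported); use \code{NULL} for the exact ratio.
#' @return ratio >= 1.
#' @export
imbalanceRatio <- function(classCounts, digits = 1) {
  if (any(classCounts <= 0)) stop("all class counts must be positive")
  r <- max(classCounts) / min(classCounts)
  if (is.null(digits)) r else floor(r * 10^digits + 0.5) / 10^digits
}

#' Full metrics report
#'
#' @param cm a confusion matrix.
#' @param trainCounts optional per-class training counts for the imbalance
#'   ratio.
#' @return list: \code{accuracy}, \code{recall} (vector), \code{gMean},
#'   and \code{imbalanceRatio} when counts are given.
#' @export
metricsReport <- function(cm, trainCounts = NULL) {
  out <- list(accuracy = cmAccuracy(cm), recall = cmRecall(cm),
              gMean = gMean(cm))
  if (!is.null(trainCounts))
    out$imbalanceRatio <- imbalanceRatio(trainCounts)
  out
}
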