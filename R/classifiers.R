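#' Classifier adapter specification
#'
#' Thin wrappers over standard learners, used only to exercise the
#' synthesis method end to end.  Defaults follow the reference settings:
#' MLP with 100 hidden nodes and 200 iterations (seed 20), RBF-kernel SVM
#' in one-versus-one mode, per-class Gaussian mixture discriminant
#' analysis (seed 42), gradient boosting with 50 rounds at learning rate
#' 1.0, and a random forest with 60 trees of depth 3 and a 20-sample leaf
#' minimum.  \code{kind = "knn"} (1-nearest-neighbour) is a deterministic
#' reference useful in harness tests.
#'
#' @param kind one of \code{"mlp"}, \code{"svm"}, \code{"gmm"},
#'   \code{"boost"}, \code{"forest"}, \code{"knn"}.
#' @param ... overrides of the per-kind hyperparameters (\code{hidden},
#'   \code{iterations}, \code{learningRate}, \code{treeDepth},
#'   \code{leafMin}, \code{trees}, \code{seed}, \code{ncomp}).
#'   \code{ncomp} switches on PCA reduction of the feature table to that
#'   many components before training (off by default).
#' @return a list of class \code{ClassifierSpec}.
#' @export
classifierSpec <- function(kind, ...) {
  defaults <- switch(kind,
    mlp = list(hidden = 100L, iterations = 200L, seed = 20L,
               minError = 0.1),
    svm = list(kernel = "radial", seed = 1L),
    gmm = list(seed = 42L),
    boost = list(iterations = 50L, learningRate = 1.0, seed = 1L),
    forest = list(trees = 60L, treeDepth = 3L, leafMin = 20L, seed = 1L),
    knn = list(kNeighbors = 1L, seed = 1L),
    stop("unknown classifier kind: ", kind)
  )
  over <- list(...)
  defaults[names(over)] <- over
  structure(c(list(kind = kind, ncomp = over$ncomp), defaults),
            class = "ClassifierSpec")
}

# z-score scaling fit on train, applied to both tables; optional PCA
.prepFeatures <- function(spec, trainX, testX) {
  trainX <- as.matrix(trainX); testX <- as.matrix(testX)
  mu <- colMeans(trainX)
  sds <- apply(trainX, 2, stats::sd)
  sds[sds == 0 | !is.finite(sds)] <- 1
  trainX <- scale(trainX, mu, sds); testX <- scale(testX, mu, sds)
  if (!is.null(spec$ncomp)) {
    pc <- stats::prcomp(trainX, center = FALSE, scale. = FALSE)
    k <- min(spec$ncomp, ncol(pc$rotation))
    trainX <- trainX %*% pc$rotation[, 1:k, drop = FALSE]
    testX <- testX %*% pc$rotation[, 1:k, drop = FALSE]
  }
  list(train = trainX, test = testX)
}

#' Train a classifier and predict test labels
#'
#' Deterministic given the spec's seed.  Feature columns must match
#' between train and test; features are z-scored on the training table
#' before fitting.
#'
#' @param spec a [classifierSpec()].
#' @param trainX,testX feature matrices / data.frames with identical
#'   columns.
#' @param trainY integer training labels.
#' @return integer vector of predicted labels, one per test row.
#' @export
trainPredict <- function(spec, trainX, trainY, testX) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  if (!identical(colnames(as.matrix(trainX)), colnames(as.matrix(testX))))
    stop("feature columns differ between train and test")
  trainY <- as.integer(trainY)
  if (any(tabulate(trainY, nbins = max(trainY)) == 0) &&
      spec$kind %in% c("gmm"))
    stop("empty training class")
  d <- .prepFeatures(spec, trainX, testX)
  set.seed(spec$seed)
  pred <- switch(spec$kind,
    mlp = {
      y <- nnet::class.ind(factor(trainY))
      fit <- nnet::nnet(d$train, y, size = spec$hidden,
                        maxit = spec$iterations, softmax = TRUE,
                        MaxNWts = 100000, abstol = spec$minError,
                        trace = FALSE)
      cls <- as.integer(colnames(y)[max.col(stats::predict(fit, d$test))])
      cls
    },
    svm = {
      fit <- e1071::svm(d$train, factor(trainY), kernel = spec$kernel,
                        scale = FALSE)
      as.integer(as.character(stats::predict(fit, d$test)))
    },
    gmm = {
      # mclust resolves its model helpers unqualified; it must be attached
      if (!"mclust" %in% .packages())
        suppressMessages(attachNamespace("mclust"))
      fit <- mclust::MclustDA(d$train, factor(trainY), verbose = FALSE)
      as.integer(as.character(stats::predict(fit, d$test)$classification))
    },
    boost = {
      fit <- xgboost::xgboost(d$train, factor(trainY),
                              nrounds = spec$iterations,
                              learning_rate = spec$learningRate,
                              nthreads = 1, verbosity = 0,
                              seed = spec$seed)
      as.integer(as.character(
        stats::predict(fit, d$test, type = "class")))
    },
    forest = {
      fit <- randomForest::randomForest(
        d$train, factor(trainY), ntree = spec$trees,
        maxnodes = 2L^spec$treeDepth, nodesize = spec$leafMin)
      as.integer(as.character(stats::predict(fit, d$test)))
    },
    knn = {
      as.integer(as.character(
        class::knn(d$train, d$test, factor(trainY), k = spec$kNeighbors)))
    },
    stop("unknown classifier kind: ", spec$kind)
  )
  pred
}
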