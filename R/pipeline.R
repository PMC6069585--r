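#' The 13-condition imbalance schedule
#'
#' Per-class training counts for the standard sweep: majority classes stay
#' at 20000 x \code{scale} while minority classes grow through
#' 200, 500, 1000, 2000, 4000, 6000, 8000, 10000, 12000, 14000, 16000,
#' 18000, 20000 (x \code{scale}), so the imbalance ratio falls from 100
#' to 1 over 13 conditions.
#'
#' @param scale scaling factor applied to every count (default 1/100, the
#'   fixture scale at which the full sweep runs in minutes).
#' @param minorityClasses integer set of minority classes (default
#'   \code{c(3, 4, 5, 8)}; configurable).
#' @return list: \code{counts} (13 x 8 integer matrix),
#'   \code{imbalanceRatio} (length-13 vector, 1-decimal rounding).
#' @export
imbalanceSchedule <- function(scale = 0.01, minorityClasses = c(3, 4, 5, 8)) {
  minoritySteps <- c(200, 500, 1000, 2000, 4000, 6000, 8000, 10000,
                     12000, 14000, 16000, 18000, 20000)
  majority <- 20000
  counts <- matrix(round(majority * scale), nrow = 13, ncol = 8)
  for (i in 1:13) counts[i, minorityClasses] <- round(minoritySteps[i] * scale)
  if (any(counts < 1)) stop("scale too small: zero class count")
  list(counts = counts,
       imbalanceRatio = apply(counts, 1, imbalanceRatio))
}

#' Experiment plan for the imbalance sweep
#'
#' @inheritParams imbalanceSchedule
#' @param testPerClass held-out test images per class (equal across
#'   classes, generated from a disjoint seed stream).
#' @param classifiers list of [classifierSpec()]s to run per condition.
#' @param seed master seed; every random draw in the run derives from it.
#' @param noiseSd fixture noise level in gray units.
#' @param schedule optional explicit schedule (a list with a conditions x 8
#'   \code{counts} matrix and an \code{imbalanceRatio} vector) replacing
#'   the standard [imbalanceSchedule()]; useful for reduced smoke runs.
#' @return a list of class \code{ExperimentPlan}.
#' @export
experimentPlan <- function(scale = 0.01, minorityClasses = c(3, 4, 5, 8),
                           testPerClass = 25,
                           classifiers = list(classifierSpec("mlp")),
                           seed = 42, noiseSd = 6, schedule = NULL) {
  sched <- if (is.null(schedule)) imbalanceSchedule(scale, minorityClasses)
           else schedule
  structure(list(schedule = sched, minorityClasses = minorityClasses,
                 testPerClass = testPerClass, classifiers = classifiers,
                 seed = seed, noiseSd = noiseSd),
            class = "ExperimentPlan")
}

# selected donor indices per singleton class, honoring the
# representative-selection contract before synthesis
.donorPools <- function(dataset, classes = c(1L, 2L, 6L, 7L)) {
  pools <- list()
  for (cls in classes) {
    idx <- which(dataset$labels == cls)
    if (length(idx) == 0L) next
    if (length(idx) >= 3L) {
      ft <- featureTable(dataset$images[idx])
      sel <- selectImages(ft)
      idx <- idx[sel$selected]
    }
    pools[[as.character(cls)]] <- idx
  }
  pools
}

#' Augment a dataset to target per-class counts by synthesis
#'
#' Synthesizes images until each class reaches its target count.
#' Composite classes are built by the overlap-synthesis chain: class 3
#' from two representative epithelial singles (classes 1-2), class 4 from
#' a 2-cell image plus a single, class 5 from a 3-cell image plus a
#' single, class 8 from two centriole singles (class 7).  Source singles
#' are drawn (uniformly, with replacement, on the package generator) from
#' the representative subset chosen by the selection module; singleton
#' classes below target receive fresh renders.  Majority classes above
#' target are never touched.
#'
#' @param dataset a \code{FixtureDataset}.
#' @param targetCounts integer vector of length 8.
#' @param gen an [LCG-class] generator.
#' @param ranges fixture parameter ranges ([classSpecRanges()]).
#' @return the augmented \code{FixtureDataset} with an added
#'   \code{provenance} data.frame (class, d, Rmin, angle1, angle2, I0,
#'   overlapCount) describing every synthesized image, in synthesis
#'   order.
#' @export
balanceDataset <- function(dataset, targetCounts, gen,
                           ranges = classSpecRanges()) {
  stopifnot(length(targetCounts) == 8L)
  donors <- .donorPools(dataset)
  drawDonor <- function(classes) {
    idx <- unlist(donors[as.character(classes)])
    if (length(idx) == 0L) stop("impossible target: no source images")
    dataset$images[[idx[lcgInteger(gen, 1L, length(idx))]]]
  }
  byClass <- function(cls) which(dataset$labels == cls)
  prov <- list()
  recipes <- list("3" = list(base = c(1L, 2L), add = c(1L, 2L)),
                  "4" = list(base = 3L, add = c(1L, 2L)),
                  "5" = list(base = 4L, add = c(1L, 2L)),
                  "8" = list(base = 7L, add = 7L))
  for (cls in c(3L, 8L, 4L, 5L)) {          # bases before their users
    need <- targetCounts[cls] - length(byClass(cls))
    rec <- recipes[[as.character(cls)]]
    for (i in seq_len(max(need, 0L))) {
      if (all(rec$base %in% c(1L, 2L, 6L, 7L))) {
        base <- drawDonor(rec$base); baseCells <- 1L
      } else {
        idx <- byClass(rec$base)
        if (length(idx) == 0L) stop("impossible target: no source images")
        pick <- idx[lcgInteger(gen, 1L, length(idx))]
        base <- dataset$images[[pick]]
        baseCells <- dataset$cellCounts[pick]
      }
      add <- drawDonor(rec$add)
      syn <- synthesizeOverlap(base, add, gen,
                               cellsA = baseCells, cellsB = 1L)
      dataset$images <- c(dataset$images, list(syn$image))
      dataset$labels <- c(dataset$labels, cls)
      dataset$cellCounts <- c(dataset$cellCounts, syn$cellCount)
      dataset$manifest <- rbind(dataset$manifest,
                                data.frame(path = "", label = cls))
      prov[[length(prov) + 1L]] <- data.frame(
        class = cls, d = syn$meta$d, Rmin = syn$meta$Rmin,
        angle1 = syn$meta$angles[1], angle2 = syn$meta$angles[2],
        I0 = syn$meta$I0, overlapCount = syn$meta$overlapCount)
    }
  }
  # singleton minority classes (configurable minority sets): fresh renders
  for (cls in c(1L, 2L, 6L, 7L)) {
    need <- targetCounts[cls] - length(byClass(cls))
    for (i in seq_len(max(need, 0L))) {
      im <- generateClassImage(cls, ranges, gen)
      dataset$images <- c(dataset$images, list(im$image))
      dataset$labels <- c(dataset$labels, cls)
      dataset$cellCounts <- c(dataset$cellCounts, 1L)
      dataset$manifest <- rbind(dataset$manifest,
                                data.frame(path = "", label = cls))
    }
  }
  dataset$provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(class = integer(0), d = numeric(0), Rmin = numeric(0),
               angle1 = numeric(0), angle2 = numeric(0), I0 = numeric(0),
               overlapCount = integer(0))
  dataset
}

#' Run the imbalance sweep
#'
#' Generates the condition-1 (most imbalanced) training fixtures, augments
#' them with synthesized overlap images up to the most balanced condition
#' (so training sets are nested and "synthesized data are added
#' gradually"), extracts the 28-feature table once, generates an
#' independent equal-sized test set from a disjoint seed stream, and for
#' every condition and classifier computes accuracy and G-mean on the
#' held-out set.
#'
#' @param plan an [experimentPlan()].
#' @return list of class \code{ExperimentResult}: \code{results}
#'   (data.frame with condition, imbalance_ratio, classifier, accuracy,
#'   g_mean), \code{provenance} (synthesis log), \code{plan}.
#' @export
runExperiment <- function(plan) {
  stopifnot(inherits(plan, "ExperimentPlan"))
  gen <- LCG(plan$seed)
  testGen <- lcgSpawn(gen, stream = 7L)
  ranges <- classSpecRanges(noiseSd = plan$noiseSd)
  counts <- plan$schedule$counts
  base <- generateDataset(counts[1, ], gen, ranges)
  maxCounts <- apply(counts, 2, max)
  pool <- balanceDataset(base, maxCounts, gen, ranges)
  poolFeat <- featureTable(pool)
  testSet <- generateDataset(rep(plan$testPerClass, 8), testGen, ranges)
  testFeat <- featureTable(testSet)
  fcols <- featureNames()
  classIdx <- lapply(1:8, function(cls) which(pool$labels == cls))
  rows <- list()
  for (cond in seq_len(nrow(counts))) {
    take <- unlist(lapply(1:8, function(cls)
      classIdx[[cls]][seq_len(counts[cond, cls])]))
    trX <- poolFeat[take, fcols]; trY <- poolFeat$label[take]
    for (spec in plan$classifiers) {
      pred <- trainPredict(spec, trX, trY, testFeat[, fcols])
      cm <- confusionMatrix(testFeat$label, pred, 8)
      rows[[length(rows) + 1L]] <- data.frame(
        condition = cond,
        imbalance_ratio = plan$schedule$imbalanceRatio[cond],
        classifier = spec$kind,
        accuracy = cmAccuracy(cm),
        g_mean = gMean(cm))
    }
  }
  structure(list(results = do.call(rbind, rows),
                 provenance = pool$provenance, plan = plan),
            class = "ExperimentResult")
}
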