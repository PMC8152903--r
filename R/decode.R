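#' Create a decoding configuration
#'
#' @param ... named slot overrides of [DecodeConfig-class] defaults, e.g.
#'   \code{nIterations = 2}.
#' @return A validated [DecodeConfig-class].
#' @export
DecodeConfig <- function(...) {
  args <- list(...)
  proto <- new("DecodeConfig")
  for (nm in names(args)) {
    cls <- class(slot(proto, nm))
    slot(proto, nm) <- if (cls == "integer") as.integer(args[[nm]]) else as.numeric(args[[nm]])
  }
  validObject(proto)
  proto
}

#' @describeIn DecodeConfig chance level, \code{1 / nClasses}
#' @param x a DecodeConfig
#' @export
setMethod("chanceLevel", "DecodeConfig", function(x) 1 / x@nClasses)

setMethod("show", "DecodeConfig", function(object) {
  cat(sprintf(paste0("DecodeConfig: %d classes (chance %.3g), %d folds x %d ",
                     "iterations,\n  lowpass %s Hz, smooth %d points, ",
                     "window %g ms, SVM cost %g\n"),
              object@nClasses, 1 / object@nClasses, object@nFolds,
              object@nIterations,
              ifelse(is.na(object@lowpassHz), "off", format(object@lowpassHz)),
              object@smoothPoints, object@windowMs, object@cost))
})

#' Balanced fold partitioning
#'
#' Randomly partitions each class's trials into k equally sized groups,
#' discarding \code{n mod k} random trials per class; with 160 trials per
#' class and k = 3 this yields 3 groups of 53 with one trial dropped.
#'
#' @param classLabels integer class label per trial.
#' @param k number of folds.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @return A [FoldAssignment-class].
#' @export
partitionBalanced <- function(classLabels, k, seed) {
  classes <- sort(unique(classLabels))
  counts <- table(factor(classLabels, levels = classes))
  short <- classes[counts < k]
  if (length(short))
    stop("class ", paste(short, collapse = ", "), " has fewer trials than folds")
  withSeed(seed, {
    groups <- vector("list", length(classes))
    dropped <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      idx <- which(classLabels == classes[i])
      idx <- idx[sample.int(length(idx))]
      gsize <- length(idx) %/% k
      keep <- idx[seq_len(gsize * k)]
      dropped[[i]] <- idx[-seq_len(gsize * k)]
      groups[[i]] <- split(keep, rep(seq_len(k), each = gsize))
    }
    names(groups) <- names(dropped) <- as.character(classes)
    new("FoldAssignment", groups = groups, dropped = dropped,
        seed = as.integer(seed))
  })
}

# Group-averaged scalp vectors for all time points at once.
# Returns array [k * nClasses, channels, times]; row (g, c) = g + (c-1)*k,
# plus the row bookkeeping as attributes.
groupMeansAll <- function(epochs, assignment) {
  d <- dim(epochs@data)
  k <- length(assignment@groups[[1]])
  nc <- length(assignment@groups)
  rowGroup <- integer(d[1]) # 0 = dropped
  for (c in seq_len(nc)) for (g in seq_len(k)) {
    rowGroup[assignment@groups[[c]][[g]]] <- g + (c - 1L) * k
  }
  keep <- rowGroup > 0L
  X <- matrix(epochs@data, d[1], d[2] * d[3])
  sums <- rowsum(X[keep, , drop = FALSE], rowGroup[keep], reorder = TRUE)
  sizes <- tabulate(rowGroup[keep], k * nc)
  gm <- array(sums / sizes, c(k * nc, d[2], d[3]))
  attr(gm, "group") <- rep(seq_len(k), nc)
  attr(gm, "class_") <- rep(seq_len(nc), each = k)
  gm
}

#' Group-averaged scalp vectors at one time point
#'
#' Arithmetic mean of each fold group's trials per class at time index
#' \code{t}; with defaults the result is 3 groups x 4 classes x 59
#' channels.
#'
#' @param epochs an [EpochSet-class].
#' @param assignment a [FoldAssignment-class].
#' @param t 1-based time index.
#' @return Numeric array, groups x classes x channels.
#' @export
averageByGroup <- function(epochs, assignment, t) {
  gm <- groupMeansAll(epochs, assignment)
  k <- length(assignment@groups[[1]])
  nc <- length(assignment@groups)
  out <- array(0, c(k, nc, dim(gm)[2]))
  for (c in seq_len(nc)) out[, c, ] <- gm[(c - 1L) * k + seq_len(k), , t]
  out
}

#' ECOC one-vs-rest SVM fit and prediction
#'
#' Trains one linear soft-margin SVM per class (one-vs-rest coding) on the
#' training vectors, features standardized by the training rows' means and
#' sds, and predicts each test vector as the class minimizing the average
#' binary hinge loss over the coding matrix; exact ties go to the lowest
#' class code. Deterministic given its inputs.
#'
#' @param train numeric matrix, training rows x channels.
#' @param classes integer class per training row (1..nClasses).
#' @param test numeric matrix, test rows x channels.
#' @param nClasses number of classes (default: max of \code{classes}).
#' @param cost SVM regularization constant.
#' @param standardize standardize features by training-fold statistics.
#' @return Integer predicted class per test row.
#' @export
fitPredictEcoc <- function(train, classes, test, nClasses = max(classes),
                           cost = 1, standardize = TRUE) {
  if (length(unique(classes)) < 2L) stop("need at least 2 classes in training rows")
  train <- as.matrix(train); test <- as.matrix(test)
  M <- array(rbind(train, test), c(nrow(train) + nrow(test), ncol(train), 1L))
  .ecocSeriesCpp(as.numeric(M), dim(M), seq_len(nrow(train)),
                 as.integer(classes), nrow(train) + seq_len(nrow(test)),
                 as.integer(nClasses), cost, standardize)[, 1L]
}

#' Time-resolved decoding with averaged-fold cross-validation
#'
#' For each of \code{nIterations} random fold assignments: trials of each
#' class are partitioned into \code{nFolds} groups and averaged within
#' group; classifiers train on the averaged vectors of k-1 groups and
#' predict the held-out group's averaged vectors, independently at every
#' time point, with each group serving as test set once. Accuracy per time
#' point is the mean over \code{nClasses x nFolds x nIterations} attempts
#' (120 with defaults) and is smoothed with the configured moving average;
#' every attempt's prediction is retained in a [PredictionStore-class].
#'
#' @param epochs an [EpochSet-class] (already preprocessed).
#' @param classLabels integer class per trial, e.g. from
#'   [collapseDimension()].
#' @param config a [DecodeConfig-class].
#' @param seed master seed for the iteration fold assignments.
#' @return List with elements \code{series} (smoothed
#'   [AccuracySeries-class]) and \code{store} ([PredictionStore-class]).
#' @export
decodeTimecourse <- function(epochs, classLabels, config = DecodeConfig(),
                             seed = 1L) {
  k <- config@nFolds
  nc <- config@nClasses
  nT <- nTimes(epochs)
  iterSeeds <- deriveSeeds(seed, config@nIterations)
  nAttPerIter <- nc * k
  pred <- matrix(0L, nAttPerIter * config@nIterations, nT)
  trueCls <- integer(nrow(pred))
  iterIdx <- integer(nrow(pred))
  foldIdx <- integer(nrow(pred))
  r <- 0L
  for (it in seq_len(config@nIterations)) {
    fa <- partitionBalanced(classLabels, k, iterSeeds[it])
    gm <- groupMeansAll(epochs, fa)
    grp <- attr(gm, "group")
    cls <- attr(gm, "class_")
    dims <- dim(gm)
    Mvec <- as.numeric(gm)
    for (f in seq_len(k)) {
      trainIdx <- which(grp != f)
      testIdx <- which(grp == f)
      p <- .ecocSeriesCpp(Mvec, dims, trainIdx, cls[trainIdx], testIdx,
                          nc, config@cost, TRUE)
      rows <- r + seq_along(testIdx)
      pred[rows, ] <- p
      trueCls[rows] <- cls[testIdx]
      iterIdx[rows] <- it
      foldIdx[rows] <- f
      r <- r + length(testIdx)
    }
  }
  times <- epochTimes(epochs)
  store <- new("PredictionStore", predicted = pred, trueClass = trueCls,
               times = times, iteration = iterIdx, fold = foldIdx)
  acc <- colMeans(pred == trueCls)
  series <- new("AccuracySeries",
                values = runningMean(acc, config@smoothPoints),
                times = times, nAttempts = nrow(pred))
  list(series = series, store = store)
}

#' Accuracy recomputed from a prediction store
#'
#' @param store a [PredictionStore-class].
#' @param smoothPoints optional odd width; 0 or 1 returns the raw series.
#' @return An [AccuracySeries-class].
#' @export
accuracyFromStore <- function(store, smoothPoints = 0L) {
  acc <- colMeans(store@predicted == store@trueClass)
  if (smoothPoints > 1L) acc <- runningMean(acc, as.integer(smoothPoints))
  new("AccuracySeries", values = acc, times = store@times,
      nAttempts = nrow(store@predicted))
}

#' Temporal generalization (cross-time) decoding
#'
#' Averages the epoch into non-overlapping \code{windowMs} windows and, for
#' every ordered (train window, test window) pair, trains on the averaged
#' fold vectors of the train window and tests on the held-out vectors of
#' the test window, under exactly the fold/iteration scheme of
#' [decodeTimecourse()]. The matrix diagonal equals a windowed
#' [decodeTimecourse()] run with the same seed (before smoothing).
#'
#' @inheritParams decodeTimecourse
#' @return A [GenMatrix-class] (rows = train window, cols = test window).
#' @export
decodeCrosstime <- function(epochs, classLabels, config = DecodeConfig(),
                            seed = 1L) {
  wepochs <- windowAverage(epochs, config@windowMs)
  k <- config@nFolds
  nc <- config@nClasses
  nW <- nTimes(wepochs)
  iterSeeds <- deriveSeeds(seed, config@nIterations)
  correct <- matrix(0, nW, nW)
  total <- 0L
  for (it in seq_len(config@nIterations)) {
    fa <- partitionBalanced(classLabels, k, iterSeeds[it])
    gm <- groupMeansAll(wepochs, fa)
    grp <- attr(gm, "group")
    cls <- attr(gm, "class_")
    dims <- dim(gm)
    Mvec <- as.numeric(gm)
    for (f in seq_len(k)) {
      trainIdx <- which(grp != f)
      testIdx <- which(grp == f)
      p <- .ecocCrossCpp(Mvec, dims, trainIdx, cls[trainIdx], testIdx,
                         nc, config@cost, TRUE)
      hit <- p == cls[testIdx] # recycles over [row, testTime, trainTime]
      dim(hit) <- dim(p)
      correct <- correct + t(colSums(hit)) # -> [train, test]
      total <- total + length(testIdx)
    }
  }
  new("GenMatrix", accuracy = correct / total,
      windowTimes = epochTimes(wepochs))
}

#' Cross-dimension decoding
#'
#' Decodes the target dimension while training and testing on disjoint
#' levels of the other (control) dimension: the classifier trains on the
#' class-by-level averages of 3 control levels and is tested on the
#' held-out level's class averages, rotating over all 4 levels. No random
#' subsampling iterations are applied, because train/test membership is
#' fully determined by the control dimension. Accuracy per time point is
#' averaged over 4 rotations x nClasses attempts and smoothed.
#'
#' @param epochs an [EpochSet-class].
#' @param targetLabels integer class per trial for the decoded dimension.
#' @param controlLabels integer level per trial of the other dimension.
#' @param config a [DecodeConfig-class].
#' @return List with \code{series} (smoothed [AccuracySeries-class]) and
#'   \code{store} ([PredictionStore-class]; fold = held-out control level).
#' @export
decodeCrossdim <- function(epochs, targetLabels, controlLabels,
                           config = DecodeConfig()) {
  nc <- config@nClasses
  levs <- sort(unique(controlLabels))
  cellCounts <- table(factor(targetLabels, levels = seq_len(nc)),
                      factor(controlLabels, levels = levs))
  if (any(cellCounts == 0L))
    stop("empty target-class x control-level cell; cross-dimension decoding needs all cells")
  d <- dim(epochs@data)
  cellOf <- match(targetLabels, seq_len(nc)) +
    (match(controlLabels, levs) - 1L) * nc # row (c, l) = c + (l-1)*nc
  X <- matrix(epochs@data, d[1], d[2] * d[3])
  sums <- rowsum(X, cellOf, reorder = TRUE)
  sizes <- tabulate(cellOf, nc * length(levs))
  gm <- array(sums / sizes, c(nc * length(levs), d[2], d[3]))
  cls <- rep(seq_len(nc), length(levs))
  lev <- rep(seq_along(levs), each = nc)
  dims <- dim(gm)
  Mvec <- as.numeric(gm)
  nT <- d[3]
  pred <- matrix(0L, nc * length(levs), nT)
  trueCls <- integer(nrow(pred))
  foldIdx <- integer(nrow(pred))
  r <- 0L
  for (f in seq_along(levs)) {
    trainIdx <- which(lev != f)
    testIdx <- which(lev == f)
    p <- .ecocSeriesCpp(Mvec, dims, trainIdx, cls[trainIdx], testIdx,
                        nc, config@cost, TRUE)
    rows <- r + seq_along(testIdx)
    pred[rows, ] <- p
    trueCls[rows] <- cls[testIdx]
    foldIdx[rows] <- f
    r <- r + length(testIdx)
  }
  times <- epochTimes(epochs)
  store <- new("PredictionStore", predicted = pred, trueClass = trueCls,
               times = times, iteration = rep(1L, nrow(pred)),
               fold = foldIdx)
  acc <- colMeans(pred == trueCls)
  series <- new("AccuracySeries",
                values = runningMean(acc, config@smoothPoints),
                times = times, nAttempts = nrow(pred))
  list(series = series, store = store)
}

#' Period-wise confusion matrices
#'
#' Pools (true, predicted) label pairs over all attempts and all time
#' points within each period and row-normalizes, giving the probability
#' that a given true class was classified as each class. Default periods
#' are perception (0-500 ms) and working-memory maintenance (500-1500 ms).
#'
#' @param store a [PredictionStore-class].
#' @param periods named list of half-open ms intervals.
#' @param nClasses number of classes.
#' @return Named list of row-stochastic nClasses x nClasses matrices; each
#'   carries its period as attribute \code{"period"}.
#' @export
confusionByPeriod <- function(store,
                              periods = list(perception = c(0, 500),
                                             maintenance = c(500, 1500)),
                              nClasses = 4L) {
  lapply(periods, function(w) {
    sel <- store@times >= w[1] & store@times < w[2]
    if (!any(sel)) stop("period [", w[1], ", ", w[2], ") contains no time points")
    p <- as.vector(store@predicted[, sel, drop = FALSE])
    tr <- rep(store@trueClass, sum(sel))
    cm <- table(factor(tr, levels = seq_len(nClasses)),
                factor(p, levels = seq_len(nClasses)))
    cm <- unclass(cm / pmax(rowSums(cm), 1L))
    dimnames(cm) <- list(true = seq_len(nClasses), predicted = seq_len(nClasses))
    attr(cm, "period") <- w
    cm
  })
}

#' @describeIn AccuracySeries accuracy values
#' @param x an AccuracySeries
#' @param ... unused
#' @export
setMethod("accuracy", "AccuracySeries", function(x, ...) x@values)

#' @describeIn AccuracySeries ms time axis
#' @export
setMethod("seriesTimes", "AccuracySeries", function(x) x@times)

#' @describeIn AccuracySeries decoding attempts per time point
#' @export
setMethod("nAttempts", "AccuracySeries", function(x) x@nAttempts)

setMethod("show", "AccuracySeries", function(object) {
  cat(sprintf("AccuracySeries: %d time points [%g, %g] ms, %d attempts/point, mean %.3f\n",
              length(object@values), min(object@times), max(object@times),
              object@nAttempts, mean(object@values)))
})

setMethod("show", "PredictionStore", function(object) {
  cat(sprintf("PredictionStore: %d attempts x %d time points (%d iterations)\n",
              nrow(object@predicted), ncol(object@predicted),
              max(object@iteration)))
})

setMethod("show", "GenMatrix", function(object) {
  cat(sprintf("GenMatrix: %d x %d windows, accuracy range [%.3f, %.3f]\n",
              nrow(object@accuracy), ncol(object@accuracy),
              min(object@accuracy), max(object@accuracy)))
})

#' @describeIn GenMatrix accuracy matrix (train x test windows)
#' @param x a GenMatrix
#' @param ... unused
#' @export
setMethod("accuracy", "GenMatrix", function(x, ...) x@accuracy)
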