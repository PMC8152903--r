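#' Point-wise one-sample t statistics
#'
#' Standard one-sample t per column of a participants x time accuracy
#' matrix against a constant (chance). Zero-variance columns yield signed
#' infinity (sign of mean - mu; 0 when the mean equals mu exactly) rather
#' than an error, so that degenerate columns remain comparable.
#'
#' @param acc numeric matrix, participants x time points.
#' @param mu null value, e.g. chance = 1/4.
#' @return Numeric t statistic per time point; df is \code{nrow(acc) - 1}.
#' @export
pointwiseT <- function(acc, mu = 0.25) {
  n <- nrow(acc)
  if (n < 2L) stop("need at least 2 participants")
  m <- colMeans(acc) - mu
  s <- sqrt(colSums(sweep(acc, 2, colMeans(acc))^2) / (n - 1))
  t <- m / (s / sqrt(n))
  zero <- s == 0
  t[zero] <- sign(m[zero]) * Inf
  t[zero & m == 0] <- 0
  t
}

# paired two-condition t per time point (reduces to one-sample on A - B)
pairedT <- function(accA, accB) pointwiseT(accA - accB, mu = 0)

#' Find clusters of contiguously significant time points
#'
#' Thresholds the t series at the point-wise alpha for the given tail and
#' returns maximal runs of contiguous significant points with their summed
#' t mass. Single-point clusters are permitted. For two-tailed tests,
#' positive and negative exceedances form separate clusters and the mass
#' keeps its sign.
#'
#' @param tSeries numeric t statistic per time point.
#' @param df degrees of freedom.
#' @param tail \code{"one"} (greater) or \code{"two"}.
#' @param pointAlpha per-point significance level (default 0.05).
#' @param times optional ms axis for reporting cluster extents.
#' @return A [ClusterSet-class] without p-values.
#' @export
formClusters <- function(tSeries, df, tail = c("one", "two"),
                         pointAlpha = 0.05, times = seq_along(tSeries)) {
  tail <- match.arg(tail)
  thr <- if (tail == "one") stats::qt(1 - pointAlpha, df)
         else stats::qt(1 - pointAlpha / 2, df)
  runsOf <- function(sig) {
    r <- rle(sig)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  segs <- runsOf(tSeries > thr)
  rows <- if (nrow(segs)) data.frame(start = segs[, 1], end = segs[, 2]) else
    data.frame(start = integer(0), end = integer(0))
  if (tail == "two") {
    nsegs <- runsOf(tSeries < -thr)
    if (nrow(nsegs))
      rows <- rbind(rows, data.frame(start = nsegs[, 1], end = nsegs[, 2]))
  }
  if (nrow(rows)) {
    rows <- rows[order(rows$start), , drop = FALSE]
    rows$startTime <- times[rows$start]
    rows$endTime <- times[rows$end]
    rows$mass <- vapply(seq_len(nrow(rows)), function(i)
      sum(tSeries[rows$start[i]:rows$end[i]]), numeric(1))
  } else {
    rows$startTime <- numeric(0); rows$endTime <- numeric(0)
    rows$mass <- numeric(0)
  }
  rownames(rows) <- NULL
  new("ClusterSet", clusters = rows, tail = tail, pointAlpha = pointAlpha,
      clusterAlpha = 0.05, df = df)
}

#' @describeIn ClusterSet cluster table
#' @param x a ClusterSet
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)

setMethod("show", "ClusterSet", function(object) {
  cl <- object@clusters
  cat(sprintf("ClusterSet (%s-tailed, point alpha %g): %d cluster(s)\n",
              object@tail, object@pointAlpha, nrow(cl)))
  if (nrow(cl)) {
    for (i in seq_len(nrow(cl))) {
      p <- if (!is.null(cl$p)) sprintf(", p = %.3g", cl$p[i]) else ""
      cat(sprintf("  [%g, %g] ms, mass %.2f%s\n",
                  cl$startTime[i], cl$endTime[i], cl$mass[i], p))
    }
  }
})


# Accuracy series (participants x time) recomputed from stores under one
# class-code relabeling per participant, smoothed like the observed series.
relabeledAccuracy <- function(stores, perms, smoothPoints) {
  t(vapply(seq_along(stores), function(s) {
    st <- stores[[s]]
    runningMean(colMeans(st@predicted == perms[[s]][st@trueClass]),
                as.integer(smoothPoints))
  }, numeric(ncol(stores[[1]]@predicted))))
}

#' Permutation null for decoding vs chance
#'
#' Builds the null distribution of the largest cluster t mass by relabeling
#' the stored test predictions: per permutation and participant, one
#' uniformly drawn permutation of the class codes is applied to the true
#' labels and used identically at every time point (respecting temporal
#' autocorrelation), accuracy is recomputed from the store without
#' retraining, smoothed with the same moving average as the observed
#' series, and clusters are formed with the same point-wise threshold; the
#' largest cluster mass (0 when no cluster) is recorded.
#'
#' @param stores list of [PredictionStore-class], one per participant, all
#'   on the same time axis.
#' @param nPerm number of permutations (default 1000, giving p resolution
#'   1e-3).
#' @param seed integer seed.
#' @param mu chance level.
#' @param smoothPoints accuracy smoothing width (same as the observed
#'   pipeline).
#' @param pointAlpha per-point threshold.
#' @param tail tail of the point-wise tests (vs chance: \code{"one"}).
#' @param nClasses number of class codes being permuted.
#' @param timeMask optional logical mask restricting the analyzed time
#'   points (the vs-chance analysis is restricted to post-onset points).
#' @return Numeric vector of \code{nPerm} max cluster masses.
#' @export
nullVsChance <- function(stores, nPerm = 1000L, seed = 1L, mu = 0.25,
                         smoothPoints = 5L, pointAlpha = 0.05,
                         tail = "one", nClasses = 4L, timeMask = NULL) {
  if (nPerm < 1L) stop("nPerm must be >= 1")
  nS <- length(stores)
  df <- nS - 1
  perms <- allPermutations(as.integer(nClasses))
  drawIdx <- withSeed(seed,
    matrix(sample.int(nrow(perms), nPerm * nS, replace = TRUE), nPerm, nS))
  vapply(seq_len(nPerm), function(p) {
    acc <- relabeledAccuracy(stores,
      lapply(seq_len(nS), function(s) perms[drawIdx[p, s], ]), smoothPoints)
    if (!is.null(timeMask)) acc <- acc[, timeMask, drop = FALSE]
    cs <- formClusters(pointwiseT(acc, mu), df, tail, pointAlpha)
    m <- cs@clusters$mass
    if (tail == "two") m <- abs(m)
    if (length(m)) max(m) else 0
  }, numeric(1))
}

#' Permutation null for a paired condition difference
#'
#' Null distribution of the largest absolute cluster t mass under random
#' swapping of the two conditions' (already smoothed) accuracy series
#' within participants: per permutation each participant's A/B series are
#' exchanged with probability 1/2, the paired two-tailed t series is
#' computed, clusters are formed as in [formClusters()], and the largest
#' |mass| (0 when no cluster) is recorded.
#'
#' @param accA,accB numeric matrices, participants x time, same shape.
#' @param nPerm number of permutations.
#' @param seed integer seed.
#' @param pointAlpha per-point threshold.
#' @return Numeric vector of \code{nPerm} max |cluster mass| values.
#' @export
nullConditionSwap <- function(accA, accB, nPerm = 1000L, seed = 1L,
                              pointAlpha = 0.05) {
  if (!all(dim(accA) == dim(accB))) stop("accA and accB must have equal shapes")
  nS <- nrow(accA)
  df <- nS - 1
  D <- accA - accB
  flips <- withSeed(seed,
    matrix(sample(c(1, -1), nPerm * nS, replace = TRUE), nPerm, nS))
  vapply(seq_len(nPerm), function(p) {
    cs <- formClusters(pointwiseT(D * flips[p, ], mu = 0), df, "two", pointAlpha)
    m <- abs(cs@clusters$mass)
    if (length(m)) max(m) else 0
  }, numeric(1))
}

#' Assign permutation p-values to clusters
#'
#' p = (number of null masses >= observed mass) / nPerm, floored at
#' 1 / nPerm (reported as "< 1/nPerm" when floored); for two-tailed cluster
#' sets the comparison uses |mass| on both sides. A cluster is declared
#' significant when its mass exceeds the 1 - clusterAlpha quantile of the
#' null.
#'
#' @param clusterSet a [ClusterSet-class] from [formClusters()].
#' @param null numeric null distribution of max cluster masses.
#' @param clusterAlpha family-wise alpha (default 0.05).
#' @return The [ClusterSet-class] with columns \code{p} and
#'   \code{significant} added.
#' @export
clusterPvalues <- function(clusterSet, null, clusterAlpha = 0.05) {
  if (!length(null)) stop("null distribution is empty")
  nPerm <- length(null)
  cl <- clusterSet@clusters
  obs <- cl$mass
  if (clusterSet@tail == "two") obs <- abs(obs)
  crit <- stats::quantile(null, 1 - clusterAlpha, type = 1, names = FALSE)
  cl$p <- vapply(obs, function(m) max(sum(null >= m) / nPerm, 1 / nPerm), numeric(1))
  cl$significant <- obs > crit
  out <- clusterSet
  out@clusters <- cl
  out@clusterAlpha <- clusterAlpha
  out
}

#' Cluster-based permutation test of decoding vs chance
#'
#' Convenience wrapper: smooth-recomputed observed accuracy, post-onset
#' point-wise one-tailed t tests, cluster formation, relabeling null, and
#' cluster p-values in one call.
#'
#' @param stores list of per-participant [PredictionStore-class].
#' @param mu chance level.
#' @param nPerm permutations for the null.
#' @param seed integer seed.
#' @param smoothPoints accuracy smoothing width.
#' @param pointAlpha per-point alpha.
#' @param clusterAlpha family-wise alpha.
#' @param postOnsetOnly restrict the analysis to time points at or after 0 ms.
#' @param nClasses number of class codes.
#' @return List: \code{clusters} ([ClusterSet-class] with p),
#'   \code{null} (numeric), \code{accMatrix} (participants x analyzed time
#'   points), \code{times} (analyzed ms axis).
#' @export
clusterTestVsChance <- function(stores, mu = 0.25, nPerm = 1000L, seed = 1L,
                                smoothPoints = 5L, pointAlpha = 0.05,
                                clusterAlpha = 0.05, postOnsetOnly = TRUE,
                                nClasses = 4L) {
  times <- stores[[1]]@times
  mask <- if (postOnsetOnly) times >= 0 else rep(TRUE, length(times))
  acc <- t(vapply(stores, function(st)
    runningMean(colMeans(st@predicted == st@trueClass), as.integer(smoothPoints)),
    numeric(length(times))))
  accM <- acc[, mask, drop = FALSE]
  cs <- formClusters(pointwiseT(accM, mu), length(stores) - 1, "one",
                     pointAlpha, times = times[mask])
  null <- nullVsChance(stores, nPerm = nPerm, seed = seed, mu = mu,
                       smoothPoints = smoothPoints, pointAlpha = pointAlpha,
                       tail = "one", nClasses = nClasses, timeMask = mask)
  list(clusters = clusterPvalues(cs, null, clusterAlpha), null = null,
       accMatrix = accM, times = times[mask])
}

#' Cluster-based permutation test of a paired condition difference
#'
#' Two-tailed paired comparison of two (smoothed) accuracy matrices with a
#' condition-swap null.
#'
#' @param accA,accB participants x time accuracy matrices (smoothed).
#' @param times ms axis.
#' @param nPerm permutations.
#' @param seed integer seed.
#' @param pointAlpha per-point alpha.
#' @param clusterAlpha family-wise alpha.
#' @return List: \code{clusters} ([ClusterSet-class] with p; positive mass
#'   means A > B), \code{null}.
#' @export
clusterTestConditionDiff <- function(accA, accB, times = NULL, nPerm = 1000L,
                                     seed = 1L, pointAlpha = 0.05,
                                     clusterAlpha = 0.05) {
  if (is.null(times)) times <- seq_len(ncol(accA))
  cs <- formClusters(pairedT(accA, accB), nrow(accA) - 1, "two", pointAlpha,
                     times = times)
  null <- nullConditionSwap(accA, accB, nPerm = nPerm, seed = seed,
                            pointAlpha = pointAlpha)
  list(clusters = clusterPvalues(cs, null, clusterAlpha), null = null)
}

#' One-sample (or paired-difference) t test
#'
#' Exact Student t with the requested tail. Zero-variance input yields a
#' signed-infinite t with p of 0 or 1 accordingly (documented behavior, not
#' an error).
#'
#' @param x numeric per-participant values (for a paired design, the
#'   differences).
#' @param mu null mean.
#' @param tail \code{"two"}, \code{"greater"} or \code{"less"}.
#' @return List with \code{t}, \code{df}, \code{p}.
#' @export
oneSampleTTest <- function(x, mu = 0, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  n <- length(x)
  if (n < 2L) stop("need at least 2 observations")
  s <- stats::sd(x)
  tstat <- if (s == 0) sign(mean(x) - mu) * Inf else
    (mean(x) - mu) / (s / sqrt(n))
  if (is.nan(tstat)) tstat <- 0
  list(t = tstat, df = n - 1, p = tTailP(tstat, n - 1, tail))
}

#' Tail p-value for a t statistic
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @param tail \code{"two"}, \code{"greater"} or \code{"less"}.
#' @return The p-value.
#' @export
tTailP <- function(t, df, tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  switch(tail,
    two = 2 * stats::pt(-abs(t), df),
    greater = stats::pt(t, df, lower.tail = FALSE),
    less = stats::pt(t, df))
}

#' JZS Bayes factor favoring the null (one-sample t)
#'
#' Default-prior Bayes factor for the one-sample (or paired) t test with a
#' Cauchy(0, r) prior on the standardized effect size: the marginal
#' likelihood under the alternative is the Cauchy mixture of noncentral-t
#' densities at the observed t, evaluated by adaptive quadrature, and BF01
#' is the central-t density over that marginal. Strictly decreasing in |t|
#' for fixed n.
#'
#' @param t observed t statistic.
#' @param n sample size (df = n - 1).
#' @param r Cauchy prior scale on effect size (default 0.707 = sqrt(2)/2).
#' @return BF01, the evidence ratio null / alternative.
#' @export
jzsBF01 <- function(t, n, r = 0.707) {
  if (n < 2) stop("n must be >= 2")
  if (r <= 0) stop("prior scale r must be positive")
  df <- n - 1
  f <- function(delta) stats::dt(t, df, ncp = delta * sqrt(n)) *
    stats::dcauchy(delta, 0, r)
  marg <- tryCatch(
    suppressWarnings(stats::integrate(f, -Inf, Inf, rel.tol = 1e-9, abs.tol = 0)),
    error = function(e) stop("quadrature failed: ", conditionMessage(e)))
  if (marg$value <= 0) stop("quadrature returned a non-positive marginal")
  stats::dt(t, df) / marg$value
}
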