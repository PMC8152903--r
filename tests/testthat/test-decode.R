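test_that("balanced partitioning drops the remainder and is seed-deterministic", {
  cls <- rep(1:4, each = 160)
  fa <- partitionBalanced(cls, 3, 11)
  for (c in as.character(1:4)) {
    expect_equal(lengths(fa@groups[[c]]), c(`1` = 53L, `2` = 53L, `3` = 53L))
    expect_length(fa@dropped[[c]], 1)
    all_idx <- sort(unname(c(unlist(fa@groups[[c]]), fa@dropped[[c]])))
    expect_equal(all_idx, which(cls == as.integer(c)))
  }
  expect_identical(partitionBalanced(cls, 3, 11)@groups, fa@groups)
  expect_false(identical(partitionBalanced(cls, 3, 12)@groups, fa@groups))

  fa2 <- partitionBalanced(rep(1:4, each = 12), 3, 5)
  expect_true(all(lengths(fa2@dropped) == 0))
  expect_true(all(unlist(lapply(fa2@groups, lengths)) == 4))
  expect_error(partitionBalanced(c(1, 1, 1, 2, 2), 3, 1), "class 2")
})

test_that("group averaging produces the groups x classes x channels matrix", {
  ep <- makeTinyEpochs(nTrials = 24, nChannels = 5, nTimes = 10)
  cls <- rep(1:4, each = 6)
  fa <- partitionBalanced(cls, 3, 2)
  av <- averageByGroup(ep, fa, 4)
  expect_equal(dim(av), c(3L, 4L, 5L))
  for (c in 1:4) for (g in 1:3) {
    idx <- fa@groups[[as.character(c)]][[g]]
    expect_equal(av[g, c, ], colMeans(ep@data[idx, , 4, drop = FALSE][, , 1]))
  }
  # singleton groups: averaging is the identity
  ep8 <- makeTinyEpochs(nTrials = 8, nChannels = 3, nTimes = 6)
  fa1 <- partitionBalanced(rep(1:4, each = 2), 2, 1)
  av1 <- averageByGroup(ep8, fa1, 2)
  expect_equal(dim(av1), c(2L, 4L, 3L))
  for (c in 1:4) for (g in 1:2)
    expect_equal(av1[g, c, ],
                 ep8@data[fa1@groups[[as.character(c)]][[g]], , 2])
})

test_that("ECOC prediction recalls separable centroids and breaks ties low", {
  ctr <- cbind(diag(4) * 3, matrix(0, 4, 6))
  train <- ctr[rep(1:4, 2), ]
  expect_equal(fitPredictEcoc(train, rep(1:4, 2), ctr), 1:4)
  # fully symmetric degenerate case: every class tied -> lowest class code
  expect_equal(fitPredictEcoc(matrix(0, 8, 5), rep(1:4, 2), matrix(0, 3, 5)),
               rep(1L, 3))
  expect_error(fitPredictEcoc(train, rep(1, 8), ctr), "2 classes")
})

test_that("ECOC on label-free Gaussian data converges to chance (Monte-Carlo oracle)", {
  set.seed(61)
  hits <- replicate(300, {
    X <- matrix(rnorm(8 * 10), 8, 10)
    Xt <- matrix(rnorm(4 * 10), 4, 10)
    fitPredictEcoc(X, rep(1:4, 2), Xt) == 1:4
  })
  n <- length(hits)
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("ECOC decisions and predictions match an independent SVM implementation", {
  skip_if_not_installed("e1071")
  set.seed(42)
  mism <- 0; maxdv <- 0
  for (rep in 1:40) {
    nch <- 12
    centers <- matrix(rnorm(4 * nch, sd = 1.5), 4, nch)
    cls <- rep(1:4, 2)
    X <- centers[cls, ] + 0.5 * matrix(rnorm(8 * nch), 8, nch)
    Xt <- centers + 0.5 * matrix(rnorm(4 * nch), 4, nch)
    mu <- colMeans(X); sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
    Xs <- scale(X, mu, sdv); Xts <- scale(Xt, mu, sdv)
    M <- array(rbind(X, Xt), c(12, nch, 1))
    dvPkg <- erpdecode:::.ecocDecisionCpp(as.numeric(M), dim(M), 1:8, cls,
                                          9:12, 4L, 1, TRUE)
    dvRef <- sapply(1:4, function(c) {
      y <- factor(ifelse(cls == c, "pos", "neg"), levels = c("pos", "neg"))
      m <- e1071::svm(Xs, y, kernel = "linear", cost = 1, scale = FALSE,
                      type = "C-classification")
      dv <- attr(predict(m, Xts, decision.values = TRUE), "decision.values")
      if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
    })
    maxdv <- max(maxdv, max(abs(dvPkg - dvRef)))
    # brute-force minimal-binary-loss oracle on the reference decisions
    lossRef <- sapply(1:4, function(c) {
      m <- ifelse(1:4 == c, 1, -1)
      apply(dvRef, 1, function(f) sum(pmax(0, 1 - m * f) / 2))
    })
    predOracle <- apply(lossRef, 1, which.min)
    predPkg <- fitPredictEcoc(X, cls, Xt)
    mism <- mism + sum(predPkg != predOracle)
  }
  expect_lt(maxdv, 0.02)
  expect_equal(mism, 0)
})

test_that("timecourse decoding: 120 attempts, exact store consistency, determinism", {
  cfg <- SynthConfig(nTrials = 48, nChannels = 6, noiseSd = 2, alphaAmp = 0)
  ep <- simulateParticipant(cfg, makeTopographies(cfg, 1), 2)
  ep <- cropEpochs(ep, c(-100, 300))
  cls <- collapseDimension(trialLabels(ep), "identity")
  res <- decodeTimecourse(ep, cls, DecodeConfig(), 5)
  expect_equal(nAttempts(res$series), 4 * 3 * 10)
  expect_equal(nrow(res$store@predicted), 120)
  # accuracy recomputed from the store equals the series exactly
  raw <- colMeans(res$store@predicted == res$store@trueClass)
  expect_identical(accuracy(res$series),
                   erpdecode:::runningMean(raw, 5L))
  expect_identical(accuracy(accuracyFromStore(res$store)), raw)
  # bit-for-bit determinism under the master seed
  res2 <- decodeTimecourse(ep, cls, DecodeConfig(), 5)
  expect_identical(res$store@predicted, res2$store@predicted)
})

test_that("decoding is invariant to trial order given the same fold content", {
  ep <- makeTinyEpochs(nTrials = 24, nChannels = 5, nTimes = 8)
  cls <- rep(1:4, each = 6)
  fa <- partitionBalanced(cls, 3, 3)
  set.seed(9)
  perm <- sample(24)
  epP <- ep
  epP@data <- ep@data[perm, , , drop = FALSE]
  inv <- order(perm) # trial i of ep is row inv[i]... map original index -> new
  mapIdx <- function(v) match(v, perm)
  faP <- fa
  for (c in seq_along(fa@groups)) {
    faP@groups[[c]] <- lapply(fa@groups[[c]], mapIdx)
    faP@dropped[[c]] <- mapIdx(fa@dropped[[c]])
  }
  expect_equal(averageByGroup(ep, fa, 5), averageByGroup(epP, faP, 5))
})

test_that("cross-time decoding: 20x20 grid, diagonal equals windowed timecourse", {
  cfg <- SynthConfig(nTrials = 96, nChannels = 10, noiseSd = 5, alphaAmp = 0)
  ep <- simulateParticipant(cfg, makeTopographies(cfg, 5), 6)
  cls <- collapseDimension(trialLabels(ep), "identity")
  cfgD <- DecodeConfig(nIterations = 2)
  gm <- decodeCrosstime(ep, cls, cfgD, 9)
  expect_equal(dim(accuracy(gm)), c(20L, 20L))
  expect_equal(gm@windowTimes, seq(-500, 1400, by = 100))
  tc <- decodeTimecourse(windowAverage(ep, 100), cls, cfgD, 9)
  expect_equal(diag(accuracy(gm)), accuracy(accuracyFromStore(tc$store)))
  # dynamic (3-segment) code: training and testing on the same window is
  # stronger than far off-diagonal transfer
  A <- accuracy(gm)
  post <- which(gm@windowTimes >= 0)
  off <- abs(outer(post, post, "-")) >= 3
  expect_gt(mean(diag(A)[post]), mean(A[post, post][off]))
})

test_that("static single-segment code generalizes across the whole post-onset grid", {
  # flat post-onset envelope: the class pattern is constant from ~0 ms on
  cfg <- SynthConfig(nTrials = 48, nChannels = 8, noiseSd = 0, alphaAmp = 0,
                     expressionGain = 0, nSegments = 1, segmentBoundaries = 0,
                     idOnset = 0, idPeak = 4, idDecay = 4, idPlateau = 1)
  ep <- simulateParticipant(cfg, makeTopographies(cfg, 2), 3)
  cls <- collapseDimension(trialLabels(ep), "identity")
  gm <- decodeCrosstime(ep, cls, DecodeConfig(nIterations = 1), 4)
  on <- which(gm@windowTimes >= 100) # windows fully inside the signal
  expect_true(all(accuracy(gm)[on, on] == 1))
})

test_that("cross-dimension decoding isolates generalizable target information", {
  cfgD <- DecodeConfig()
  # control dimension carries all the signal -> target decoding at chance
  cfg0 <- SynthConfig(nTrials = 160, nChannels = 12, identityGain = 0,
                      noiseSd = 4, alphaAmp = 0)
  ep0 <- simulateParticipant(cfg0, makeTopographies(cfg0, 2), 3)
  lab0 <- trialLabels(ep0)
  r0 <- decodeCrossdim(ep0, collapseDimension(lab0, "identity"),
                       collapseDimension(lab0, "expression"), cfgD)
  tm <- seriesTimes(r0$series)
  expect_lt(abs(mean(accuracy(r0$series)[tm >= 0]) - 0.25), 0.08)
  expect_equal(nrow(r0$store@predicted), 16) # 4 rotations x 4 classes

  # target signal independent of control, noiseless -> perfect where active
  cfg1 <- SynthConfig(nTrials = 64, nChannels = 12, expressionGain = 0,
                      noiseSd = 0, alphaAmp = 0, nSegments = 1,
                      segmentBoundaries = 0)
  ep1 <- simulateParticipant(cfg1, makeTopographies(cfg1, 2), 3)
  lab1 <- trialLabels(ep1)
  r1 <- decodeCrossdim(ep1, collapseDimension(lab1, "identity"),
                       collapseDimension(lab1, "expression"), cfgD)
  env <- envelopeGain("identity", tm, cfg1)
  expect_true(all(accuracy(accuracyFromStore(r1$store))[env > 0.05] == 1))

  expect_error(decodeCrossdim(ep1, rep(1:4, 16), rep(1:4, 16), cfgD),
               "empty target-class x control-level cell")
})

test_that("interaction-only patterns decode within but not across control levels", {
  # class information carried on disjoint channel blocks per control level:
  # fully decodable within a level, with nothing that generalizes to the
  # held-out level's channels
  set.seed(21)
  nCh <- 16; nTr <- 64; nT <- 6
  P <- array(0, c(nCh, 4, 4)) # channel x target class x control level
  for (l in 1:4) P[(l - 1) * 4 + 1:4, , l] <- rnorm(16, sd = 2)
  lab <- erpdecode:::simulateLabels(SynthConfig(nTrials = nTr, nChannels = 2), 8)
  X <- array(0.05 * rnorm(nTr * nCh * nT), c(nTr, nCh, nT))
  for (j in seq_len(nTr))
    X[j, , ] <- X[j, , ] + P[, lab$identity[j], lab$expression[j]]
  ep <- EpochSet(X, fs = 250, tStart = 0, labels = lab)
  cfgD <- DecodeConfig(nIterations = 3, smoothPoints = 1)
  std <- decodeTimecourse(ep, lab$identity, cfgD, 4)
  xd <- decodeCrossdim(ep, lab$identity, lab$expression, cfgD)
  # the standard analysis exploits the level-specific signal freely
  expect_gt(mean(accuracy(std$series)), 0.6)
  # the cross-dimension analysis is immune: accuracy stays at chance
  expect_lt(abs(mean(accuracy(xd$series)) - 0.25), 0.1)
})

test_that("confusion matrices pool periods and are row-stochastic", {
  cfg <- SynthConfig(nTrials = 64, nChannels = 8, noiseSd = 0, alphaAmp = 0,
                     expressionGain = 0, nSegments = 1, segmentBoundaries = 0,
                     idDecay = 2000)
  ep <- simulateParticipant(cfg, makeTopographies(cfg, 2), 3)
  res <- decodeTimecourse(ep, collapseDimension(trialLabels(ep), "identity"),
                          DecodeConfig(nIterations = 1), 4)
  cms <- confusionByPeriod(res$store)
  expect_named(cms, c("perception", "maintenance"))
  expect_equal(attr(cms$perception, "period"), c(0, 500))
  # perfect decoder inside the signal period -> identity matrix
  expect_equal(unname(unclass(cms$maintenance)), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(rowSums(cms$perception)), rep(1, 4), tolerance = 1e-9)
  expect_error(confusionByPeriod(res$store, list(bad = c(5000, 6000))),
               "no time points")
  # uniform random predictions -> all entries near 0.25
  fake <- res$store
  set.seed(2)
  fake@predicted <- matrix(sample(1:4, length(fake@predicted), TRUE),
                           nrow(fake@predicted))
  cmU <- confusionByPeriod(fake)$perception
  expect_lt(max(abs(cmU - 0.25)), 0.05)
})
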