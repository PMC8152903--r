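test_that("point-wise t statistics match hand arithmetic", {
  acc <- matrix(0.25, 5, 4)
  expect_equal(pointwiseT(acc, 0.25), rep(0, 4))
  # n = 22, mean 0.30, sd 0.10 -> t = 0.05 / (0.10 / sqrt(22)) = 2.3452
  set.seed(3)
  x <- as.vector(scale(rnorm(22))) * 0.10 + 0.30
  tt <- pointwiseT(matrix(x, 22, 1), 0.25)
  expect_equal(tt, 0.05 / (0.10 / sqrt(22)), tolerance = 1e-9)
  expect_equal(tt, 2.345, tolerance = 1e-3)
  # zero-variance columns give signed infinities, 0 when centered on mu
  degen <- cbind(rep(0.30, 4), rep(0.20, 4), rep(0.25, 4))
  expect_equal(pointwiseT(degen, 0.25), c(Inf, -Inf, 0))
  # paired variant on identical conditions
  expect_equal(erpdecode:::pairedT(acc, acc), rep(0, 4))
  expect_error(pointwiseT(matrix(1, 1, 3)), "at least 2")
})

test_that("cluster formation finds maximal contiguous runs with summed mass", {
  df <- 9
  none <- formClusters(rep(0.5, 20), df, "one")
  expect_equal(nrow(clusters(none)), 0)
  ts <- rep(0, 25); ts[6:15] <- 3
  cs <- formClusters(ts, df, "one", times = (0:24) * 4)
  expect_equal(nrow(clusters(cs)), 1)
  expect_equal(clusters(cs)$mass, 30)
  expect_equal(clusters(cs)$startTime, 20)
  expect_equal(clusters(cs)$endTime, 56)
  # a single sub-threshold point splits a run in two
  ts2 <- rep(3, 11); ts2[6] <- 0
  cs2 <- formClusters(ts2, df, "one")
  expect_equal(nrow(clusters(cs2)), 2)
  expect_equal(clusters(cs2)$mass, c(15, 15))
  # two-tailed: positive and negative clusters kept separately, signed mass
  ts3 <- c(rep(4, 3), 0, rep(-4, 3))
  cs3 <- formClusters(ts3, df, "two")
  expect_equal(clusters(cs3)$mass, c(12, -12))
  # single-point clusters are permitted
  ts4 <- rep(0, 9); ts4[5] <- 5
  expect_equal(nrow(clusters(formClusters(ts4, df, "one"))), 1)
})

test_that("relabeling null is centered on chance and includes the identity relabeling", {
  cfg <- nullStudyConfig(nParticipants = 3, nTrials = 64, nChannels = 6)
  cfg@epochMs <- c(0, 160)
  stores <- decodeGroup(cfg, nullStudyDecodeConfig(2), 17)
  null <- nullVsChance(stores, nPerm = 200, seed = 8)
  expect_length(null, 200)
  expect_true(all(null >= 0))
  # mean relabeled accuracy over permutations is chance
  perms <- erpdecode:::allPermutations(4L)
  set.seed(1)
  accs <- replicate(100, {
    pms <- lapply(1:3, function(s) perms[sample.int(24, 1), ])
    mean(erpdecode:::relabeledAccuracy(stores, pms, 1L))
  })
  expect_lt(abs(mean(accs) - 0.25), 3 * sqrt(0.25 * 0.75 / (24 * 40 * 100)) + 0.01)
  # identity relabeling reproduces the observed series exactly
  idmap <- lapply(1:3, function(s) 1:4)
  accId <- erpdecode:::relabeledAccuracy(stores, idmap, 5L)
  expect_equal(accId, accMatrix(stores))
  expect_error(nullVsChance(stores, nPerm = 0), "nPerm")
})

test_that("relabeling null matches exhaustive enumeration on a toy store", {
  # 5 participants, 3 classes, 20 time points; 6^5 = 7776 relabeling schemes
  # 8 attempts make every accuracy a dyadic rational, so the package's
  # cumulative-sum smoother and the oracle's windowed mean agree bitwise
  nS <- 5; nT <- 20; nAtt <- 8
  set.seed(33)
  stores <- lapply(1:nS, function(s) {
    new("PredictionStore",
        predicted = matrix(sample(1:3, nAtt * nT, TRUE), nAtt, nT),
        trueClass = rep(1:3, c(3, 3, 2)), times = (0:(nT - 1)) * 4,
        iteration = rep(1L, nAtt), fold = rep(1L, nAtt))
  })
  # independent oracle: plain-R enumeration of every relabeling combination
  perms3 <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  smoothNaive <- function(x, np = 5) {
    n <- length(x); h <- (np - 1) / 2
    sapply(seq_len(n), function(i) {
      hh <- min(h, i - 1, n - i)
      mean(x[(i - hh):(i + hh)])
    })
  }
  maxMass <- function(combo) {
    acc <- t(sapply(1:nS, function(s) {
      st <- stores[[s]]
      smoothNaive(colMeans(st@predicted == perms3[combo[s], ][st@trueClass]))
    }))
    m <- colMeans(acc); sdv <- apply(acc, 2, sd)
    tstat <- ifelse(sdv == 0, ifelse(m > 1 / 3, Inf, ifelse(m < 1 / 3, -Inf, 0)),
                    (m - 1 / 3) / (sdv / sqrt(nS)))
    sig <- tstat > qt(0.95, nS - 1)
    if (!any(sig)) return(0)
    r <- rle(sig)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    masses <- mapply(function(a, b) sum(tstat[a:b]),
                     starts[r$values], ends[r$values])
    max(masses)
  }
  combos <- as.matrix(expand.grid(rep(list(1:6), nS)))
  oracle <- apply(combos, 1, maxMass)
  null <- nullVsChance(stores, nPerm = 400, seed = 12, mu = 1 / 3,
                       nClasses = 3L)
  # every sampled mass occurs in the enumerated distribution (zero-variance
  # columns yield infinite t mass in both implementations)
  isIn <- vapply(null, function(v) {
    if (is.infinite(v)) any(is.infinite(oracle) & sign(oracle) == sign(v))
    else any(abs(oracle - v) < 1e-9)
  }, logical(1))
  expect_true(all(isIn))
  # and the sampled distribution tracks the enumerated one
  fo <- oracle[is.finite(oracle)]; fn <- null[is.finite(null)]
  expect_lt(abs(mean(fn) - mean(fo)), 3 * sd(fo) / sqrt(length(fn)) + 0.05)
  expect_lt(abs(mean(is.infinite(null)) - mean(is.infinite(oracle))),
            3 * sqrt(mean(is.infinite(oracle)) * 0.99 / length(null)) + 0.02)
  expect_lte(max(fn), max(fo))
})

test_that("condition-swap null: identical conditions give an all-zero null", {
  A <- matrix(runif(60), 6, 10)
  null <- nullConditionSwap(A, A, nPerm = 50, seed = 3)
  expect_equal(null, rep(0, 50))
  # swapping every participant exactly negates the paired difference
  B <- A + matrix(rnorm(60, sd = 0.1), 6, 10)
  tAB <- erpdecode:::pairedT(A, B)
  tBA <- erpdecode:::pairedT(B, A)
  expect_equal(tAB, -tBA)
  expect_error(nullConditionSwap(A, A[, 1:5]), "equal shapes")
})

test_that("cluster p-values use the counting estimator with a 1/nPerm floor", {
  cs <- formClusters(c(rep(0, 5), rep(3, 5)), 9, "one")
  null <- c(0, sort(runif(999, 0, 30)))
  got <- clusterPvalues(cs, null)
  m <- clusters(got)$mass
  expect_equal(clusters(got)$p, max(sum(null >= m) / 1000, 1e-3))
  # observed above every null mass -> floored at 1/nPerm (reported < 0.001)
  bigger <- formClusters(rep(10, 10), 9, "one")
  expect_equal(clusters(clusterPvalues(bigger, null))$p, 1e-3)
  expect_true(clusters(clusterPvalues(bigger, null))$significant)
  # observed at the null median -> p ~ 0.5; below every null -> p = 1
  target <- median(null)
  if (target > qt(0.95, 9)) {
    csMed <- formClusters(c(rep(0, 9), target), 9, "one")
    pMed <- clusters(clusterPvalues(csMed, null))$p
    expect_lt(abs(pMed - 0.5), 2 / 1000 + 0.01)
  }
  tiny <- formClusters(c(rep(0, 9), qt(0.96, 9)), 9, "one")
  expect_equal(clusters(clusterPvalues(tiny, c(sort(runif(100, 20, 30)))))$p, 1)
  # monotonicity: p non-increasing in observed mass
  masses <- c(1, 5, 10, 25)
  ps <- sapply(masses, function(m) {
    cs <- formClusters(c(rep(0, 5), m), 4, "one", pointAlpha = 0.49)
    clusters(clusterPvalues(cs, null))$p
  })
  expect_true(all(diff(ps) <= 0))
  expect_error(clusterPvalues(cs, numeric(0)), "empty")
})

test_that("one-sample t test reproduces printed behavioral statistics", {
  # the reference paired behavioral comparison: t(21) = 0.733 -> p = 0.472
  expect_equal(tTailP(0.733, 21, "two"), 0.472, tolerance = 0.002)
  x <- rep(0.4, 6)
  r <- oneSampleTTest(x, mu = 0.4)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  # n = 4 hand-computed oracle
  y <- c(0.3, 0.35, 0.25, 0.30)
  m <- mean(y); s <- sd(y)
  tHand <- (m - 0.25) / (s / sqrt(4))
  r4 <- oneSampleTTest(y, mu = 0.25)
  expect_equal(r4$t, tHand, tolerance = 1e-12)
  expect_equal(r4$df, 3)
  expect_equal(r4$p, 2 * pt(-abs(tHand), 3), tolerance = 1e-12)
  # matches stats::t.test
  ref <- t.test(y, mu = 0.25)
  expect_equal(r4$t, unname(ref$statistic))
  expect_equal(r4$p, ref$p.value)
  r1 <- oneSampleTTest(y, mu = 0.25, tail = "greater")
  expect_equal(r1$p, pt(tHand, 3, lower.tail = FALSE))
  expect_error(oneSampleTTest(1), "at least 2")
})

test_that("JZS Bayes factor agrees with an independent quadrature and is monotone", {
  # independent oracle: Zellner-Siow g-integral (inverse-gamma(1/2, r^2/2))
  bf10G <- function(t, n, r) {
    df <- n - 1
    f <- function(g)
      (1 + n * g)^(-1 / 2) *
        ((1 + t^2 / ((1 + n * g) * df)) / (1 + t^2 / df))^(-(df + 1) / 2) *
        r / (sqrt(2 * pi) * g^(3 / 2)) * exp(-r^2 / (2 * g))
    integrate(f, 0, Inf, rel.tol = 1e-10)$value
  }
  for (tv in c(0, 0.733, 2.5)) {
    expect_equal(jzsBF01(tv, 22, 0.707), 1 / bf10G(tv, 22, 0.707),
                 tolerance = 1e-3)
  }
  expect_gt(jzsBF01(0, 22), 1)
  # reciprocal consistency with an independently computed BF10
  expect_equal(jzsBF01(0.733, 22, 0.707) * bf10G(0.733, 22, 0.707), 1,
               tolerance = 1e-6)
  # strictly decreasing in |t|; overwhelming evidence at |t| = 10
  bfs <- sapply(c(0, 0.5, 1, 2, 4, 10), function(tv) jzsBF01(tv, 22))
  expect_true(all(diff(bfs) < 0))
  expect_lt(jzsBF01(10, 22), 0.01)
  expect_error(jzsBF01(1, 1), "n must be")
  expect_error(jzsBF01(1, 22, r = 0), "prior scale")
})

test_that("vs-chance cluster test restricts to post-onset points and is reproducible", {
  cfg <- nullStudyConfig(nParticipants = 4, nTrials = 64, nChannels = 6)
  cfg@epochMs <- c(-100, 200)
  stores <- decodeGroup(cfg, nullStudyDecodeConfig(2), 55)
  ct <- clusterTestVsChance(stores, nPerm = 100, seed = 2)
  expect_true(all(ct$times >= 0))
  ct2 <- clusterTestVsChance(stores, nPerm = 100, seed = 2)
  expect_identical(ct$null, ct2$null)
  expect_identical(clusters(ct$clusters), clusters(ct2$clusters))
})
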