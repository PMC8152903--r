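#' Create a synthetic study configuration
#'
#' Thin constructor over [SynthConfig-class]; any slot can be overridden by
#' name. See the class documentation for defaults and units.
#'
#' @param ... named slot overrides, e.g. \code{nParticipants = 10}.
#' @return A validated [SynthConfig-class].
#' @export
SynthConfig <- function(...) {
  args <- list(...)
  proto <- new("SynthConfig")
  for (nm in names(args)) {
    cls <- class(slot(proto, nm))
    slot(proto, nm) <- if (cls == "integer") as.integer(args[[nm]]) else as.numeric(args[[nm]])
  }
  validObject(proto)
  proto
}

# number of time samples implied by the half-open epoch interval
synthNTimes <- function(config) round(diff(config@epochMs) * config@fs / 1000)

#' Draw class topographies
#'
#' One unit-norm random spatial vector per class and pattern segment, for
#' each face dimension. Consecutive segments of the same class are positively
#' correlated but not identical when more than one segment is configured
#' (dynamic coding); with a single segment the pattern is static.
#'
#' @param config a [SynthConfig-class].
#' @param seed integer seed; the result is a deterministic function of
#'   (config, seed).
#' @return A [TopographySet-class].
#' @export
makeTopographies <- function(config, seed) {
  if (config@nSegments < 1L) stop("nSegments must be >= 1")
  nCh <- config@nChannels
  nSeg <- config@nSegments
  draw <- function() {
    a <- array(0, c(nCh, 4L, nSeg))
    for (cl in 1:4) {
      v <- stats::rnorm(nCh)
      a[, cl, 1L] <- v / sqrt(sum(v^2))
      if (nSeg > 1L) for (s in 2:nSeg) {
        w <- 0.6 * a[, cl, s - 1L] + 0.8 * stats::rnorm(nCh) / sqrt(nCh)
        a[, cl, s] <- w / sqrt(sum(w^2))
      }
    }
    a
  }
  withSeed(seed, {
    tid <- draw()
    tex <- draw()
    new("TopographySet", identity = tid, expression = tex)
  })
}

#' Temporal gain envelope
#'
#' Deterministic gain multiplier in [0, 1] as a function of epoch time.
#' All envelopes are zero before their onset. The rise is a squared
#' quarter-sine reaching 1 at the peak; the fall is a half-cosine over the
#' configured decay duration, settling exactly on the plateau (0 for
#' identity by default, positive and sustained for expression). The
#' reactivation envelope is a raised-cosine bump starting after stimulus
#' onset, modeling the re-emergence of the previous trial's pattern.
#'
#' @param dimension \code{"identity"}, \code{"expression"} or
#'   \code{"reactivation"}.
#' @param t time(s) in ms relative to stimulus onset (vectorized).
#' @param config a [SynthConfig-class].
#' @return Numeric gain(s) in [0, 1].
#' @export
envelopeGain <- function(dimension = c("identity", "expression", "reactivation"),
                         t, config) {
  dimension <- match.arg(dimension)
  if (dimension == "reactivation") {
    onset <- config@reactOnset
    width <- config@reactWidth
    u <- (t - onset) / width
    out <- ifelse(u >= 0 & u <= 1, 0.5 - 0.5 * cos(2 * pi * u), 0)
    return(pmin(pmax(out, 0), 1))
  }
  p <- switch(dimension,
    identity = list(onset = config@idOnset, peak = config@idPeak,
                    decay = config@idDecay, plateau = config@idPlateau),
    expression = list(onset = config@exOnset, peak = config@exPeak,
                      decay = config@exDecay, plateau = config@exPlateau))
  out <- numeric(length(t))
  rise <- t >= p$onset & t < p$peak
  out[rise] <- sin(0.5 * pi * (t[rise] - p$onset) / (p$peak - p$onset))^2
  fall <- t >= p$peak & t < p$peak + p$decay
  out[fall] <- p$plateau +
    (1 - p$plateau) * 0.5 * (1 + cos(pi * (t[fall] - p$peak) / p$decay))
  out[t >= p$peak + p$decay] <- p$plateau
  pmin(pmax(out, 0), 1)
}

# segment index per time point: segment s spans [boundary_s, boundary_{s+1})
# post-onset; pre-onset times map to segment 1 (envelopes are zero there).
segmentIndex <- function(times, config) {
  idx <- findInterval(times, config@segmentBoundaries)
  idx[idx < 1L] <- 1L
  idx[idx > config@nSegments] <- config@nSegments
  idx
}

# Sequence nTrials cells (1..16) such that consecutive trials never share
# identity or expression; counts gives the multiset of cells to place.
# Restarts on dead ends (rare). Returns integer cell codes.
sequenceCells <- function(counts) {
  nTot <- sum(counts)
  idOf <- rep(1:4, each = 4)
  exOf <- rep(1:4, times = 4)
  for (attempt in 1:200) {
    rem <- counts
    seqc <- integer(nTot)
    prevId <- 0L; prevEx <- 0L
    ok <- TRUE
    for (i in seq_len(nTot)) {
      cand <- which(rem > 0L & idOf != prevId & exOf != prevEx)
      if (!length(cand)) { ok <- FALSE; break }
      cell <- if (length(cand) == 1L) cand else
        sample(cand, 1L, prob = rem[cand])
      seqc[i] <- cell
      rem[cell] <- rem[cell] - 1L
      prevId <- idOf[cell]; prevEx <- exOf[cell]
    }
    if (ok) return(seqc)
  }
  stop("could not sequence trials under the no-repeat constraint (infeasible balance)")
}

# Simulate the per-trial label table: balanced analysis trials plus optional
# extra post-test-flagged trials, sequenced with the no-repeat constraint.
simulateLabels <- function(config, seed) {
  withSeed(seed, {
    base <- config@nTrials %/% 16L
    counts <- rep(base, 16L)
    extra <- integer(16L)
    if (config@nExtraPostTest > 0L) {
      add <- sample.int(16L, config@nExtraPostTest, replace = TRUE)
      extra <- tabulate(add, 16L)
    }
    seqc <- sequenceCells(counts + extra)
    # decide which occurrences of each cell carry the post-test flag
    flags <- logical(length(seqc))
    for (cell in which(extra > 0L)) {
      occ <- which(seqc == cell)
      flags[sample(occ, extra[cell])] <- TRUE
    }
    data.frame(
      trial_index = seq_along(seqc),
      identity = rep(1:4, each = 4)[seqc],
      expression = rep(1:4, times = 4)[seqc],
      is_post_test = flags,
      is_first = seq_along(seqc) == 1L
    )
  })
}

#' Simulate one participant's epochs
#'
#' Builds the voltage tensor as
#' \deqn{x_{j,\cdot}(t) = g_{ID}\,e_{ID}(t)\,T_{ID}(c_j, s(t)) +
#'   g_{EX}\,e_{EX}(t)\,T_{EX}(d_j, s(t)) +
#'   \rho\,e_{R}(t)\,T_{ID}(c_{j-1}, s(t)) + \mathrm{noise}}
#' where \eqn{c_j, d_j} are trial j's identity and expression,
#' \eqn{c_{j-1}} the previous trial's identity, \eqn{e} the envelopes,
#' \eqn{T} the segmentwise topographies and \eqn{s(t)} the segment index.
#' Noise is Gaussian AR(1) in time (coefficient \code{arPhi}, innovation sd
#' \code{noiseSd}), independent across channels and trials, plus one
#' alpha-band sinusoid per trial (frequency uniform in 8-12 Hz, uniform
#' phase) applied to all channels.
#'
#' @param config a [SynthConfig-class].
#' @param topo a [TopographySet-class] from [makeTopographies()].
#' @param seed integer seed; output is bit-reproducible given
#'   (config, topo, seed).
#' @param participantId identifier stored in the result.
#' @return An [EpochSet-class].
#' @export
simulateParticipant <- function(config, topo, seed, participantId = "sim01") {
  labels <- simulateLabels(config, seed)
  nTr <- nrow(labels)
  nCh <- config@nChannels
  nT <- synthNTimes(config)
  times <- config@epochMs[1] + (seq_len(nT) - 1) * 1000 / config@fs
  seg <- segmentIndex(times, config)

  envId <- envelopeGain("identity", times, config)
  envEx <- envelopeGain("expression", times, config)
  envRe <- envelopeGain("reactivation", times, config)

  # class- and dimension-specific signal templates, channels x time
  tmplId <- lapply(1:4, function(cl)
    config@identityGain * topo@identity[, cl, seg] *
      rep(envId, each = nCh))
  tmplEx <- lapply(1:4, function(cl)
    config@expressionGain * topo@expression[, cl, seg] *
      rep(envEx, each = nCh))
  tmplRe <- lapply(1:4, function(cl)
    config@reactivationGain * topo@identity[, cl, seg] *
      rep(envRe, each = nCh))

  prevId <- c(NA_integer_, labels$identity[-nTr])

  withSeed(deriveSeeds(seed, 2L)[2L], {
    # noise for all (trial, channel) rows at once; AR(1) recursion over time
    M <- matrix(stats::rnorm(nTr * nCh * nT, sd = config@noiseSd), nTr * nCh, nT)
    phi <- config@arPhi
    if (phi > 0) {
      M[, 1L] <- M[, 1L] / sqrt(1 - phi^2)
      for (t in 2:nT) M[, t] <- phi * M[, t - 1L] + M[, t]
    }
    if (config@alphaAmp > 0) {
      f <- stats::runif(nTr, 8, 12)
      ph <- stats::runif(nTr, 0, 2 * pi)
      alphaMat <- config@alphaAmp *
        sin(outer(f, times) * 2 * pi / 1000 + ph)
      M <- M + alphaMat[rep(seq_len(nTr), nCh), ]
    }
    chOff <- (seq_len(nCh) - 1L) * nTr
    for (cl in 1:4) {
      selId <- which(labels$identity == cl)
      rows <- rep(selId, nCh) + rep(chOff, each = length(selId))
      M[rows, ] <- M[rows, ] + tmplId[[cl]][rep(seq_len(nCh), each = length(selId)), ]
      selEx <- which(labels$expression == cl)
      rows <- rep(selEx, nCh) + rep(chOff, each = length(selEx))
      M[rows, ] <- M[rows, ] + tmplEx[[cl]][rep(seq_len(nCh), each = length(selEx)), ]
      if (config@reactivationGain > 0) {
        selRe <- which(!is.na(prevId) & prevId == cl)
        if (length(selRe)) {
          rows <- rep(selRe, nCh) + rep(chOff, each = length(selRe))
          M[rows, ] <- M[rows, ] + tmplRe[[cl]][rep(seq_len(nCh), each = length(selRe)), ]
        }
      }
    }
    EpochSet(array(M, c(nTr, nCh, nT)), fs = config@fs,
             tStart = config@epochMs[1],
             participantId = participantId, labels = labels)
  })
}

#' Simulate a whole study
#'
#' Draws one topography set per participant (participants differ in their
#' scalp patterns, as in real data) and simulates each participant's epochs
#' from per-participant child seeds of one master seed.
#'
#' @param config a [SynthConfig-class].
#' @param seed master seed.
#' @return List of [EpochSet-class], length \code{nParticipants}.
#' @export
simulateStudy <- function(config, seed) {
  seeds <- deriveSeeds(seed, 2L * config@nParticipants)
  lapply(seq_len(config@nParticipants), function(i) {
    topo <- makeTopographies(config, seeds[2L * i - 1L])
    simulateParticipant(config, topo, seeds[2L * i],
                        participantId = sprintf("sim%02d", i))
  })
}

#' Simulate behavioral memory-test accuracy
#'
#' Per participant, a true accuracy is drawn from a normal distribution
#' (truncated to [0.3, 0.95]) and the identity- and expression-test reports
#' are binomial draws over 40 test trials each, mirroring the 80 memory
#' tests split evenly between the two dimensions.
#'
#' @param config a [SynthConfig-class].
#' @param seed integer seed.
#' @return data.frame with columns \code{participant}, \code{idAcc},
#'   \code{exAcc}.
#' @export
simulateBehavior <- function(config, seed) {
  withSeed(seed, {
    n <- config@nParticipants
    p <- pmin(pmax(stats::rnorm(n, config@behavMean, config@behavSd), 0.3), 0.95)
    data.frame(
      participant = sprintf("sim%02d", seq_len(n)),
      idAcc = stats::rbinom(n, 40, p) / 40,
      exAcc = stats::rbinom(n, 40, p) / 40
    )
  })
}
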