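#' Zero-phase FIR low-pass filter
#'
#' Two-pass (forward-backward) Hamming-windowed sinc FIR low-pass applied
#' per trial and channel. The filter order is about \code{3 * fs / cutoff}
#' (rounded to even), capped so the kernel fits the epoch; edges are handled
#' by odd (anti-symmetric) reflection padding before the two passes, so DC
#' is preserved and no phase shift is introduced. The two passes are applied
#' in the frequency domain as multiplication by the squared magnitude
#' response, which is exactly equivalent to forward-backward convolution
#' with the same kernel.
#'
#' @param epochs an [EpochSet-class].
#' @param cutoffHz low-pass cutoff, Hz; must be below Nyquist.
#' @return A filtered [EpochSet-class] of identical shape.
#' @export
lowpassFilter <- function(epochs, cutoffHz) {
  fs <- samplingRate(epochs)
  if (cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist frequency (fs/2)")
  if (cutoffHz <= 0) stop("cutoff must be positive")
  d <- dim(epochs@data)
  nT <- d[3]
  ord <- 2L * round(3 * fs / cutoffHz / 2)
  maxOrd <- 2L * ((nT - 1L) %/% 2L)
  if (ord > maxOrd) {
    warning("epoch too short for the requested filter order; using order ", maxOrd)
    ord <- maxOrd
  }
  h <- signal::fir1(ord, cutoffHz / (fs / 2), type = "low")
  h <- h / sum(h) # exact unit DC gain
  taps <- length(h)
  # time-first matrix of all (trial, channel) series
  X <- matrix(aperm(epochs@data, c(3, 1, 2)), nT, d[1] * d[2])
  p <- taps
  Xp <- rbind(
    2 * X[rep(1L, p), , drop = FALSE] - X[(p + 1L):2L, , drop = FALSE],
    X,
    2 * X[rep(nT, p), , drop = FALSE] - X[(nT - 1L):(nT - p), , drop = FALSE]
  )
  N <- stats::nextn(nrow(Xp) + taps, c(2, 3, 5))
  H2 <- Mod(stats::fft(c(h, numeric(N - taps))))^2
  out <- matrix(0, nT, ncol(Xp))
  pad <- matrix(0, N - nrow(Xp), min(2048L, ncol(Xp)))
  for (j0 in seq(1L, ncol(Xp), by = 2048L)) {
    jj <- j0:min(j0 + 2047L, ncol(Xp))
    Xf <- stats::mvfft(rbind(Xp[, jj, drop = FALSE],
                             pad[, seq_along(jj), drop = FALSE]))
    Y <- Re(stats::mvfft(Xf * H2, inverse = TRUE)) / N
    out[, jj] <- Y[(p + 1L):(p + nT), , drop = FALSE]
  }
  res <- epochs
  res@data <- aperm(array(out, c(nT, d[1], d[2])), c(2, 3, 1))
  res
}

#' Baseline correction
#'
#' Subtracts, per trial and channel, the mean voltage over the baseline
#' window (half-open in ms, default the 500 ms before stimulus onset).
#'
#' @param epochs an [EpochSet-class].
#' @param window ms interval \code{c(from, to)}; samples with
#'   \code{from <= t < to} form the baseline.
#' @return A baseline-corrected [EpochSet-class].
#' @export
baselineCorrect <- function(epochs, window = c(-500, 0)) {
  tm <- epochTimes(epochs)
  sel <- tm >= window[1] & tm < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  means <- apply(epochs@data[, , sel, drop = FALSE], c(1, 2), mean)
  res <- epochs
  res@data <- epochs@data - as.vector(means) # recycles over the time dim
  res
}

#' Moving-average smoothing of an accuracy series
#'
#' Centered moving average of odd width; at the series edges the window
#' shrinks symmetrically so it never extends past the series (no padding,
#' hence no bias toward zero at the edges). With the 5-point default at a
#' 4-ms sampling step this spans +/- 8 ms.
#'
#' @param series an [AccuracySeries-class] or numeric vector.
#' @param nPoints odd window width (default 5).
#' @return Same type as the input, smoothed, same length.
#' @export
smoothSeries <- function(series, nPoints = 5L) {
  nPoints <- as.integer(nPoints)
  if (nPoints < 1L || nPoints %% 2L == 0L) stop("nPoints must be odd and >= 1")
  if (is(series, "AccuracySeries")) {
    series@values <- runningMean(series@values, nPoints)
    return(series)
  }
  runningMean(series, nPoints)
}

#' Non-overlapping window averaging of the time axis
#'
#' Averages consecutive non-overlapping windows of \code{widthMs}; window i
#' covers \code{[tStart + i*width, tStart + (i+1)*width)}. Used before
#' temporal-generalization decoding: a \code{[-500, 1500)} ms epoch with
#' 100-ms windows yields 20 time points.
#'
#' @param epochs an [EpochSet-class].
#' @param widthMs window width, ms (default 100).
#' @return An [EpochSet-class] whose time axis holds one sample per window
#'   (placed at the window start).
#' @export
windowAverage <- function(epochs, widthMs = 100) {
  fs <- samplingRate(epochs)
  spw <- widthMs * fs / 1000
  if (spw < 1) stop("window width must cover at least one sample period")
  if (abs(spw - round(spw)) > 1e-9)
    stop("window width must be a whole number of samples")
  spw <- as.integer(round(spw))
  d <- dim(epochs@data)
  nWin <- d[3] %/% spw
  if (d[3] %% spw != 0L)
    stop("epoch duration must be divisible by the window width (within one sample)")
  X <- matrix(epochs@data, d[1] * d[2], d[3])
  W <- matrix(0, d[3], nWin)
  W[cbind(seq_len(d[3]), rep(seq_len(nWin), each = spw))] <- 1 / spw
  out <- X %*% W
  res <- epochs
  res@data <- array(out, c(d[1], d[2], nWin))
  res@fs <- fs / spw
  res
}
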