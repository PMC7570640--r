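# Fixed preprocessing chain: 50 Hz notch -> 0.1-100 Hz bandpass ->
# decimation by 10 (1000 -> 100 Hz) -> artifact excision -> skip 60 s,
# take 60 s -> reshape to 60 steps x 63 channels x 100 samples.

.applyFiltfilt <- function(sig, filt) {
  .filtfiltCpp(filt$b, filt$a, sig)
}

#' Zero-phase 50 Hz notch filter
#'
#' Per-channel second-order IIR notch (biquad, quality factor \code{Q}),
#' applied forward-backward so the net phase response is zero. Removes the
#' power-line component while leaving neighbouring frequencies essentially
#' untouched.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param f0 notch frequency, Hz (default 50, the local mains frequency).
#' @param Q quality factor of the biquad (default 30).
#' @return The filtered \linkS4class{RawRecording} (same shape and rate).
#' @export
notchFilter <- function(recording, f0 = 50, Q = 30) {
  fs <- samplingRate(recording)
  if (f0 <= 0 || f0 >= fs / 2)
    stop("notch frequency must lie strictly inside (0, fs/2)")
  w0 <- 2 * pi * f0 / fs
  al <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  out <- recording
  out@signal <- .applyFiltfilt(recording@signal, signal::Arma(b = b, a = a))
  out
}

#' Zero-phase Butterworth bandpass filter
#'
#' Restricts the signal to the physiologically interpreted 0.1-100 Hz
#' range covering the delta through gamma bands. Realised as a cascade of
#' a 2nd-order Butterworth high-pass at \code{low} and a 4th-order
#' low-pass at \code{high}, each applied forward-backward (zero phase): a
#' single transfer-function bandpass with a 0.1 Hz edge at 1000 Hz places
#' poles so close to the unit circle that its direct-form coefficients are
#' numerically ill-conditioned, while the cascade is exact to machine
#' precision and has the same passband.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param low,high band edges, Hz (defaults 0.1 and 100).
#' @param orderLow,orderHigh orders of the high-pass (at \code{low}) and
#'   low-pass (at \code{high}) stages; defaults 2 and 4.
#' @return The filtered \linkS4class{RawRecording}.
#' @export
bandpassFilter <- function(recording, low = 0.1, high = 100, orderLow = 2,
                           orderHigh = 4) {
  fs <- samplingRate(recording)
  if (low <= 0 || high <= low || high >= fs / 2)
    stop("band edges must satisfy 0 < low < high < fs/2")
  hp <- signal::butter(orderLow, low / (fs / 2), type = "high")
  lp <- signal::butter(orderHigh, high / (fs / 2), type = "low")
  out <- recording
  out@signal <- .applyFiltfilt(.applyFiltfilt(recording@signal, hp), lp)
  out
}

#' Decimate a recording
#'
#' Literal decimation \eqn{x_i[n] = d_i[Dn]}: every D-th sample is kept
#' starting at the first, and the sampling rate drops to \code{fs / D}. No
#' anti-alias filter is applied by default (the chain's bandpass has
#' already removed content above 100 Hz, but 50-100 Hz content does alias
#' at the new 50 Hz Nyquist); set \code{antiAlias = TRUE} for an optional
#' 45 Hz zero-phase low-pass beforehand.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param D positive integer decimation factor (default 10).
#' @param antiAlias apply a 45 Hz low-pass before decimating (default off).
#' @return The decimated \linkS4class{RawRecording} with \code{fs/D}.
#' @export
downsampleRecording <- function(recording, D = 10, antiAlias = FALSE) {
  if (length(D) != 1 || !is.finite(D) || D < 1 || D != round(D))
    stop("D must be a positive integer")
  D <- as.integer(D)
  out <- recording
  if (antiAlias && D > 1) {
    fs <- samplingRate(recording)
    lp <- signal::butter(4, min(45, 0.9 * fs / (2 * D)) / (fs / 2),
                         type = "low")
    out@signal <- .applyFiltfilt(out@signal, lp)
  }
  out@signal <- out@signal[, seq(1, ncol(out@signal), by = D), drop = FALSE]
  out@fs <- recording@fs / D
  out
}

#' Automatic amplitude-threshold artifact detector
#'
#' Replaces manual visual inspection with a reproducible rule: a time point
#' is flagged when any channel deviates from its median by more than
#' \code{threshold} robust standard deviations (1.4826 x median absolute
#' deviation); flagged points are padded by \code{pad} seconds on each side
#' and merged into intervals.
#'
#' @param recording a \linkS4class{RawRecording} (typically post-decimation).
#' @param threshold robust-SD multiplier (default 5).
#' @param pad padding added around flagged points, seconds (default 0.25).
#' @return An \linkS4class{ArtifactMask} on the recording's time axis.
#' @export
detectArtifacts <- function(recording, threshold = 5, pad = 0.25) {
  sig <- eegSignal(recording)
  fs <- samplingRate(recording)
  med <- apply(sig, 1, stats::median)
  rsd <- apply(sig, 1, stats::mad)
  rsd[rsd == 0] <- Inf  # flat channels never flag
  flag <- colSums(abs(sig - med) > threshold * rsd) > 0
  if (!any(flag)) return(artifactMask())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  iv <- cbind((starts[keep] - 1) / fs - pad, ends[keep] / fs + pad)
  iv[, 1] <- pmax(iv[, 1], 0)
  iv[, 2] <- pmin(iv[, 2], ncol(sig) / fs)
  # merge overlaps after padding
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    if (iv[k, 1] <= merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], iv[k, 2])
    else merged <- rbind(merged, iv[k, ])
  }
  artifactMask(merged[, 1], merged[, 2])
}

#' Excise masked segments from a recording
#'
#' Removes the half-open intervals of \code{mask} (seconds) from the
#' recording and concatenates the remaining segments in time order; the
#' duration shrinks by the total masked length.
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param mask an \linkS4class{ArtifactMask} within the recording bounds.
#' @return The shortened \linkS4class{RawRecording}.
#' @export
removeArtifactSegments <- function(recording, mask) {
  iv <- maskIntervals(mask)
  out <- recording
  if (nrow(iv) == 0) return(out)
  fs <- samplingRate(recording)
  dur <- ncol(eegSignal(recording)) / fs
  if (any(iv[, 2] > dur + 1e-9))
    stop("mask extends beyond the recording (", dur, " s)")
  tt <- (seq_len(ncol(recording@signal)) - 1) / fs
  drop <- rep(FALSE, length(tt))
  for (k in seq_len(nrow(iv)))
    drop <- drop | (tt >= iv[k, 1] & tt < iv[k, 2])
  out@signal <- recording@signal[, !drop, drop = FALSE]
  out
}

#' Extract the analysis window as a step sequence
#'
#' Discards the first \code{skip} seconds (early-recording artifacts,
#' subject settling) and takes the following \code{take} seconds, reshaped
#' into one-second steps: with the canonical 100 Hz input this yields the
#' 63 x 6000 matrix as a 60 steps x 63 channels x 100 samples array.
#'
#' @param recording a \linkS4class{RawRecording} (canonically at 100 Hz).
#' @param skip,take seconds to skip and to keep (defaults 60 and 60).
#' @return A \linkS4class{StepSequence}.
#' @export
extractWindow <- function(recording, skip = 60, take = 60) {
  fs <- samplingRate(recording)
  sig <- eegSignal(recording)
  perStep <- round(fs)
  need <- round((skip + take) * fs)
  if (ncol(sig) < need)
    stop(sprintf(
      "recording too short: %.1f s available, %.1f s required (deficit %.1f s)",
      ncol(sig) / fs, skip + take, (need - ncol(sig)) / fs))
  idx <- (round(skip * fs) + 1):need
  win <- sig[, idx, drop = FALSE]
  nstep <- as.integer(take)
  dat <- array(0, c(nstep, nrow(win), perStep))
  for (k in seq_len(nstep))
    dat[k, , ] <- win[, ((k - 1) * perStep + 1):(k * perStep)]
  stepSequence(dat, label = classLabel(recording),
               id = recordingId(recording))
}

#' Full preprocessing chain
#'
#' Applies, in order: 50 Hz notch, 0.1-100 Hz bandpass, decimation by
#' \code{D} (1000 to 100 Hz), artifact excision (automatic detector unless
#' a mask is supplied), and the skip-60 s / take-60 s window extraction.
#' With \code{raw = TRUE} the filtering and excision stages are skipped and
#' only decimation plus windowing are applied (the "raw EEG" ablation arm,
#' which must still meet the LSTM's input shape contract).
#'
#' @param recording a \linkS4class{RawRecording} at 1000 Hz.
#' @param mask optional \linkS4class{ArtifactMask} (post-decimation time
#'   axis); when \code{NULL} and \code{autoArtifacts} is on, the automatic
#'   detector supplies it.
#' @param autoArtifacts run \code{\link{detectArtifacts}} when no mask is
#'   given (default on).
#' @param D decimation factor (default 10).
#' @param skip,take window parameters in seconds (defaults 60/60).
#' @param raw skip filtering and excision (ablation arm).
#' @param antiAlias optional anti-alias low-pass before decimation.
#' @return A \linkS4class{StepSequence}, canonically 60 x 63 x 100.
#' @export
#' @examples
#' rec <- simulateRecording("healthy", simConfig(), seed = 1)
#' seqc <- preprocessRecording(rec)
#' dim(stepData(seqc))
preprocessRecording <- function(recording, mask = NULL,
                                autoArtifacts = TRUE, D = 10, skip = 60,
                                take = 60, raw = FALSE, antiAlias = FALSE) {
  x <- recording
  if (!raw) {
    x <- notchFilter(x)
    x <- bandpassFilter(x)
  }
  x <- downsampleRecording(x, D = D, antiAlias = antiAlias)
  if (!raw) {
    if (is.null(mask) && autoArtifacts) mask <- detectArtifacts(x)
    if (!is.null(mask)) x <- removeArtifactSegments(x, mask)
  }
  extractWindow(x, skip = skip, take = take)
}

#' Preprocess a list of recordings
#'
#' @param recordings list of \linkS4class{RawRecording}s.
#' @param ... passed to \code{\link{preprocessRecording}}.
#' @return List of \linkS4class{StepSequence}s.
#' @export
preprocessDataset <- function(recordings, ...) {
  lapply(recordings, preprocessRecording, ...)
}
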