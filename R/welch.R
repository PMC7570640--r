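#' Welch power spectral density estimate
#'
#' Averaged modified periodogram (Hann window, 50\% overlap) of a single
#' channel. Used by the package's own tests and by band-power summaries of
#' simulated recordings; kept deliberately minimal.
#'
#' @param x numeric vector.
#' @param fs sampling rate, Hz.
#' @param nperseg segment length in samples (default \code{4 * fs},
#'   truncated to the signal length).
#' @return List with \code{freq} (Hz) and \code{psd} (power per Hz, one-sided).
#' @export
#' @examples
#' p <- welchPsd(sin(2 * pi * 10 * seq(0, 10, by = 0.01)), fs = 100)
#' p$freq[which.max(p$psd)]
welchPsd <- function(x, fs, nperseg = min(length(x), 4 * fs)) {
  n <- length(x)
  nperseg <- min(nperseg, n)
  step <- max(1, floor(nperseg / 2))
  starts <- seq(1, n - nperseg + 1, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  nf <- floor(nperseg / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * u)
  }
  psd <- acc / length(starts)
  # one-sided: double all bins except DC (and Nyquist for even lengths)
  inner <- 2:(nf - if (nperseg %% 2 == 0) 1 else 0)
  psd[inner] <- 2 * psd[inner]
  list(freq = (seq_len(nf) - 1) * fs / nperseg, psd = psd)
}

#' Band power from a Welch estimate
#'
#' Integrates the Welch PSD of each channel over \code{[low, high)} Hz and
#' returns the per-channel band power (\eqn{\mu V^2}).
#'
#' @param recording a \linkS4class{RawRecording}.
#' @param low,high band edges, Hz.
#' @param nperseg Welch segment length (samples).
#' @return Numeric vector, one power per channel.
#' @export
bandPower <- function(recording, low, high,
                      nperseg = min(ncol(eegSignal(recording)),
                                    4 * samplingRate(recording))) {
  sig <- eegSignal(recording)
  fs <- samplingRate(recording)
  apply(sig, 1, function(ch) {
    p <- welchPsd(ch, fs, nperseg)
    sel <- p$freq >= low & p$freq < high
    sum(p$psd[sel]) * (p$freq[2] - p$freq[1])
  })
}
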