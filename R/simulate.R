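# Synthetic resting-state EEG with class-dependent alpha/theta structure.
#
# Each channel is synthesised in the frequency domain: complex Gaussian
# coefficients shaped per component, normalised exactly (Parseval) to the
# requested RMS amplitude, then one inverse FFT per channel. Oscillatory
# bands are therefore narrowband-filtered Gaussian noise, not pure tones.

.defaultBands <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1,  4,  8, 13, 30),
    high = c(4,  8, 13, 30, 45),
    amp  = c(10, 8, 20,  5,  2))  # baseline RMS amplitude, microvolts
}

#' Simulation configuration for synthetic resting-state EEG
#'
#' Defines the study conditions the generator emulates: 12 recordings per
#' class, 63 channels at 1000 Hz, 140 s duration, band-limited oscillations
#' over a 1/f background, 50 Hz line contamination and Poisson-placed
#' high-amplitude artifact bursts. Traumatic brain injury is expressed as
#' attenuated alpha and amplified theta activity, graded with severity;
#' all other bands are shared across classes.
#'
#' @param nPerClass recordings per class (default 12, i.e. 36 in total).
#' @param fs sampling rate, Hz (default 1000).
#' @param duration recording length, seconds (default 140; at least 121 s
#'   is needed downstream for the skip-60 s / take-60 s window).
#' @param bandPowers data frame with columns \code{band}, \code{low},
#'   \code{high} (Hz) and \code{amp} (baseline RMS amplitude, microvolts);
#'   bands must be disjoint sub-intervals of [0.1, 100] Hz.
#' @param alphaAttenuation named multipliers in [0, 1] applied to the alpha
#'   amplitude of the TBI classes; moderate must be attenuated at least as
#'   much as mild. Default \code{c(mild = 0.7, moderate = 0.5)}.
#' @param thetaGain named multipliers >= 1 on the theta amplitude of the
#'   TBI classes, moderate >= mild. Default \code{c(mild = 1.5, moderate = 2)}.
#' @param lineNoiseAmp 50 Hz line-noise sinusoid amplitude, microvolts peak.
#' @param artifactRate expected number of artifact bursts per recording
#'   (Poisson); bursts are 0.5-2 s of added noise at 5x the channel RMS.
#' @param noiseExponent spectral slope beta of the 1/f^beta background.
#' @param noiseAmp background noise RMS amplitude, microvolts.
#' @param seed integer seed from which per-recording seeds are derived.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
#' @examples
#' cfg <- simConfig(nPerClass = 2, duration = 20)
simConfig <- function(nPerClass = 12, fs = 1000, duration = 140,
                      bandPowers = .defaultBands(),
                      alphaAttenuation = c(mild = 0.7, moderate = 0.5),
                      thetaGain = c(mild = 1.5, moderate = 2.0),
                      lineNoiseAmp = 5, artifactRate = 3,
                      noiseExponent = 1, noiseAmp = 5, seed = 1L) {
  cfg <- structure(list(
    nPerClass = as.integer(nPerClass), fs = fs, duration = duration,
    bandPowers = bandPowers, alphaAttenuation = alphaAttenuation,
    thetaGain = thetaGain, lineNoiseAmp = lineNoiseAmp,
    artifactRate = artifactRate, noiseExponent = noiseExponent,
    noiseAmp = noiseAmp, seed = as.integer(seed)),
    class = "SimulationConfig")
  validateSimConfig(cfg)
  cfg
}

#' Validate a SimulationConfig
#'
#' Checks the structural invariants: positive sizes, attenuation in
#' [0, 1] graded with severity, theta gain >= 1 graded with severity, and
#' disjoint frequency bands inside [0.1, 100] Hz.
#'
#' @param cfg a \code{SimulationConfig}.
#' @return Invisibly \code{TRUE}; stops on violation.
#' @export
validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (cfg$nPerClass < 1 || cfg$fs <= 0 || cfg$duration <= 0)
    stop("nPerClass, fs and duration must be positive")
  aa <- cfg$alphaAttenuation
  tg <- cfg$thetaGain
  if (!all(c("mild", "moderate") %in% names(aa)) ||
      !all(c("mild", "moderate") %in% names(tg)))
    stop("alphaAttenuation and thetaGain need 'mild' and 'moderate' entries")
  if (any(aa < 0 | aa > 1)) stop("alphaAttenuation must lie in [0, 1]")
  if (aa[["moderate"]] > aa[["mild"]])
    stop("moderate alpha attenuation must be at least as strong as mild")
  if (any(tg < 1)) stop("thetaGain must be >= 1")
  if (tg[["moderate"]] < tg[["mild"]])
    stop("moderate theta gain must be at least the mild gain")
  bp <- cfg$bandPowers
  if (!all(c("band", "low", "high", "amp") %in% names(bp)))
    stop("bandPowers needs columns band, low, high, amp")
  bp <- bp[order(bp$low), ]
  if (any(bp$low < 0.1) || any(bp$high > 100) || any(bp$low >= bp$high))
    stop("bands must be sub-intervals of [0.1, 100] Hz")
  if (nrow(bp) > 1 && any(bp$low[-1] < bp$high[-nrow(bp)]))
    stop("bands must be disjoint")
  if (cfg$lineNoiseAmp < 0 || cfg$artifactRate < 0 || cfg$noiseAmp < 0)
    stop("amplitudes and rates must be non-negative")
  invisible(TRUE)
}

# Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

# Complex-Gaussian spectrum over frequency selector `sel` (indices into
# positive-frequency bins), normalised so the time-domain RMS equals `amp`.
.shapedComponent <- function(spec, sel, shape, amp, n) {
  if (!length(sel) || amp <= 0) return(spec)
  g <- complex(real = stats::rnorm(length(sel)),
               imaginary = stats::rnorm(length(sel))) * shape
  # two-sided energy: RMS^2 = 2 * sum(|g|^2) / n^2
  ss <- sqrt(2 * sum(Mod(g)^2) / n^2)
  spec[sel] <- spec[sel] + g * (amp / ss)
  spec
}

#' Simulate one synthetic resting-state EEG recording
#'
#' Generates a 63-channel recording of \code{duration * fs} samples as the
#' sum of (i) band-limited Gaussian oscillations with per-band RMS
#' amplitudes, alpha and theta modulated by class, (ii) 1/f^beta background
#' noise, (iii) a 50 Hz line-noise sinusoid, and (iv) Poisson-placed
#' high-amplitude artifact bursts whose ground-truth intervals are stored
#' with the recording. Deterministic given \code{(classLabel, config, seed)}.
#'
#' @param classLabel \code{"healthy"}, \code{"mild"} or \code{"moderate"}.
#' @param config a \code{\link{simConfig}}.
#' @param seed integer seed for this recording.
#' @param id recording identifier.
#' @return A \linkS4class{RawRecording} with the ground-truth artifact log
#'   in its \code{artifacts} slot.
#' @export
#' @examples
#' rec <- simulateRecording("healthy", simConfig(duration = 10), seed = 7)
simulateRecording <- function(classLabel, config = simConfig(), seed,
                              id = paste0(classLabel, "_", seed)) {
  validateSimConfig(config)
  classLabel <- match.arg(classLabel, .classLevels)
  if (config$duration < 121)
    warning("duration below 121 s: preprocessing will reject this recording")
  fs <- config$fs
  n <- round(config$duration * fs)
  nchan <- 63
  freqs <- (seq_len(floor(n / 2) - 1)) * fs / n  # positive bins, no DC/Nyquist
  posIdx <- seq_len(floor(n / 2) - 1) + 1        # 1-based indices into spectrum

  bp <- config$bandPowers
  amps <- bp$amp
  names(amps) <- bp$band
  if (classLabel != "healthy") {
    if ("alpha" %in% bp$band)
      amps[["alpha"]] <- amps[["alpha"]] * config$alphaAttenuation[[classLabel]]
    if ("theta" %in% bp$band)
      amps[["theta"]] <- amps[["theta"]] * config$thetaGain[[classLabel]]
  }

  bgSel <- which(freqs >= 0.1 & freqs < fs / 2)
  bandSel <- lapply(seq_len(nrow(bp)), function(j)
    which(freqs >= bp$low[j] & freqs < bp$high[j]))

  .withSeed(seed, {
    sig <- matrix(0, nchan, n)
    tt <- (seq_len(n) - 1) / fs
    for (ch in seq_len(nchan)) {
      spec <- complex(n)
      spec <- .shapedComponent(spec, posIdx[bgSel],
                               freqs[bgSel]^(-config$noiseExponent / 2),
                               config$noiseAmp, n)
      for (j in seq_len(nrow(bp)))
        spec <- .shapedComponent(spec, posIdx[bandSel[[j]]],
                                 rep(1, length(bandSel[[j]])),
                                 amps[[bp$band[j]]], n)
      # hermitian mirror so the inverse transform is real
      spec[n + 2 - posIdx] <- Conj(spec[posIdx])
      x <- Re(stats::fft(spec, inverse = TRUE)) / n
      phase <- stats::runif(1, 0, 2 * pi)
      sig[ch, ] <- x + config$lineNoiseAmp * sin(2 * pi * 50 * tt + phase)
    }

    nArt <- stats::rpois(1, config$artifactRate)
    arts <- data.frame(start = numeric(0), end = numeric(0))
    if (nArt > 0) {
      lens <- stats::runif(nArt, 0.5, 2)
      starts <- stats::runif(nArt, 0, pmax(config$duration - lens, 0))
      chRms <- sqrt(rowMeans(sig^2))
      for (a in seq_len(nArt)) {
        i0 <- floor(starts[a] * fs) + 1
        i1 <- min(n, floor((starts[a] + lens[a]) * fs))
        idx <- i0:i1
        sig[, idx] <- sig[, idx] +
          matrix(stats::rnorm(nchan * length(idx)), nchan) * (5 * chRms)
      }
      arts <- data.frame(start = starts, end = starts + lens)
      arts <- arts[order(arts$start), ]
      rownames(arts) <- NULL
    }
    rawRecording(sig, fs = fs, channelNames = montage1010(),
                 label = classLabel, id = id, artifacts = arts)
  })
}

#' Simulate a balanced labelled dataset
#'
#' Generates \code{3 * nPerClass} recordings (default 36: 12 healthy, 12
#' mild TBI, 12 moderate TBI) with per-recording seeds derived
#' deterministically from \code{config$seed}.
#'
#' @param config a \code{\link{simConfig}}.
#' @return List of \linkS4class{RawRecording}s with balanced labels.
#' @export
simulateDataset <- function(config = simConfig()) {
  validateSimConfig(config)
  plan <- datasetPlan(config)
  lapply(seq_len(nrow(plan)), function(i)
    simulateRecording(plan$label[i], config, seed = plan$seed[i],
                      id = plan$id[i]))
}

#' Per-recording simulation plan
#'
#' The labels, derived seeds and identifiers \code{\link{simulateDataset}}
#' would use; exposed so pipelines can simulate recordings one at a time
#' (memory-friendly streaming) while remaining bitwise-identical to the
#' list version.
#'
#' @param config a \code{\link{simConfig}}.
#' @return Data frame with columns \code{label}, \code{seed}, \code{id}.
#' @export
datasetPlan <- function(config = simConfig()) {
  n <- 3L * config$nPerClass
  seeds <- .withSeed(config$seed, sample.int(.Machine$integer.max - 1, n))
  labels <- rep(.classLevels, each = config$nPerClass)
  data.frame(label = labels, seed = seeds,
             id = sprintf("%s_%02d", labels,
                          rep(seq_len(config$nPerClass), times = 3)))
}
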