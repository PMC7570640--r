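test_that("simulation config enforces its invariants", {
  expect_silent(validateSimConfig(simConfig()))
  expect_error(simConfig(nPerClass = 0), "positive")
  expect_error(simConfig(alphaAttenuation = c(mild = 1.2, moderate = 0.5)),
               "\\[0, 1\\]")
  expect_error(simConfig(alphaAttenuation = c(mild = 0.5, moderate = 0.7)),
               "at least as strong")
  expect_error(simConfig(thetaGain = c(mild = 0.8, moderate = 2)), ">= 1")
  expect_error(simConfig(thetaGain = c(mild = 2, moderate = 1.5)),
               "at least the mild")
  overlap <- data.frame(band = c("a", "b"), low = c(4, 6), high = c(8, 10),
                        amp = c(1, 1))
  expect_error(simConfig(bandPowers = overlap), "disjoint")
  outside <- data.frame(band = "x", low = 0.01, high = 5, amp = 1)
  expect_error(simConfig(bandPowers = outside), "sub-intervals")
})

test_that("recordings are deterministic, labelled and montage-complete", {
  cfg <- simConfig(duration = 10)
  r1 <- suppressWarnings(simulateRecording("mild", cfg, seed = 3))
  r2 <- suppressWarnings(simulateRecording("mild", cfg, seed = 3))
  expect_identical(eegSignal(r1), eegSignal(r2))
  expect_identical(classLabel(r1), "mild")
  expect_identical(channelNames(r1), montage1010())
  expect_length(channelNames(r1), 63)
  expect_false("CPz" %in% channelNames(r1))
  expect_equal(dim(eegSignal(r1)), c(63, 10 * 1000))
  expect_error(suppressWarnings(simulateRecording("severe", cfg, seed = 1)))
  expect_warning(simulateRecording("mild", simConfig(duration = 50), seed = 1),
                 "121")
})

test_that("the healthy spectrum peaks in the alpha band", {
  rec <- fixtureRecording()
  p <- welchPsd(eegSignal(rec)[10, ], samplingRate(rec))
  sel <- p$freq >= 2 & p$freq <= 40
  peak <- p$freq[sel][which.max(p$psd[sel])]
  expect_gte(peak, 8)
  expect_lt(peak, 13)
})

test_that("alpha attenuation scales alpha power quadratically", {
  cfg <- simConfig(alphaAttenuation = c(mild = 0.7, moderate = 0.5),
                   artifactRate = 0)
  h <- simulateRecording("healthy", cfg, seed = 7)
  m <- simulateRecording("moderate", cfg, seed = 7)
  ratio <- mean(bandPower(m, 8, 13)) / mean(bandPower(h, 8, 13))
  # amplitude halved => band power quartered (plus shared background)
  expect_gt(ratio, 0.2)
  expect_lt(ratio, 0.35)
})

test_that("50 Hz line noise stands out against neighbouring bins", {
  rec <- simulateRecording(
    "healthy", simConfig(lineNoiseAmp = 10, artifactRate = 0), seed = 1)
  # independent periodogram: direct FFT of one channel
  x <- eegSignal(rec)[1, ]
  n <- length(x)
  f <- (seq_len(n) - 1) * samplingRate(rec) / n
  pw <- Mod(stats::fft(x))^2
  p50 <- pw[which.min(abs(f - 50))]
  p47 <- pw[which.min(abs(f - 47))]
  expect_gt(p50 / p47, 10)
})

test_that("datasets are balanced with derived per-recording seeds", {
  cfg <- simConfig(nPerClass = 2, duration = 5)
  ds <- suppressWarnings(simulateDataset(cfg))
  expect_length(ds, 6)
  labs <- vapply(ds, classLabel, character(1))
  expect_equal(as.integer(table(labs)[tbiClasses()]), rep(2L, 3))
  ds2 <- suppressWarnings(simulateDataset(cfg))
  expect_identical(lapply(ds, eegSignal), lapply(ds2, eegSignal))
  plan <- datasetPlan(simConfig())
  expect_equal(nrow(plan), 36)
  expect_equal(sum(plan$label == "mild"), 12)
})

test_that("alpha-band power is strictly ordered across classes", {
  cfg <- simConfig(duration = 30, artifactRate = 0)
  pow <- sapply(tbiClasses(), function(cl)
    sapply(1:7, function(s) mean(bandPower(
      suppressWarnings(simulateRecording(cl, cfg, seed = 100 + s)), 8, 13))))
  expect_true(all(pow[, "healthy"] > pow[, "mild"]))
  expect_true(all(pow[, "mild"] > pow[, "moderate"]))
})

test_that("injected artifact bursts exceed the detector threshold", {
  cfg <- simConfig(artifactRate = 3)
  for (s in 1:3) {
    rec <- simulateRecording("healthy", cfg, seed = 40 + s)
    truth <- rec@artifacts
    if (nrow(truth) == 0) next
    mask <- detectArtifacts(downsampleRecording(
      bandpassFilter(notchFilter(rec))))
    iv <- maskIntervals(mask)
    centers <- (truth$start + truth$end) / 2
    covered <- vapply(centers, function(ct)
      any(iv[, 1] <= ct & iv[, 2] >= ct), logical(1))
    expect_true(all(covered))
  }
})
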