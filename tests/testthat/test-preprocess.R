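rms <- function(x) sqrt(mean(x^2))

test_that("the notch filter removes 50 Hz and spares the EEG bands", {
  fs <- 1000
  tt <- seq(0, 10, by = 1 / fs)
  r50 <- rawRecording(matrix(sin(2 * pi * 50 * tt), 1), fs = fs)
  expect_lt(rms(eegSignal(notchFilter(r50))) / rms(eegSignal(r50)), 0.05)
  r10 <- rawRecording(matrix(sin(2 * pi * 10 * tt), 1), fs = fs)
  expect_equal(rms(eegSignal(notchFilter(r10))) / rms(eegSignal(r10)), 1,
               tolerance = 0.02)
  z <- rawRecording(matrix(0, 2, 1000), fs = fs)
  expect_equal(eegSignal(notchFilter(z)), matrix(0, 2, 1000))
  expect_error(notchFilter(rawRecording(matrix(0, 1, 10), fs = 80), f0 = 50),
               "Nyquist|inside")
})

test_that("the bandpass passes 20 Hz and suppresses slow drift", {
  fs <- 1000
  tt <- seq(0, 20, by = 1 / fs)
  r20 <- rawRecording(matrix(sin(2 * pi * 20 * tt), 1), fs = fs)
  expect_equal(rms(eegSignal(bandpassFilter(r20))) / rms(eegSignal(r20)), 1,
               tolerance = 0.02)
  drift <- rawRecording(matrix(sin(2 * pi * 0.01 * tt), 1), fs = fs)
  expect_lt(rms(eegSignal(bandpassFilter(drift))) / rms(eegSignal(drift)),
            0.1)
  z <- rawRecording(matrix(0, 1, 2000), fs = fs)
  expect_equal(eegSignal(bandpassFilter(z)), matrix(0, 1, 2000))
  expect_error(bandpassFilter(rawRecording(matrix(0, 1, 10), fs = 100),
                              low = 0.1, high = 60))
})

test_that("decimation equals the keep-every-Dth-sample index formula", {
  ramp <- rawRecording(matrix(0:99, 1), fs = 1000)
  d <- downsampleRecording(ramp, 10)
  expect_equal(eegSignal(d)[1, ], 10 * (0:9))
  expect_equal(samplingRate(d), 100)
  set.seed(5)
  for (D in c(1, 2, 3, 7)) {
    x <- matrix(rnorm(3 * 60), 3)
    rec <- rawRecording(x, fs = 60)
    got <- eegSignal(downsampleRecording(rec, D))
    expect_identical(got, x[, seq(1, 60, by = D), drop = FALSE])
  }
  expect_identical(eegSignal(downsampleRecording(ramp, 1)), eegSignal(ramp))
  expect_error(downsampleRecording(ramp, 2.5), "integer")
  expect_error(downsampleRecording(ramp, 0), "integer")
  big <- rawRecording(matrix(0, 1, 140000), fs = 1000)
  dd <- downsampleRecording(big, 10)
  expect_equal(ncol(eegSignal(dd)), 14000)
  expect_equal(samplingRate(dd), 100)
})

test_that("artifact excision removes masked time and keeps order", {
  rec <- rawRecording(matrix(seq_len(1300) - 1, 1), fs = 10)  # 130 s ramp
  expect_identical(eegSignal(removeArtifactSegments(rec, artifactMask())),
                   eegSignal(rec))
  m <- artifactMask(50, 52)
  out <- removeArtifactSegments(rec, m)
  expect_equal(ncol(eegSignal(out)), 1280)  # 128 s left
  # remaining samples concatenated in time order
  expect_equal(eegSignal(out)[1, ], setdiff(0:1299, 500:519))
  expect_error(removeArtifactSegments(rec, artifactMask(125, 135)),
               "beyond")
  expect_error(artifactMask(c(1, 2), c(3, 4)), "non-overlapping")
})

test_that("auto-detection recovers injected bursts", {
  rec <- fixtureRecording()
  truth <- rec@artifacts
  expect_gt(nrow(truth), 0)  # seed 7 draws two bursts
  down <- downsampleRecording(bandpassFilter(notchFilter(rec)), 10)
  mask <- detectArtifacts(down)
  iv <- maskIntervals(mask)
  expect_gte(nrow(iv), nrow(truth))
  centers <- (truth$start + truth$end) / 2
  expect_true(all(vapply(centers, function(ct)
    any(iv[, 1] <= ct & iv[, 2] >= ct), logical(1))))
})

test_that("window extraction yields the canonical 60 x 63 x 100 shape", {
  sig <- matrix(rnorm(63 * 13000), 63)  # 130 s at 100 Hz
  rec <- rawRecording(sig, fs = 100, label = "mild")
  sq <- extractWindow(rec)
  expect_equal(dim(stepData(sq)), c(60, 63, 100))
  expect_equal(classLabel(sq), "mild")
  # step k equals raw samples [6000 + 100(k-1), 6000 + 100k) per channel
  for (k in c(1, 17, 60))
    expect_equal(matrix(stepData(sq)[k, , ], 63, 100),
                 sig[, (6000 + 100 * (k - 1) + 1):(6000 + 100 * k)])
  # flattening the steps reproduces the 63 x 6000 matrix
  expect_equal(asStepMatrix(sq), sig[, 6001:12000])
  short <- rawRecording(matrix(0, 63, 11900), fs = 100)  # 119 s
  expect_error(extractWindow(short), "deficit")
})

test_that("the full chain is shape-stable, deterministic and linear", {
  cfg <- simConfig(duration = 125, artifactRate = 0, lineNoiseAmp = 8)
  rec <- simulateRecording("healthy", cfg, seed = 9)
  s1 <- preprocessRecording(rec)
  expect_equal(dim(stepData(s1)), c(60, 63, 100))
  s2 <- preprocessRecording(rec)
  expect_identical(stepData(s1), stepData(s2))
  # filtering stages are linear: preprocess(a x) = a preprocess(x)
  rec3 <- rec
  rec3@signal <- 3 * rec3@signal
  s3 <- preprocessRecording(rec3, autoArtifacts = FALSE)
  s1b <- preprocessRecording(rec, autoArtifacts = FALSE)
  expect_equal(stepData(s3), 3 * stepData(s1b), tolerance = 1e-10)
  # 50 Hz periodogram power reduced >= 95% by the chain's notch
  x <- eegSignal(rec)[1, ]
  post <- eegSignal(notchFilter(rec))[1, ]
  f <- (seq_along(x) - 1) * 1000 / length(x)
  i50 <- which.min(abs(f - 50))
  p0 <- Mod(stats::fft(x))^2
  p1 <- Mod(stats::fft(post))^2
  expect_lt(p1[i50] / p0[i50], 0.05)
})

test_that("the raw ablation arm skips filtering but keeps the contract", {
  cfg <- simConfig(duration = 125, artifactRate = 0)
  rec <- simulateRecording("moderate", cfg, seed = 4)
  sq <- preprocessRecording(rec, raw = TRUE)
  expect_equal(dim(stepData(sq)), c(60, 63, 100))
  # raw arm output equals plain decimation + window
  direct <- extractWindow(downsampleRecording(rec, 10))
  expect_identical(stepData(sq), stepData(direct))
})
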