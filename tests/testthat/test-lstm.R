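test_that("initialisation is seeded, orthogonal and forget-biased", {
  m1 <- initLSTM(8, 20, seed = 1)
  m2 <- initLSTM(8, 20, seed = 1)
  expect_identical(m1@W, m2@W)
  expect_identical(m1@R, m2@R)
  # each recurrent gate block is orthogonal
  for (g in 0:3) {
    Rg <- m1@R[(g * 8 + 1):((g + 1) * 8), ]
    expect_lt(max(abs(crossprod(Rg) - diag(8))), 1e-6)
  }
  expect_equal(m1@b, c(rep(1, 8), rep(0, 24)))
  expect_error(initLSTM(0, 20), "positive")
})

test_that("the forward pass matches a hand-unrolled recurrence", {
  set.seed(42)
  H <- 3; D <- 4; Tn <- 2
  m <- initLSTM(H, D, seed = 1)
  dat <- array(rnorm(Tn * 1 * D), c(Tn, 1, D))
  sq <- stepSequence(dat, label = "healthy")
  out <- lstmForward(m, sq)
  sig <- function(x) 1 / (1 + exp(-x))
  h <- rep(0, H); cc <- rep(0, H)
  for (t in 1:Tn) {
    x <- as.vector(matrix(dat[t, , ], 1, D))
    z <- m@W %*% x + m@R %*% h + m@b
    f <- sig(z[1:H]); i <- sig(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sig(z[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
  }
  expect_equal(out$states[Tn, ], h, tolerance = 1e-12)
  expect_equal(unname(out$scores), as.numeric(m@Wy %*% h + m@by),
               tolerance = 1e-12)
})

test_that("degenerate parameter regimes behave as the equations demand", {
  H <- 4; D <- 6
  m <- initLSTM(H, D, seed = 2)
  # all-zero parameters => hidden states identically zero
  m0 <- m
  m0@W[] <- 0; m0@R[] <- 0; m0@b[] <- 0
  sq <- stepSequence(array(rnorm(5 * 2 * 3), c(5, 2, 3)))
  out <- lstmForward(m0, sq)
  expect_true(all(out$states == 0))
  # saturated forget gate with silenced input gate freezes the cell at 0
  msat <- m
  msat@b[1:H] <- 50                    # forget ~ 1
  msat@b[(H + 1):(2 * H)] <- -50       # input ~ 0
  msat@W[seq_len(2 * H), ] <- 0
  msat@R[seq_len(2 * H), ] <- 0
  outs <- lstmForward(msat, sq)
  expect_lt(max(abs(outs$states)), 1e-10)
  # hidden states are bounded by construction
  outr <- lstmForward(m, sq)
  expect_true(all(abs(outr$states) < 1))
  # shape mismatch errors
  expect_error(lstmForward(m, stepSequence(array(0, c(5, 2, 4)))),
               "match")
})

test_that("the loss has its closed forms and L2 additivity", {
  expect_equal(computeLoss(c(0, 0, 0), 1), log(3), tolerance = 1e-12)
  expect_equal(computeLoss(c(10, 0, 0), 1),
               -log(exp(10) / (exp(10) + 2)), tolerance = 1e-10)
  expect_lt(computeLoss(c(10, 0, 0), 1), 1e-4)
  m <- initLSTM(3, 4, seed = 1)
  base <- computeLoss(c(1, 2, 0), "mild", m, l2 = 0)
  pen <- computeLoss(c(1, 2, 0), "mild", m, l2 = 0.1)
  expect_equal(pen - base,
               0.1 * 0.5 * (sum(m@W^2) + sum(m@R^2) + sum(m@Wy^2)),
               tolerance = 1e-10)
})

test_that("analytic BPTT gradients match central differences", {
  set.seed(11)
  H <- 3; D <- 4; Tn <- 2
  m <- initLSTM(H, D, seed = 3)
  seqs <- lapply(1:3, function(i)
    stepSequence(array(rnorm(Tn * 1 * D, sd = 0.7), c(Tn, 1, D)),
                 label = tbiClasses()[i]))
  labs <- tbiClasses()
  g <- lstmGradients(m, seqs, labs, l2 = 0.001)
  eps <- 1e-5
  maxrel <- 0
  for (sl in c("W", "R", "b", "Wy", "by")) {
    s <- slot(m, sl)
    for (ix in sample(length(s), min(15, length(s)))) {
      mm <- m
      v <- slot(mm, sl); v[ix] <- v[ix] + eps; slot(mm, sl) <- v
      up <- lstmGradients(mm, seqs, labs, l2 = 0.001)$loss
      v[ix] <- v[ix] - 2 * eps; slot(mm, sl) <- v
      dn <- lstmGradients(mm, seqs, labs, l2 = 0.001)$loss
      num <- (up - dn) / (2 * eps)
      ana <- g[[sl]][ix]
      maxrel <- max(maxrel, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
    }
  }
  expect_lt(maxrel, 1e-5)
})

test_that("training fits linearly separable toy sequences", {
  seqs <- tinySeqs(n = 4, steps = 3, channels = 2, samples = 5, seed = 2)
  cfg <- trainConfig(hiddenUnits = 8, epochs = 10, miniBatch = 2, seed = 4)
  m <- trainLSTM(seqs, cfg)
  tr <- lossTrace(m)
  expect_length(tr, 10)
  expect_true(all(diff(tr[1:5]) < 0))  # strictly decreasing early on
  expect_equal(predictSoftmax(m, seqs), vapply(seqs, classLabel,
                                               character(1)))
  # seeded determinism
  m2 <- trainLSTM(seqs, cfg)
  expect_identical(m@W, m2@W)
  expect_identical(lossTrace(m), lossTrace(m2))
  # missing class errors
  expect_error(trainLSTM(seqs[1:4], cfg), "missing class")
  expect_error(trainLSTM(list(), cfg), "empty")
})

test_that("stronger L2 shrinks trained weight norms", {
  seqs <- tinySeqs(n = 3, steps = 2, channels = 1, samples = 6, seed = 5)
  wnorm <- function(l2) {
    m <- trainLSTM(seqs, trainConfig(hiddenUnits = 4, epochs = 8,
                                     miniBatch = 3, l2 = l2, seed = 9))
    sum(m@W^2) + sum(m@R^2) + sum(m@Wy^2)
  }
  expect_lt(wnorm(5), wnorm(0))
})

test_that("features are the final hidden state with dimension H", {
  seqs <- tinySeqs(n = 2, steps = 4, channels = 2, samples = 3, seed = 6)
  m <- trainLSTM(seqs, trainConfig(hiddenUnits = 5, epochs = 2,
                                   miniBatch = 2, seed = 1))
  fe <- extractFeatures(m, seqs)
  expect_equal(dim(fe), c(6, 5))
  fw <- lstmForward(m, seqs[[1]])
  expect_equal(unname(fe[1, ]), unname(fw$states[4, ]), tolerance = 1e-12)
  # mean pooling averages the states
  fm <- extractFeatures(m, seqs[[1]], pool = "mean")
  expect_equal(unname(fm[1, ]), unname(colMeans(fw$states)),
               tolerance = 1e-12)
  # the canonical architecture yields 256-value features
  m256 <- initLSTM(256, 12, seed = 1)
  sq <- stepSequence(array(rnorm(2 * 3 * 4), c(2, 3, 4)))
  expect_equal(ncol(extractFeatures(m256, sq)), 256)
  # zero model gives zero features
  m0 <- m256
  m0@W[] <- 0; m0@R[] <- 0; m0@b[] <- 0
  expect_true(all(extractFeatures(m0, sq) == 0))
})
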