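test_that("bootstrap samples preserve size and stratification", {
  labs <- rep(tbiClasses(), each = 12)
  set.seed(1)
  idx <- bootstrapSample(labs)
  expect_length(idx, 36)
  expect_equal(as.integer(table(labs[idx])[tbiClasses()]), rep(12L, 3))
  expect_gt(sum(duplicated(idx)), 0)  # with-replacement draws repeat
  # a single-item dataset bootstraps to n copies of that item
  expect_equal(bootstrapSample("healthy"), 1L)
  set.seed(2)
  expect_equal(unique(bootstrapSample(rep("mild", 5))[1:5] %in% 1:5), TRUE)
  expect_error(bootstrapSample(character(0)), "empty")
})

test_that("the distinct fraction matches the closed-form expectation", {
  # drawing 12 of 12 with replacement: E[distinct]/12 = 1 - (1 - 1/12)^12
  set.seed(31)
  frac <- replicate(1000, length(unique(sample.int(12, 12, TRUE))) / 12)
  expected <- 1 - (1 - 1 / 12)^12
  # the package's stratified sampler reproduces the same inclusion law
  labs <- rep(tbiClasses(), each = 12)
  set.seed(32)
  fracPkg <- replicate(1000, {
    idx <- bootstrapSample(labs)
    length(unique(idx[labs[idx] == "mild"])) / 12
  })
  expect_equal(mean(frac), expected, tolerance = 0.02)
  expect_equal(mean(fracPkg), expected, tolerance = 0.02)
})

test_that("confusion-matrix metrics match hand-computed values", {
  perfect <- computeMetrics(diag(c(4, 4, 4)))
  expect_equal(unname(perfect), c(100, 100, 100, 100))
  conf <- rbind(c(4, 0, 0), c(1, 3, 0), c(0, 1, 3))
  m <- computeMetrics(conf)
  expect_equal(unname(m["accuracy"]), 100 * 10 / 12, tolerance = 1e-10)
  expect_equal(unname(m["sensitivity"]), 100 * mean(c(1, 3 / 4, 3 / 4)),
               tolerance = 1e-10)
  expect_equal(unname(m["specificity"]), 100 * mean(c(7 / 8, 7 / 8, 1)),
               tolerance = 1e-10)
  expect_equal(unname(m["precision"]), 100 * mean(c(4 / 5, 3 / 4, 1)),
               tolerance = 1e-10)
  # permuting classes leaves macro averages unchanged
  p <- c(3, 1, 2)
  expect_equal(computeMetrics(conf[p, p]), m)
  # never-predicted class: precision contribution 0 with a warning
  conf0 <- rbind(c(4, 0, 0), c(4, 0, 0), c(0, 0, 4))
  expect_warning(m0 <- computeMetrics(conf0), "never predicted")
  expect_equal(unname(m0["precision"]), 100 * mean(c(0.5, 0, 1)))
  expect_error(computeMetrics(matrix(0, 3, 3)), "zero")
  expect_error(computeMetrics(matrix(1, 2, 3)), "square")
})

test_that("cross-validation partitions stratified folds and pools them", {
  seqs <- tinySeqs(n = 4, steps = 2, channels = 2, samples = 5, seed = 3)
  cfg <- evalConfig(train = trainConfig(hiddenUnits = 8, epochs = 12,
                                        miniBatch = 4), kFolds = 3)
  set.seed(7)
  conf <- crossValidate(seqs, cfg)
  expect_equal(sum(conf), 12)            # every item tested exactly once
  expect_equal(unname(rowSums(conf)), rep(4, 3))
  # separable toy data: pooled confusion is diagonal
  expect_equal(unname(diag(conf)), rep(4, 3))
  # fixed rng => identical folds and confusion
  set.seed(7)
  conf2 <- crossValidate(seqs, cfg)
  expect_identical(conf, conf2)
})

test_that("bootstrap evaluation aggregates, summarises and reproduces", {
  seqs <- tinySeqs(n = 4, steps = 2, channels = 2, samples = 5, seed = 4)
  cfg <- evalConfig(nBootstrap = 3, kFolds = 3, seed = 21,
                    train = trainConfig(hiddenUnits = 8, epochs = 12,
                                        miniBatch = 4))
  rep1 <- runBootstrapEvaluation(seqs, cfg)
  expect_s4_class(rep1, "BootstrapReport")
  r <- replicates(rep1)
  expect_equal(nrow(r), 3)
  expect_true(all(r$accuracy >= 0 & r$accuracy <= 100))
  s <- metricSummary(rep1)
  expect_true(all(s$ci_lower <= s$mean & s$mean <= s$ci_upper))
  # separable data: perfect metrics with zero spread
  expect_equal(s["accuracy", "mean"], 100)
  expect_equal(s["accuracy", "sd"], 0)
  # deterministic end to end
  rep2 <- runBootstrapEvaluation(seqs, cfg)
  expect_identical(replicates(rep1), replicates(rep2))
  # single replicate: summary equals that replicate, SD 0 by convention
  one <- runBootstrapEvaluation(seqs, evalConfig(
    nBootstrap = 1, seed = 5,
    train = trainConfig(hiddenUnits = 4, epochs = 4, miniBatch = 4)))
  expect_equal(metricSummary(one)["accuracy", "mean"],
               replicates(one)$accuracy[1])
  expect_equal(metricSummary(one)["accuracy", "sd"], 0)
})

test_that("the softmax head is available as the ablation arm", {
  seqs <- tinySeqs(n = 4, steps = 2, channels = 2, samples = 5, seed = 6)
  cfg <- evalConfig(nBootstrap = 2, seed = 13, head = "softmax",
                    train = trainConfig(hiddenUnits = 8, epochs = 80,
                                        miniBatch = 4))
  rep <- runBootstrapEvaluation(seqs, cfg)
  expect_equal(metricSummary(rep)["accuracy", "mean"], 100)
})

test_that("the hill-climbing sweep fixes each axis at its best value", {
  seqs <- tinySeqs(n = 3, steps = 2, channels = 1, samples = 4, seed = 8)
  base <- evalConfig(nBootstrap = 2, seed = 31,
                     train = trainConfig(hiddenUnits = 4, epochs = 4,
                                         miniBatch = 3))
  sw <- sweepHyperparameters(
    seqs, grid = list(learningRate = c(0.01, 0.001), hiddenUnits = c(4, 8)),
    config = base)
  expect_equal(nrow(sw$table), 4)
  expect_equal(sum(sw$table$selected), 2)
  for (ax in unique(sw$table$axis)) {
    rows <- sw$table[sw$table$axis == ax, ]
    expect_equal(rows$value[rows$selected],
                 rows$value[which.max(rows$accuracy)])
  }
  # the selected values are carried into the returned best config
  bestH <- as.integer(sw$table$value[sw$table$axis == "hiddenUnits" &
                                     sw$table$selected])
  expect_equal(sw$best$hiddenUnits, bestH)
  # one-point grid: single row, trivially selected
  sw1 <- sweepHyperparameters(seqs, grid = list(miniBatch = 2),
                              config = base)
  expect_equal(nrow(sw1$table), 1)
  expect_true(sw1$table$selected)
})
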