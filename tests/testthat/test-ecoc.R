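test_that("the default design is the one-vs-one matrix", {
  M <- designMatrix(defaultDesign())
  expect_equal(unname(M["healthy", ]), c(1, 1, 0))
  expect_equal(unname(M["mild", ]), c(-1, 0, 1))
  expect_equal(unname(M["moderate", ]), c(0, -1, -1))
  expect_s4_class(defaultDesign(), "CodingDesign")
})

test_that("invalid designs are rejected", {
  expect_error(codingDesign(rbind(c(1, 1), c(1, 0))),
               "\\+1 and.*-1|distinct")
  expect_error(codingDesign(rbind(c(1, 0), c(-1, 0))), "-1")
  expect_error(codingDesign(rbind(c(1, 2), c(-1, 0))), "entries")
  expect_error(codingDesign(rbind(c(1, -1), c(-1, 1), c(1, -1))),
               "distinct")
})

test_that("Hamming decoding matches exhaustive minimum-distance search", {
  design <- defaultDesign()
  M <- designMatrix(design)
  # independent oracle: enumerate distances directly
  oracleDecode <- function(pred) {
    d <- numeric(nrow(M))
    for (k in seq_len(nrow(M)))
      for (j in seq_len(ncol(M)))
        if (M[k, j] != 0 && M[k, j] != pred[j]) d[k] <- d[k] + 1
    rownames(M)[which(d == min(d))][1]
  }
  grid <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  for (r in seq_len(nrow(grid))) {
    pred <- as.numeric(grid[r, ])
    expect_identical(hammingDecode(pred, design), oracleDecode(pred))
  }
  # the worked codeword examples
  expect_identical(hammingDecode(c(1, 1, -1)), "healthy")
  expect_identical(hammingDecode(c(-1, -1, 1)), "mild")
  expect_identical(hammingDecode(c(1, -1, -1)), "moderate")
  # exact codewords decode to their class at distance zero
  expect_identical(hammingDecode(c(1, 1, 1)), "healthy")
  expect_identical(hammingDecode(c(-1, -1, -1)), "moderate")
  expect_error(hammingDecode(c(0, 1, -1)), "-1 or \\+1")
  expect_error(hammingDecode(c(1, 1), defaultDesign()), "length")
})

test_that("every +/-1 vector decodes to a unique class under tie-break", {
  M <- designMatrix(defaultDesign())
  grid <- expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))
  decoded <- apply(grid, 1, hammingDecode, design = defaultDesign())
  expect_true(all(decoded %in% rownames(M)))
  expect_equal(sort(unique(decoded)), sort(rownames(M)))
})

test_that("training respects the column coding and separates blobs", {
  feats <- blobFeatures(nPer = 6, dim = 5, gap = 10, seed = 3)
  labs <- attr(feats, "labels")
  model <- trainEcoc(feats)
  expect_s4_class(model, "EcocModel")
  expect_length(model@learners, 3)
  # perfectly separated blobs: training-set accuracy 100%
  expect_equal(predictEcoc(model, feats), labs)
  expect_equal(unname(predict(model, feats)), labs)
  # 0-coded classes are excluded: each learner saw only 12 of 18 examples
  for (j in 1:3)
    expect_length(model@learners[[j]]$fitted, 12)
  # single-class input errors naming the column
  expect_error(trainEcoc(feats[labs == "mild", ], labs[labs == "mild"]),
               "column")
})

test_that("batch prediction preserves order and length", {
  feats <- blobFeatures(nPer = 5, dim = 4, gap = 8, seed = 9)
  labs <- attr(feats, "labels")
  model <- trainEcoc(feats)
  idx <- c(13, 2, 7, 1)
  expect_equal(predictEcoc(model, feats[idx, ]), labs[idx])
  expect_error(predictEcoc(model, feats[, 1:3]), "dimension")
})

test_that("permuting learner columns with design columns is invariant", {
  feats <- blobFeatures(nPer = 5, dim = 6, gap = 10, seed = 12)
  labs <- attr(feats, "labels")
  base <- trainEcoc(feats)
  perm <- c(3, 1, 2)
  M <- designMatrix(defaultDesign())[, perm]
  permModel <- trainEcoc(feats, labs, design = codingDesign(M))
  expect_equal(predictEcoc(permModel, feats), predictEcoc(base, feats))
})
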