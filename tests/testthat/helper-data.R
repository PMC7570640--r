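# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

.cached <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# tiny labelled step sequences: class information in constant per-class
# offsets, linearly separable by construction
tinySeqs <- function(n = 4, steps = 2, channels = 1, samples = 4, sd = 0.3,
                     seed = 1) {
  set.seed(seed)
  offs <- lapply(1:3, function(k) 2 * stats::rnorm(channels * samples))
  out <- list()
  for (k in 1:3) for (i in seq_len(n)) {
    dat <- array(stats::rnorm(steps * channels * samples, sd = sd),
                 c(steps, channels, samples)) +
      rep(offs[[k]], each = steps)
    out <- c(out, stepSequence(dat, label = tbiClasses()[k],
                               id = sprintf("%s_%d", tbiClasses()[k], i)))
  }
  out
}

# well-separated Gaussian feature blobs for the ECOC tests
blobFeatures <- function(nPer = 6, dim = 5, gap = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(3 * dim), 3) * gap
  feats <- do.call(rbind, lapply(1:3, function(k)
    matrix(stats::rnorm(nPer * dim, sd = 0.5), nPer) +
      matrix(centers[k, ], nPer, dim, byrow = TRUE)))
  rownames(feats) <- paste0("b", seq_len(3 * nPer))
  attr(feats, "labels") <- rep(tbiClasses(), each = nPer)
  feats
}

# one full-length simulated recording (healthy, defaults), reused widely
fixtureRecording <- function() {
  .cached("rec_healthy", function()
    simulateRecording("healthy", simConfig(), seed = 7))
}

# the default 36-recording dataset, preprocessed (the study conditions)
acceptanceSeqs <- function() {
  .cached("seqs_sep", function() {
    cfg <- simConfig(seed = 20260923)
    plan <- datasetPlan(cfg)
    lapply(seq_len(nrow(plan)), function(i)
      preprocessRecording(simulateRecording(plan$label[i], cfg,
                                            plan$seed[i], plan$id[i])))
  })
}

# the null dataset: class effects disabled, labels carry no signal
acceptanceNullSeqs <- function() {
  .cached("seqs_null", function() {
    cfg <- simConfig(seed = 20260924,
                     alphaAttenuation = c(mild = 1, moderate = 1),
                     thetaGain = c(mild = 1, moderate = 1))
    plan <- datasetPlan(cfg)
    lapply(seq_len(nrow(plan)), function(i)
      preprocessRecording(simulateRecording(plan$label[i], cfg,
                                            plan$seed[i], plan$id[i])))
  })
}
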