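# Shared fixtures, built once per test run.

# a flat profile: every subregion SOR level `level` with SD `sd`,
# asymmetry `asym` with SD `asymSd`
flatProfile <- function(group = "NC", level = 1, sd = 0, asym = 0,
                        asymSd = 0) {
  keys8 <- c("caudate_anterior", "caudate_middle", "caudate_posterior",
             "putamen_anterior", "putamen_middle", "putamen_posterior",
             "pallidum", "midbrain")
  keys6 <- keys8[1:6]
  groupProfile(group,
               sorMean = stats::setNames(rep(level, 8), keys8),
               sorSd = stats::setNames(rep(sd, 8), keys8),
               asymMean = stats::setNames(rep(asym, 6), keys6),
               asymSd = stats::setNames(rep(asymSd, 6), keys6))
}

# profiles that separate the three disease groups strongly (for separable
# classification fixtures): distinct putaminal levels, narrow spread
separatedProfiles <- function(sd = 0.08) {
  keys8 <- c("caudate_anterior", "caudate_middle", "caudate_posterior",
             "putamen_anterior", "putamen_middle", "putamen_posterior",
             "pallidum", "midbrain")
  keys6 <- keys8[1:6]
  mk <- function(g, base) groupProfile(
    g,
    sorMean = stats::setNames(base, keys8),
    sorSd = stats::setNames(rep(sd, 8), keys8),
    asymMean = stats::setNames(rep(0.3, 6), keys6),
    asymSd = stats::setNames(rep(0.1, 6), keys6))
  list(PD = mk("PD", c(1.8, 1.5, 1.2, 0.6, 0.4, 0.2, 0.8, 0.4)),
       MSA = mk("MSA", c(0.8, 0.7, 0.6, 1.6, 1.4, 1.2, 0.5, 0.4)),
       PSP = mk("PSP", c(0.4, 0.3, 0.2, 0.9, 0.8, 0.7, 1.4, 0.2)))
}

# default-geometry phantom spec without noise
quietSpec <- function(gridShape = c(64L, 64L, 64L)) {
  phantomSpec(gridShape = gridShape, noiseSd = 0, mriNoiseSd = 0)
}

# cached truth geometry for the default 64^3 spec (labels + subregions),
# shared by tests that only read it
defaultTruth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- phantomTruth(phantomSpec())
    cache
  }
})

# classifier config with a fixed cost (skips the inner grid search)
fastConfig <- function(seed = 1L) classifierConfig(costGrid = 1, seed = seed)

# null-experiment config: class weighting cancels the leave-one-out
# training-prior artifact, so chance really is 1/3 under shuffled labels
nullConfig <- function(seed = 1L)
  classifierConfig(costGrid = 1, seed = seed, classWeight = TRUE)

# two well-separated Gaussian blobs (binary) or three (multiclass)
toyBlobs <- function(n = 10, classes = 2, sep = 10, seed = 1) {
  set.seed(seed)
  centers <- matrix(c(0, 0, sep, 0, 0, sep), ncol = 2, byrow = TRUE)
  X <- do.call(rbind, lapply(seq_len(classes), function(k)
    cbind(rnorm(n, centers[k, 1]), rnorm(n, centers[k, 2]))))
  colnames(X) <- c("sor_f1", "sor_f2")
  list(X = X, y = factor(rep(LETTERS[seq_len(classes)], each = n)))
}
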