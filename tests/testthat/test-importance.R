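# published per-feature contribution table (right/left split subregions
# plus pallidum), used as the aggregation oracle
publishedContributions <- function() {
  c(sor_caudate_anterior_R = 0.113, sor_caudate_anterior_L = 0.072,
    sor_caudate_middle_R = 0.099, sor_caudate_middle_L = 0.064,
    sor_caudate_posterior_R = 0.067, sor_caudate_posterior_L = 0.077,
    sor_putamen_anterior_R = 0.048, sor_putamen_anterior_L = 0.053,
    sor_putamen_middle_R = 0.092, sor_putamen_middle_L = 0.076,
    sor_putamen_posterior_R = 0.075, sor_putamen_posterior_L = 0.072,
    sor_pallidum_R = 0.038, sor_pallidum_L = 0.054)
}

test_that("bilateral and nucleus aggregates reproduce the printed table", {
  agg <- aggregateContributions(publishedContributions())
  expect_equal(unname(agg$nucleusPercent["caudate"]), 49.2)
  expect_equal(unname(agg$nucleusPercent["putamen"]), 41.6)
  expect_equal(unname(agg$nucleusPercent["pallidum"]), 9.2)
  expect_equal(unname(agg$bilateralPercent["caudate_anterior"]), 18.5)
  expect_equal(unname(agg$bilateralPercent["putamen_middle"]), 16.8)
  expect_equal(unname(agg$bilateralPercent["caudate_middle"]), 16.3)
  expect_equal(unname(agg$bilateralPercent["putamen_posterior"]), 14.7)
  expect_equal(unname(agg$bilateralPercent["caudate_posterior"]), 14.4)
  expect_equal(unname(agg$bilateralPercent["putamen_anterior"]), 10.1)
  expect_equal(unname(agg$bilateralPercent["pallidum"]), 9.2)
})

test_that("aggregation is linear and rejects unknown keys", {
  a <- publishedContributions()
  b <- rev(a)[names(a)]
  s <- aggregateContributions(a + b)
  expect_equal(s$bilateral,
               aggregateContributions(a)$bilateral +
                 aggregateContributions(b)$bilateral)
  one <- setNames(rep(0, 14), names(a)); one["sor_pallidum_L"] <- 1
  agg1 <- aggregateContributions(one)
  expect_equal(unname(agg1$nucleusPercent), c(0, 0, 100))
  bad <- setNames(rep(1 / 3, 3), c("sor_pallidum_R", "sor_pallidum_L",
                                   "sor_thalamus_R"))
  expect_error(aggregateContributions(bad), "thalamus")
})

test_that("forest contributions are normalized and rank a planted signal", {
  profs <- list(
    PD = flatProfile("PD", level = 0.5, sd = 0.25, asym = 0.4, asymSd = 0.2),
    MSA = flatProfile("MSA", level = 1.0, sd = 0.25, asym = 0.4, asymSd = 0.2),
    PSP = flatProfile("PSP", level = 1.6, sd = 0.25, asym = 0.4, asymSd = 0.2))
  # only the anterior caudate separates the groups: flatten all else
  for (g in names(profs)) {
    keep <- profs[[g]]$sorMean["caudate_anterior"]
    profs[[g]]$sorMean[] <- 1.0
    profs[[g]]$sorMean["caudate_anterior"] <- keep
  }
  ft <- suppressWarnings(sampleCohortFeatures(
    profs, nPerGroup = c(PD = 20L, MSA = 20L, PSP = 20L), seed = 13L))
  X <- featureMatrix(ft)[, featureColumns("striatum")]
  imp <- featureContributions(X, ft$group,
                              importanceConfig(nRep = 5, seed = 13L))
  expect_equal(sum(imp$perFeature), 1, tolerance = 1e-9)
  expect_true(all(imp$perFeature >= 0))
  expect_equal(names(which.max(imp$bilateral)), "caudate_anterior")
  # aggregates are exact sums of their members
  expect_equal(unname(imp$nucleus["caudate"]),
               sum(imp$perFeature[grep("caudate", names(imp$perFeature))]))
})

test_that("identically distributed features show no spurious dominance", {
  prof <- flatProfile(level = 1.0, sd = 0.3, asym = 0.4, asymSd = 0.2)
  profs <- list(PD = prof, MSA = prof, PSP = prof)
  profs$PD$group <- "PD"; profs$MSA$group <- "MSA"; profs$PSP$group <- "PSP"
  ft <- suppressWarnings(sampleCohortFeatures(
    profs, nPerGroup = c(PD = 25L, MSA = 25L, PSP = 25L), seed = 17L))
  X <- featureMatrix(ft)[, featureColumns("striatum")]
  imp <- featureContributions(X, ft$group,
                              importanceConfig(nRep = 20, seed = 17L))
  expect_lte(max(imp$bilateral), 2 * min(imp$bilateral))
})

test_that("exact McNemar p-values match binomial tail enumeration", {
  # independent oracle: sum binomial point masses directly
  tailP <- function(b, c_) {
    n <- b + c_
    if (n == 0) return(1)
    k <- min(b, c_)
    min(1, 2 * sum(choose(n, 0:k) / 2^n))
  }
  expect_equal(mcnemarExact(0, 0)$p, 1)
  expect_equal(mcnemarExact(5, 5)$p, 1)
  expect_equal(mcnemarExact(9, 1)$p, 2 * pbinom(1, 10, 0.5))
  expect_lt(abs(mcnemarExact(9, 1)$p - 0.0215), 5e-4)
  for (b in 0:12) for (c_ in 0:(12 - b)) {
    expect_equal(mcnemarExact(b, c_)$p, tailP(b, c_), tolerance = 1e-12)
  }
  # continuity-corrected chi-squared variant stays close for larger counts
  expect_equal(mcnemarExact(30, 14, method = "chisq")$p,
               mcnemar.test(matrix(c(50, 30, 14, 50), 2, 2))$p.value,
               tolerance = 1e-12)
  expect_error(mcnemarExact(-1, 2), "nonnegative")
})

test_that("the midbrain add-on comparison runs and guards subject identity", {
  profs <- separatedProfiles()
  ft <- suppressWarnings(sampleCohortFeatures(
    profs, nPerGroup = c(PD = 8L, MSA = 8L, PSP = 8L), seed = 19L,
    featureSet = "striatum+midbrain"))
  ft14 <- ft[, c("subject_id", "group", "stage", featureColumns("striatum"))]
  ft2 <- ft[, c("subject_id", "group", "stage", featureColumns("midbrain"))]
  out <- midbrainAddonTest(ft, ft14, ft2, ft$group, fastConfig())
  expect_named(out$accuracy, c("striatum_midbrain", "striatum", "midbrain"))
  # fully separable in both striatal arms: no discordant pairs
  expect_equal(out$mcnemar$p, 1)
  expect_equal(out$accuracy[["striatum_midbrain"]], 1)
  shuffled <- ft14[rev(seq_len(nrow(ft14))), ]
  expect_error(midbrainAddonTest(ft, shuffled, ft2, ft$group, fastConfig()),
               "identical subjects")
})

test_that("contribution maps paint each subregion with its aggregate", {
  truth <- defaultTruth()
  agg <- aggregateContributions(publishedContributions())
  agg$perFeature <- publishedContributions()
  class(agg) <- "ImportanceTable"
  cmap <- contributionMap(truth$submap, agg)
  grid <- volData(truth$submap)
  expect_equal(unique(volData(cmap)[grid == 11L]), 18.5)   # anterior caudate
  expect_equal(unique(volData(cmap)[grid == 5L]), 9.2)     # pallidum
  expect_equal(unique(volData(cmap)[grid == 7L]), 0)       # midbrain unscored
})
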