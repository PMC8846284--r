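# a minimal hand-built subregion map: one caudate-anterior pair plus the
# occipital reference, on a 6x6x6 grid
tinySubmap <- function() {
  a <- array(0L, c(6L, 6L, 6L))
  a[1:2, 5:6, 1:2] <- 11L  # caudate anterior R
  a[5:6, 5:6, 1:2] <- 14L  # caudate anterior L
  a[1:2, 1:2, 1:2] <- 9L   # occipital R
  a[5:6, 1:2, 1:2] <- 10L  # occipital L
  new("SubregionMap", data = a, spacing = c(1, 1, 1), origin = c(0, 0, 0),
      codeTable = subregionCodeTable())
}

petWith <- function(submap, subMeanR, occMean = 1.5, subMeanL = subMeanR) {
  p <- array(0, dim(submap))
  p[volData(submap) == 11L] <- subMeanR
  p[volData(submap) == 14L] <- subMeanL
  p[volData(submap) %in% c(9L, 10L)] <- occMean
  volumeImage(p, voxelSpacing(submap))
}

test_that("SOR follows the specific-binding-ratio convention", {
  sm <- tinySubmap()
  pet <- petWith(sm, subMeanR = 3.0, occMean = 1.5)
  expect_equal(computeSOR(pet, sm, 11L), 1.0, tolerance = 1e-12)
  # ratio convention as the documented alternative
  expect_equal(computeSOR(pet, sm, 11L, formula = "plain_ratio"), 2.0,
               tolerance = 1e-12)
  # equal means give zero
  expect_equal(computeSOR(petWith(sm, 1.5), sm, 11L), 0, tolerance = 1e-12)
  # global intensity scaling cancels exactly
  pet5 <- volumeImage(volData(pet) * 5, voxelSpacing(pet))
  expect_identical(computeSOR(pet5, sm, 11L), computeSOR(pet, sm, 11L))
  # non-positive reference is an error
  expect_error(computeSOR(petWith(sm, 1, occMean = 0), sm, 11L),
               "occipital")
})

test_that("asymmetry index matches its defining arithmetic", {
  expect_equal(computeAsymmetry(1.2, 0.8), 0.4, tolerance = 1e-12)
  expect_equal(computeAsymmetry(0.8, 1.2), 0.4, tolerance = 1e-12)  # sideless
  for (x in c(0.3, 1, 2.7)) expect_equal(computeAsymmetry(x, x), 0)
  expect_equal(computeAsymmetry(1.0, 0.0), 2.0, tolerance = 1e-12)
  und <- computeAsymmetry(-0.4, 0.2)
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(computeAsymmetry(Inf, 1), "finite")
})

test_that("feature vectors have the documented shape per feature set", {
  spec <- quietSpec()
  subj <- generateSubject(spec, flatProfile(level = 1), 3L)
  sub <- phantomTruth(spec)$submap
  for (fs in c("striatum+midbrain", "striatum", "midbrain")) {
    ft <- extractSubject(subj$pet, sub, list(subject_id = "s"),
                         featureSet = fs)
    sorCols <- grep("^sor_", names(ft), value = TRUE)
    expect_identical(sorCols, featureColumns(fs))
    expect_length(sorCols, c("striatum+midbrain" = 16L, "striatum" = 14L,
                             "midbrain" = 2L)[[fs]])
    expect_length(grep("^ai_", names(ft)), 6L)
  }
})

test_that("noise-free phantoms planted at SOR 1 recover 1 everywhere", {
  spec <- quietSpec()
  subj <- generateSubject(spec, flatProfile(level = 1, asym = 0), 11L)
  sub <- phantomTruth(spec)$submap
  ft <- extractSubject(subj$pet, sub, list(subject_id = "s"))
  sor <- unlist(ft[grep("^sor_", names(ft))])
  ai <- unlist(ft[grep("^ai_", names(ft))])
  expect_true(all(abs(sor - 1) < 0.02))
  expect_true(all(abs(ai) < 0.02))
})

test_that("feature tables survive a CSV round trip at full precision", {
  ft <- suppressWarnings(sampleCohortFeatures(
    nPerGroup = c(PD = 3L, NC = 2L), seed = 8L, includeAsymmetry = TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  back <- readFeatureTable(path)
  num <- grep("^(sor|ai)_", names(ft), value = TRUE)
  for (cl in num) expect_equal(back[[cl]], ft[[cl]], tolerance = 1e-12)
  expect_identical(back$subject_id, ft$subject_id)
})

test_that("unknown feature-table columns are dropped with a warning", {
  ft <- suppressWarnings(sampleCohortFeatures(
    nPerGroup = c(PD = 2L, NC = 2L), seed = 1L))
  ft$scanner_id <- "A"
  path <- withr::local_tempfile(fileext = ".csv")
  writeFeatureTable(ft, path)
  expect_warning(back <- readFeatureTable(path), "scanner_id")
  expect_false("scanner_id" %in% names(back))
})

test_that("the cohort table runs end to end and excludes broken subjects", {
  out <- withr::local_tempdir()
  spec <- phantomSpec()
  man <- generateCohort(spec, nPerGroup = c(PD = 2L, MSA = 2L),
                        outDir = out, seed = 5L)
  ft <- cohortFeatureTable(man)
  expect_equal(nrow(ft), 4L)
  expect_false(anyNA(featureMatrix(ft, includeAsymmetry = TRUE)))
  expect_length(attr(ft, "failures"), 0L)
  # break one subject's PET path
  man$pet_path[2] <- file.path(out, "missing.nii.gz")
  expect_message(ft2 <- cohortFeatureTable(man), "failed")
  expect_equal(nrow(ft2), 3L)
  expect_length(attr(ft2, "failures"), 1L)
})

test_that("group summaries recover sampled cohort means within 3 SE", {
  n <- 40L
  ft <- suppressWarnings(sampleCohortFeatures(
    nPerGroup = c(PD = n, NC = n), seed = 21L))
  gs <- groupFeatureSummary(ft)
  profs <- defaultGroupProfiles()
  for (g in c("PD", "NC")) {
    pr <- profs[[g]]
    for (k in c("putamen_anterior", "caudate_anterior")) {
      row <- gs[gs$group == g & gs$measure == "sor" & gs$subregion == k, ]
      expect_lt(abs(row$mean - pr$sorMean[[k]]),
                3 * pr$sorSd[[k]] / sqrt(n))
    }
  }
})
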