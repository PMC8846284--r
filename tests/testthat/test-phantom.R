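test_that("noise-free generation plants exact uptake levels", {
  spec <- quietSpec()
  subj <- generateSubject(spec, flatProfile(level = 1, asym = 0), 42L)
  truth <- phantomTruth(spec)
  pet <- volData(subj$pet)
  grid <- volData(truth$submap)
  ct <- codeTable(truth$submap)
  for (code in ct$code[ct$region != "occipital"]) {
    expect_equal(mean(pet[grid == code]), 2 * spec$occipitalUptake,
                 tolerance = 1e-12)
  }
  occ <- ct$code[ct$region == "occipital"]
  expect_equal(mean(pet[grid %in% occ]), spec$occipitalUptake,
               tolerance = 1e-12)
})

test_that("asymmetry is realized as level (1 +/- a/2) and inverts exactly", {
  draws <- drawSubjectSOR(flatProfile(level = 1, asym = 0.4), seed = 3L)
  i <- match("putamen_anterior", draws$key)
  sides <- sort(c(draws$sorR[i], draws$sorL[i]))
  expect_equal(sides, c(0.8, 1.2), tolerance = 1e-12)
  expect_equal(computeAsymmetry(draws$sorL[i], draws$sorR[i]), 0.4,
               tolerance = 1e-12)
  # pallidum and midbrain are symmetric
  for (k in c("pallidum", "midbrain")) {
    j <- match(k, draws$key)
    expect_identical(draws$sorR[j], draws$sorL[j])
  }
})

test_that("generation is bit-reproducible given the subject seed", {
  spec <- phantomSpec()  # with noise
  a <- generateSubject(spec, defaultGroupProfiles()$PD, 7L)
  b <- generateSubject(spec, defaultGroupProfiles()$PD, 7L)
  expect_identical(volData(a$pet), volData(b$pet))
  expect_identical(volData(a$mri), volData(b$mri))
  c_ <- generateSubject(spec, defaultGroupProfiles()$PD, 8L)
  expect_false(identical(volData(a$pet), volData(c_$pet)))
})

test_that("zero asymmetry and zero noise give mirror-equal side SORs", {
  spec <- quietSpec()
  subj <- generateSubject(spec, flatProfile(level = 1.4, sd = 0, asym = 0), 5L)
  truth <- phantomTruth(spec)
  ft <- extractSubject(subj$pet, truth$submap, list(subject_id = "s"))
  for (k in c("caudate_anterior", "caudate_middle", "caudate_posterior",
              "putamen_anterior", "putamen_middle", "putamen_posterior",
              "pallidum", "midbrain")) {
    expect_equal(ft[[paste0("sor_", k, "_R")]], ft[[paste0("sor_", k, "_L")]],
                 tolerance = 1e-12)
  }
})

test_that("out-of-range draws are truncated with a warning", {
  bad <- flatProfile(level = -0.95, sd = 0.5)
  expect_warning(drawSubjectSOR(bad, seed = 2L), "redrawing")
  ok <- replicate(20, {
    d <- suppressWarnings(drawSubjectSOR(bad, seed = sample.int(1e6, 1)))
    all(d$level > -1)
  })
  expect_true(all(ok))
})

test_that("phantom spec validation rejects broken geometry", {
  g <- defaultRoiGeometry()
  g$cx[g$region == "occipital" & g$side == "R"] <- 140  # outside
  expect_error(phantomSpec(roiGeometry = g), "outside")
  g2 <- defaultRoiGeometry()
  g2$cy[g2$region == "caudate" & g2$side == "L"] <- 60  # breaks mirror
  expect_error(phantomSpec(roiGeometry = g2), "mirror")
  expect_error(phantomSpec(occipitalUptake = 0), "occipitalUptake")
})

test_that("cohort generation writes volumes, manifest and is reproducible", {
  out <- withr::local_tempdir()
  spec <- phantomSpec(gridShape = c(32L, 32L, 32L))
  n <- c(PD = 2L, MSA = 2L, PSP = 2L, NC = 2L)
  man <- generateCohort(spec, nPerGroup = n, outDir = out, seed = 9L)
  expect_equal(nrow(man), 8L)
  expect_equal(anyDuplicated(man$subject_id), 0L)
  expect_true(all(file.exists(man$mri_path)))
  expect_true(all(file.exists(man$pet_path)))
  expect_true(all(file.exists(man$labels_path)))
  expect_true(file.exists(file.path(out, "manifest.csv")))
  out2 <- withr::local_tempdir()
  man2 <- generateCohort(spec, nPerGroup = n, outDir = out2, seed = 9L)
  expect_identical(man$seed, man2$seed)
  expect_identical(man$stage, man2$stage)
  v1 <- readVolume(man$pet_path[1]); v2 <- readVolume(man2$pet_path[1])
  expect_identical(volData(v1), volData(v2))
})

test_that("default cohort composition matches the study design", {
  man <- generateCohort(phantomSpec(), writeVolumes = FALSE, seed = 1L)
  expect_equal(nrow(man), 129L)
  expect_equal(sum(man$group != "NC"), 107L)
  es <- table(man$group[man$stage == "ES"])
  expect_equal(as.integer(es[c("PD", "MSA", "PSP")]), c(11L, 17L, 8L))
  expect_true(all(is.na(man$stage[man$group == "NC"])))
  expect_equal(sum(man$stage == "AS", na.rm = TRUE), 71L)
})

test_that("statistical feature sampler matches the voxel path's layout", {
  ft <- suppressWarnings(sampleCohortFeatures(
    nPerGroup = c(PD = 3L, NC = 3L), seed = 2L,
    featureSet = "striatum+midbrain", includeAsymmetry = TRUE))
  expect_equal(nrow(ft), 6L)
  expect_true(all(featureColumns("striatum+midbrain", TRUE) %in% names(ft)))
  ft2 <- suppressWarnings(sampleCohortFeatures(
    nPerGroup = c(PD = 3L, NC = 3L), seed = 2L,
    featureSet = "striatum+midbrain", includeAsymmetry = TRUE))
  expect_identical(ft, ft2)
})
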