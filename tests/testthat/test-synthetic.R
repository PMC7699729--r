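test_that("generated connectomes are symmetric, non-negative, zero-diagonal integers", {
  for (seed in c(2, 7, 19)) {
    coh <- generateCohort(smallConfig(seed))
    for (cm in connectomes(coh@dataset)) {
      w <- connWeights(cm)
      expect_identical(w, t(w))
      expect_true(all(w >= 0))
      expect_true(all(diag(w) == 0))
      expect_true(all(w == round(w)))
    }
  }
})

test_that("cohort dimensions follow the config and the default cohort has 191 subjects", {
  coh <- generateCohort(smallConfig(1))
  expect_equal(nSubjects(coh@dataset), 42)
  expect_equal(length(roiLabels(coh@dataset)), 24)
  expect_equal(ncol(clinicalValues(clinicalData(coh@dataset))), 10)
  defaults <- syntheticConfig()@params
  expect_equal(defaults$n_nc + defaults$n_mci + defaults$n_ad, 191)
  expect_equal(defaults$n_nc, 48)
  expect_equal(defaults$n_mci, 104)
  expect_equal(defaults$n_ad, 39)
  expect_equal(defaults$n_rois, 120)
})

test_that("equal seeds reproduce the cohort; different seeds differ", {
  a <- generateCohort(smallConfig(5))
  b <- generateCohort(smallConfig(5))
  c <- generateCohort(smallConfig(6))
  expect_identical(connWeights(connectomes(a@dataset)[[3]]),
                   connWeights(connectomes(b@dataset)[[3]]))
  expect_identical(trueSeverity(a), trueSeverity(b))
  expect_false(identical(connWeights(connectomes(a@dataset)[[3]]),
                         connWeights(connectomes(c@dataset)[[3]])))
})

test_that("noiseless indices are exact multiples of severity; zero effect size kills feature association", {
  coh <- generateCohort(smallConfig(3, index_noise_sd = 0))
  y <- clinicalValues(clinicalData(coh@dataset))
  for (s in seq_len(ncol(y)))
    expect_equal(abs(cor(y[, s], trueSeverity(coh))), 1, tolerance = 1e-12)

  coh0 <- generateCohort(syntheticConfig(effect_size = 0, n_rois = 30,
                                         seed = 4))
  expect_true(nrow(plantedFeatures(coh0)) > 0)
  x2 <- buildX2(coh0@dataset)
  vals <- featureValues(x2)
  rs <- vapply(plantedFeatures(coh0)$label, function(l)
    cor(vals[, match(l, featureLabels(x2))], trueSeverity(coh0)), numeric(1))
  expect_true(all(abs(rs) < 0.25))   # n = 191, null correlation
})

test_that("planted strength features carry the planted sign across seeds", {
  agree <- c()
  for (seed in 1:50) {
    coh <- generateCohort(smallConfig(seed, n_rois = 40, n_nc = 48,
                                      n_mci = 104, n_ad = 39,
                                      index_noise_sd = 0.1))
    sev <- trueSeverity(coh)
    strengths <- t(vapply(connectomes(coh@dataset), function(cm)
      unname(nodeStrength(cm)), numeric(40)))
    planted <- plantedFeatures(coh)
    roiIdx <- match(sub("^S-", "", planted$label), roiLabels(coh@dataset))
    agree <- c(agree, sign(vapply(roiIdx, function(i)
      cor(strengths[, i], sev), numeric(1))) == planted$sign)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("planted ROI sets must be disjoint and in range", {
  expect_error(syntheticConfig(planted_negative_rois = c(3, 5),
                               planted_positive_rois = c(5, 9)),
               "disjoint")
  expect_error(syntheticConfig(n_rois = 10, planted_negative_rois = 3,
                               planted_positive_rois = 11),
               "out of range")
})

test_that("cohorts round-trip through disk losslessly", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(smallConfig(8))
  writeCohort(coh, dir, overwrite = TRUE)
  back <- readCohort(dir)
  expect_identical(subjectIDs(back), subjectIDs(coh@dataset))
  expect_identical(diagnosis(back), diagnosis(coh@dataset))
  for (i in seq_len(nSubjects(back)))
    expect_identical(connWeights(connectomes(back)[[i]]) + 0,
                     connWeights(connectomes(coh@dataset)[[i]]) + 0)
  expect_equal(clinicalValues(clinicalData(back)),
               clinicalValues(clinicalData(coh@dataset)),
               tolerance = 1e-12)
  expect_error(writeCohort(coh, dir), "not empty")
})

test_that("a 3-subject, 4-ROI cohort writes 3 connectivity files of 4x4", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(syntheticConfig(n_nc = 1, n_mci = 1, n_ad = 1,
                                        n_rois = 4, planted_negative_rois = 1,
                                        planted_positive_rois = 3, seed = 2))
  writeCohort(coh, dir, overwrite = TRUE)
  files <- list.files(dir, pattern = "^sub.*\\.csv$")
  expect_length(files, 3)
  w <- as.matrix(read.csv(file.path(dir, files[1]), header = FALSE))
  expect_equal(dim(w), c(4, 4))
  truth <- read.csv(file.path(dir, "ground_truth_planted.csv"))
  expect_equal(nrow(truth), 2)
})

test_that("empty planted sets produce an empty ground-truth feature list", {
  dir <- withr::local_tempdir()
  coh <- generateCohort(smallConfig(1, planted_negative_rois = integer(0),
                                    planted_positive_rois = integer(0)))
  expect_equal(nrow(plantedFeatures(coh)), 0)
  writeCohort(coh, dir, overwrite = TRUE)
  expect_equal(nrow(read.csv(file.path(dir, "ground_truth_planted.csv"))), 0)
})
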