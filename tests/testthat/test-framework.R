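test_that("the correlation filter drops exactly the redundant indices", {
  set.seed(41)
  # mutually uncorrelated battery is untouched
  y <- clinicalTable(matrix(rnorm(600), ncol = 3),
                     diagnosis = rep("NC", 200))
  expect_identical(indexNames(filterIndices(y, 0.75)), indexNames(y))
  # identical columns: exactly one of the pair is dropped
  base <- rnorm(200)
  y2 <- clinicalTable(cbind(base, base, rnorm(200)),
                      indexNames = c("a", "b", "c"),
                      diagnosis = rep("NC", 200))
  f2 <- filterIndices(y2, 0.75)
  expect_equal(ncol(clinicalValues(f2)), 2)
  expect_true("c" %in% indexNames(f2))
  # a single highly correlated pair among four indices: three survive
  u <- rnorm(500)
  y4 <- clinicalTable(cbind(u + rnorm(500, 0, 0.32), u + rnorm(500, 0, 0.32),
                            rnorm(500), rnorm(500)),
                      indexNames = c("p1", "p2", "q1", "q2"),
                      diagnosis = rep("NC", 500))
  expect_gte(abs(cor(clinicalValues(y4))[1, 2]), 0.85)
  f4 <- filterIndices(y4, 0.75)
  expect_equal(ncol(clinicalValues(f4)), 3)
  expect_true(all(c("q1", "q2") %in% indexNames(f4)))
  expect_error(filterIndices(y2, 1.5), "threshold")
})

test_that("the fold plan partitions the cohort and yields V*k rounds", {
  coh <- generateCohort(smallConfig(2))
  folds <- makeFolds(coh@dataset, v = 10, k = 6, seed = 4)
  expect_length(folds, 60)
  m <- nSubjects(coh@dataset)
  for (rep_ in 1:10) {
    rounds <- folds[((rep_ - 1) * 6 + 1):(rep_ * 6)]
    tests <- lapply(rounds, `[[`, "test")
    expect_setequal(unlist(tests), seq_len(m))
    expect_equal(sum(lengths(tests)), m)      # pairwise disjoint
    for (rd in rounds)
      expect_setequal(c(rd$train, rd$test), seq_len(m))
  }
  # folds are stratified: every test fold contains each diagnosis
  tab <- table(diagnosis(coh@dataset)[folds[[1]]$test])
  expect_setequal(names(tab), c("NC", "MCI", "AD"))
  # leave-one-out via v = 1, k = M
  loo <- suppressWarnings(
    makeFolds(rep(c("NC", "AD"), each = 10), v = 1, k = 20, seed = 1))
  expect_true(all(lengths(lapply(loo, `[[`, "test")) == 1))
})

test_that("fold construction is seed-deterministic and warns on tiny groups", {
  labels <- rep(c("NC", "MCI", "AD"), times = c(10, 12, 8))
  a <- makeFolds(labels, v = 3, k = 5, seed = 9)
  b <- makeFolds(labels, v = 3, k = 5, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, makeFolds(labels, v = 3, k = 5, seed = 10)))
  expect_warning(makeFolds(rep(c("NC", "AD"), c(30, 3)), v = 1, k = 5,
                           seed = 1), "unstratified")
})

test_that("rank-sum comparison behaves at the extremes", {
  set.seed(51)
  a <- rnorm(100)
  expect_gt(compareModels(a, a), 0.9)
  b <- rnorm(100) + 100   # disjoint supports
  expect_lt(compareModels(a, b), 1e-10)
  expect_error(compareModels(rep(1, 100), a), "constant")
})

test_that("the experiment is reproducible and leakage-free", {
  coh <- generateCohort(smallConfig(6, n_rois = 16))
  cfg <- experimentConfig(vRepeats = 1, kFolds = 3, seed = 2,
                          variants = "X2", targets = "generalized",
                          nPerm = 25, nLambda = 12, lambdaRatio = 1e-2)
  r1 <- runExperiment(coh@dataset, cfg)
  r2 <- runExperiment(coh@dataset, cfg)
  expect_identical(resultTable(r1), resultTable(r2))
  expect_identical(r1@B, r2@B)
  expect_identical(r1@scoreSummary, r2@scoreSummary)

  # canary: perturbing one held-out subject after training changes nothing
  # for the model or for other subjects' scores
  fold <- r1@folds[[1]]
  cl <- clinicalData(coh@dataset)
  model <- fitScore(cl[fold$train])
  zBefore <- transformScore(model, cl[fold$test])
  perturbed <- clinicalValues(cl)
  victim <- fold$test[1]
  perturbed[victim, ] <- perturbed[victim, ] + 50
  clPert <- clinicalTable(perturbed, indexNames = indexNames(cl),
                          subjectIDs = subjectIDs(cl),
                          diagnosis = diagnosis(cl))
  modelPert <- fitScore(clPert[fold$train])
  expect_identical(model@loadings, modelPert@loadings)
  expect_identical(model@center, modelPert@center)
  zAfter <- transformScore(modelPert, clPert[fold$test])
  keep <- fold$test != victim
  expect_identical(zBefore[keep], zAfter[keep])

  x2 <- buildX2(coh@dataset)
  fitA <- tuneLambda(featureValues(x2)[fold$train, ], model@trainScores,
                     seed = 7, diagnosis = diagnosis(coh@dataset)[fold$train])
  xPert <- featureValues(x2)
  xPert[victim, ] <- xPert[victim, ] * 10
  fitB <- tuneLambda(xPert[fold$train, ], model@trainScores, seed = 7,
                     diagnosis = diagnosis(coh@dataset)[fold$train])
  expect_identical(fitA@beta, fitB@beta)
  predA <- predict(fitA, featureValues(x2)[fold$test, , drop = FALSE])
  predB <- predict(fitB, xPert[fold$test, , drop = FALSE])
  expect_identical(predA[keep], predB[keep])
})

test_that("a zero-effect cohort yields correlations near zero", {
  coh <- generateCohort(smallConfig(14, n_nc = 16, n_mci = 26, n_ad = 12,
                                    effect_size = 0))
  cfg <- experimentConfig(vRepeats = 1, kFolds = 4, seed = 3,
                          variants = "X2", targets = "generalized",
                          nPerm = 0, nLambda = 12, lambdaRatio = 1e-2)
  res <- runExperiment(coh@dataset, cfg)
  expect_lt(abs(mean(resultTable(res)$r)), 0.3)
})

test_that("experiment results carry coherent structure", {
  coh <- generateCohort(smallConfig(3, n_rois = 12))
  cfg <- experimentConfig(vRepeats = 1, kFolds = 3, seed = 8,
                          variants = "X2", targets = "all", nPerm = 20,
                          nLambda = 10, lambdaRatio = 1e-2)
  res <- runExperiment(coh@dataset, cfg)
  tab <- resultTable(res)
  expect_setequal(unique(tab$target),
                  c("generalized_score",
                    indexNames(filterIndices(clinicalData(coh@dataset)))))
  expect_true(all(tab$r >= -1 & tab$r <= 1))
  expect_equal(nrow(res@B$X2), 3)
  expect_equal(ncol(res@B$X2), 36)
  expect_true(all(is.finite(res@scoreSummary$nmi)))
  s <- summarizeR(res)
  expect_true(all(c("variant", "target", "meanR", "sdR") %in% names(s)))
})
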