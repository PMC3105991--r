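test_that("the default equivalence spec reproduces the benchmark shape", {
  sp <- equivalenceSpec()
  expect_identical(sp$nSamples, 750L)
  expect_identical(sp$nGenes, 999L)
  expect_identical(sp$nTrueSignatures, 72)
  expect_identical(sp$alwaysMember, "X10")
  expect_identical(lengths(sp$classes), c(4L, 2L, 3L, 3L))
  expect_length(sp$noiseGenes, 999 - 13)

  tiny <- generateTiedLike(equivalenceSpec(nSamples = 100, nGenes = 10,
                                           classSizes = c(2, 2), seed = 1))
  expect_length(tiny$groundTruth, 4)
  expect_true(all(signatureSizes(tiny$groundTruth) == 3L))

  ## singleton classes mean a unique signature
  solo <- equivalenceSpec(nSamples = 100, nGenes = 10,
                          classSizes = c(1, 1), seed = 1)
  expect_identical(generateTiedLike(solo)$groundTruth@signatures,
                   list(sort(c("X1", "X2", "X3"))))

  expect_error(equivalenceSpec(classSizes = c(2, 0)), ">= 1")
  expect_error(equivalenceSpec(nGenes = 5, classSizes = c(4, 2)), "at least")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- generateTiedLike(equivalenceSpec(nSamples = 150, nGenes = 30,
                                        classSizes = c(2, 2), seed = 3))
  b <- generateTiedLike(equivalenceSpec(nSamples = 150, nGenes = 30,
                                        classSizes = c(2, 2), seed = 3))
  expect_identical(exprsMatrix(a$data), exprsMatrix(b$data))
  expect_identical(phenotype(a$data), phenotype(b$data))

  c1 <- generateCohortData(cohortSpec(nGenes = 40, seed = 4))
  c2 <- generateCohortData(cohortSpec(nGenes = 40, seed = 4))
  expect_identical(exprsMatrix(c1), exprsMatrix(c2))

  f1 <- generateSeparationFixture(seed = 5)
  f2 <- generateSeparationFixture(seed = 5)
  expect_identical(exprsMatrix(f1), exprsMatrix(f2))

  n1 <- generateLinearGaussianNetwork(seed = 6)
  n2 <- generateLinearGaussianNetwork(seed = 6)
  expect_identical(exprsMatrix(n1$data), exprsMatrix(n2$data))
})

test_that("noise genes carry no phenotype association", {
  tied <- generateTiedLike(equivalenceSpec(nSamples = 300, nGenes = 300,
                                           classSizes = c(2, 2), seed = 7))
  X <- exprsMatrix(tied$data)
  ph <- phenotype(tied$data)
  pv <- vapply(tied$spec$noiseGenes, function(g) {
    fisherZTest(cbind(g = X[, g], t = as.numeric(ph)), "g", "t")$pValue
  }, numeric(1))
  frac <- mean(pv > 0.05)
  expect_gt(frac, 0.90)
  expect_lt(frac, 0.99)
})

test_that("class members are information-equivalent and latents independent", {
  tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 30,
                                           classSizes = c(3, 2), seed = 8))
  X <- exprsMatrix(tied$data)
  cls <- tied$spec$classes
  ## within-class copies are near-perfectly correlated
  expect_gt(abs(cor(X[, cls[[1]][1]], X[, cls[[1]][2]])), 0.999999)
  ## across classes essentially uncorrelated
  expect_lt(abs(cor(X[, cls[[1]][1]], X[, cls[[2]][1]])), 0.2)
  ## every class member is marginally associated with the phenotype
  ph <- as.numeric(phenotype(tied$data))
  for (g in c(unlist(cls), tied$spec$alwaysMember))
    expect_lt(fisherZTest(cbind(g = X[, g], t = ph), "g", "t")$pValue, 1e-6)
})

test_that("cohort generator injects the requested batch shift scale", {
  cs <- cohortSpec(cohorts = data.frame(name = c("A", "B", "C", "D"),
                                        nInfected = rep(5L, 4),
                                        nUninfected = rep(50L, 4)),
                   nGenes = 800, batchShiftSd = 1, seed = 9)
  ed <- generateCohortData(cs)
  X <- exprsMatrix(ed)
  ph <- phenotype(ed)
  co <- cohort(ed)
  ## per-gene spread of cohort means among uninfected samples
  cohortMeans <- sapply(levels(co), function(lev) {
    colMeans(X[co == lev & ph == 0L, , drop = FALSE])
  })
  spread2 <- mean(apply(cohortMeans, 1, var))
  ## observed spread includes the sampling noise of each cohort mean
  expected2 <- cs$batchShiftSd^2 + cs$noiseSd^2 / 50
  expect_lt(abs(sqrt(spread2) - sqrt(expected2)) / sqrt(expected2), 0.1)
})

test_that("without batch shifts the correction only removes sampling noise", {
  cs <- cohortSpec(nGenes = 400, batchShiftSd = 0, seed = 10)
  ed <- generateCohortData(cs)
  delta <- exprsMatrix(cohortUninfectedMeanCorrect(ed)) - exprsMatrix(ed)
  ## per cohort, the change equals minus the uninfected-mean profile, whose
  ## sd is noiseSd / sqrt(u)
  u <- 8
  expect_lt(abs(sd(delta[1, ]) - cs$noiseSd / sqrt(u)) /
              (cs$noiseSd / sqrt(u)), 0.3)
})

test_that("signal genes separate the classes when requested", {
  cs <- cohortSpec(nGenes = 300, nSignalGenes = 30, effectSize = 3,
                   seed = 11)
  edNull <- generateCohortData(cs, nullPhenotype = TRUE)
  edSig <- generateCohortData(cs, nullPhenotype = FALSE)
  expect_lte(countSignificant(edNull), 2L)
  expect_gte(countSignificant(edSig), 27L)
})

test_that("the separation fixture reproduces the variance-collapse effect", {
  sf <- generateSeparationFixture()
  ph <- phenotype(sf)
  co <- cohort(sf)
  x <- exprsMatrix(sf)[, 1]
  pBefore <- welchTTest(x[ph == 1L], x[ph == 0L])$pValue
  xc <- exprsMatrix(cohortUninfectedMeanCorrect(sf))[, 1]
  pAfter <- welchTTest(xc[ph == 1L], xc[ph == 0L])$pValue
  expect_gt(pBefore, 0.1)
  expect_lt(pAfter, 1e-3)
  expect_lt(pAfter / pBefore, 1e-2)

  ## within-cohort group mean difference is untouched
  for (lev in levels(co)) {
    d0 <- mean(x[co == lev & ph == 1L]) - mean(x[co == lev & ph == 0L])
    d1 <- mean(xc[co == lev & ph == 1L]) - mean(xc[co == lev & ph == 0L])
    expect_equal(d1, d0, tolerance = 1e-12)
  }

  ## no-op limit: zero offsets leave the p-value essentially unchanged
  sf0 <- generateSeparationFixture(cohortOffsets = c(0, 0))
  ph0 <- phenotype(sf0)
  y <- exprsMatrix(sf0)[, 1]
  yc <- exprsMatrix(cohortUninfectedMeanCorrect(sf0))[, 1]
  q0 <- welchTTest(y[ph0 == 1L], y[ph0 == 0L])$pValue
  q1 <- welchTTest(yc[ph0 == 1L], yc[ph0 == 0L])$pValue
  expect_gt(q1 / q0, 0.1)
  expect_lt(q1 / q0, 10)
})

test_that("small equivalence problems are recovered exactly across seeds", {
  exact <- 0
  for (s in 1:5) {
    tied <- generateTiedLike(equivalenceSpec(nSamples = 400, nGenes = 40,
                                             classSizes = c(2, 2),
                                             seed = s))
    ss <- tieStar(tied$data)
    exact <- exact + identical(sigKeys(ss), sigKeys(tied$groundTruth))
  }
  expect_gte(exact, 4)
})
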