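test_that("global centering removes exactly the grand mean", {
  expect_identical(centerGlobal(matrix(0, 3, 4)), matrix(0, 3, 4))
  expect_identical(centerGlobal(matrix(7, 2, 5)), matrix(0, 2, 5))
  set.seed(50)
  M <- matrix(rnorm(60, mean = 3), 6, 10)
  expect_lt(abs(mean(centerGlobal(M))), 1e-12)
})

test_that("per-gene standardization uses the sample (n-1) convention", {
  out <- standardizePerGene(cbind(g = c(1, 2, 3)))
  expect_equal(as.vector(out), c(-1, 0, 1))
  set.seed(51)
  M <- matrix(rnorm(200, 5, 3), 20, 10)
  S <- standardizePerGene(M)
  expect_true(all(abs(colMeans(S)) < 1e-10))
  expect_true(all(abs(apply(S, 2, sd) - 1) < 1e-10))
  ## idempotence
  expect_equal(standardizePerGene(S), S, tolerance = 1e-12)
  ## constant gene
  expect_warning(C <- standardizePerGene(cbind(a = 1:4, b = rep(2, 4))),
                 "constant")
  expect_identical(C[, "b"], rep(0, 4))
})

test_that("per-gene [0,1] scaling maps the range exactly", {
  expect_equal(as.vector(scale01PerGene(cbind(g = c(1, 3, 5)))),
               c(0, 0.5, 1))
  set.seed(52)
  M <- matrix(rnorm(100), 10, 10)
  S <- scale01PerGene(M)
  expect_true(all(abs(apply(S, 2, min)) < 1e-15))
  expect_true(all(abs(apply(S, 2, max) - 1) < 1e-15))
  expect_equal(scale01PerGene(S), S, tolerance = 1e-12)
  expect_warning(C <- scale01PerGene(cbind(a = 1:4, b = rep(2, 4))), "0.5")
  expect_identical(C[, "b"], rep(0.5, 4))
})

test_that("cohort reference-mean correction zeroes the uninfected means", {
  ed <- generateCohortData(cohortSpec(nGenes = 50, seed = 53))
  out <- cohortUninfectedMeanCorrect(ed)
  X <- exprsMatrix(out)
  ph <- phenotype(ed)
  co <- cohort(ed)
  for (lev in levels(co)) {
    mu <- colMeans(X[co == lev & ph == 0L, , drop = FALSE])
    expect_true(all(abs(mu) < 1e-12))
  }
  ## within-cohort group contrast untouched (shift invariance)
  X0 <- exprsMatrix(ed)
  for (lev in levels(co)) {
    i <- co == lev & ph == 1L
    u <- co == lev & ph == 0L
    d0 <- colMeans(X0[i, , drop = FALSE]) - colMeans(X0[u, , drop = FALSE])
    d1 <- colMeans(X[i, , drop = FALSE]) - colMeans(X[u, , drop = FALSE])
    expect_equal(d1, d0, tolerance = 1e-12)
  }
})

test_that("cohort correction pools cross-cohort uninfected variance downward", {
  ed <- generateCohortData(cohortSpec(nGenes = 200, batchShiftSd = 1,
                                      seed = 54))
  ph <- phenotype(ed)
  before <- exprsMatrix(ed)[ph == 0L, ]
  after <- exprsMatrix(cohortUninfectedMeanCorrect(ed))[ph == 0L, ]
  expect_lt(median(apply(after, 2, var)), median(apply(before, 2, var)))
})

test_that("cohort correction names a cohort without uninfected samples", {
  X <- matrix(rnorm(40), 10, 4)
  co <- rep(c("early", "late"), each = 5)
  mask <- c(TRUE, rep(FALSE, 9))
  expect_error(cohortUninfectedMeanCorrect(X, co, mask), "late")
})

test_that("batch correction matches the sva reference implementation", {
  library(sva)
  set.seed(55)
  n <- 30
  g <- 20
  batch <- rep(c("a", "b"), each = 15)
  ph <- rep(c(0L, 1L, 0L, 1L, 0L, 1L), 5)
  X <- matrix(rnorm(n * g), n, g) +
    outer(as.integer(batch == "b"), rnorm(g, sd = 1))
  refRun <- function(mod) {
    t(suppressMessages(ComBat(t(X), batch = batch, mod = mod,
                              par.prior = TRUE)))
  }
  mine <- combatCorrect(X, batches = batch, covariates = ph)
  ref <- refRun(model.matrix(~ph))
  expect_lt(sqrt(mean((mine - ref)^2)), 1e-6)

  mine0 <- combatCorrect(X, batches = batch, covariates = NULL)
  ref0 <- refRun(NULL)
  expect_lt(sqrt(mean((mine0 - ref0)^2)), 1e-6)
})

test_that("batch correction shrinks toward a no-op without batch effects", {
  set.seed(56)
  X <- matrix(rnorm(40 * 200), 40, 200)
  batch <- rep(c("a", "b"), each = 20)
  out <- combatCorrect(X, batches = batch)
  rmsPerGene <- sqrt(colMeans((out - X)^2))
  expect_lt(mean(rmsPerGene), 0.1)
})

test_that("batch correction removes most of an injected location shift", {
  set.seed(57)
  X <- matrix(rnorm(60 * 300), 60, 300)
  batch <- rep(c("a", "b"), each = 30)
  gamma <- rnorm(300, sd = 1.5)
  X[batch == "b", ] <- sweep(X[batch == "b", ], 2, gamma, "+")
  out <- combatCorrect(X, batches = batch)
  gap <- function(M) {
    abs(colMeans(M[batch == "b", ]) - colMeans(M[batch == "a", ]))
  }
  expect_gt(mean(1 - gap(out) / gap(X)), 0.9)
})

test_that("batch correction validates its design", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(combatCorrect(X, batches = rep("a", 10)), "2 batches")
  ## covariate confounded with batch -> rank-deficient design
  expect_error(combatCorrect(X, batches = rep(c("a", "b"), each = 5),
                             covariates = rep(c(0, 1), each = 5)),
               "rank")
})

test_that("batch corrections cut within-group variance, not group contrast", {
  cs <- cohortSpec(cohorts = data.frame(name = c("A", "B", "C"),
                                        nInfected = c(17, 17, 16),
                                        nUninfected = c(17, 17, 16)),
                   nGenes = 400, batchShiftSd = 1, nSignalGenes = 50,
                   effectSize = 2, seed = 58)
  ed <- generateCohortData(cs, nullPhenotype = FALSE)
  X <- exprsMatrix(ed)
  ph <- phenotype(ed)
  wgVar <- function(M) {
    (apply(M[ph == 1L, ], 2, var) + apply(M[ph == 0L, ], 2, var)) / 2
  }
  groupDiff <- function(M) {
    colMeans(M[ph == 1L, , drop = FALSE]) -
      colMeans(M[ph == 0L, , drop = FALSE])
  }
  for (method in c("cohort_uninfected_mean", "combat")) {
    Y <- exprsMatrix(applyPreprocessing(ed, method))
    expect_lt(median(wgVar(Y)), median(wgVar(X)))
    relChange <- median(abs(groupDiff(Y) - groupDiff(X))) /
      median(abs(groupDiff(X)))
    expect_lt(relChange, 0.05)
  }
})

test_that("the dispatcher is exact for 'none' and rejects unknown methods", {
  set.seed(59)
  M <- matrix(rnorm(50), 10, 5)
  expect_identical(applyPreprocessing(M, preprocessSpec("none")), M)
  expect_identical(applyPreprocessing(M, "center_global"), centerGlobal(M))
  expect_error(preprocessSpec("quantile"), "arg")
})

test_that("phenotype-blind transforms ignore the phenotype argument", {
  ed <- generateCohortData(cohortSpec(nGenes = 30, seed = 60))
  ph <- phenotype(ed)
  phPerm <- permutePhenotype(ph, 99)
  for (method in c("none", "center_global", "standardize_per_gene",
                   "scale01_per_gene")) {
    a <- applyPreprocessing(exprsMatrix(ed), method, phenotype = ph)
    b <- applyPreprocessing(exprsMatrix(ed), method, phenotype = phPerm)
    expect_identical(a, b)
  }
})

test_that("all methods preserve shape and ordering", {
  ed <- generateCohortData(cohortSpec(nGenes = 25, seed = 61))
  for (method in c("none", "center_global", "standardize_per_gene",
                   "scale01_per_gene", "cohort_uninfected_mean", "combat")) {
    out <- applyPreprocessing(ed, method)
    expect_identical(dim(out), dim(ed))
    expect_identical(probeIds(out), probeIds(ed))
    expect_identical(sampleIds(out), sampleIds(ed))
  }
})
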