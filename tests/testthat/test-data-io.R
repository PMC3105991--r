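test_that("expression TSV round-trips exactly in both orientations", {
  M <- makeToyMatrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTsv(M, path)
  ed <- readExpressionTsv(path)
  expect_identical(exprsMatrix(ed), M)

  writeExpressionTsv(M, path, orientation = "genesInRows")
  edT <- readExpressionTsv(path, orientation = "genesInRows")
  expect_identical(exprsMatrix(edT), M)

  ## labels can be attached on load
  ed2 <- readExpressionTsv(path, orientation = "genesInRows",
                           phenotype = c(0, 1, 1), cohort = c("a", "a", "b"))
  expect_identical(phenotype(ed2), c(0L, 1L, 1L))
  expect_identical(levels(cohort(ed2)), c("a", "b"))
})

test_that("malformed expression files fail with named errors", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("id\tgA\tgB", "s1\t1.5\tNA", "s2\t2\t3"), path)
  expect_error(readExpressionTsv(path), "missing value.*gB.*s1")

  writeLines(c("id\tgA\tgB", "s1\t1.5\tx7", "s2\t2\t3"), path)
  expect_error(readExpressionTsv(path), "non-numeric.*gB.*s1")

  writeLines(c("id\tgA\tgB", "s1\t1\t2", "s1\t3\t4"), path)
  expect_error(readExpressionTsv(path), "duplicate row")

  writeLines(c("id\tgA\tgA", "s1\t1\t2", "s2\t3\t4"), path)
  expect_error(readExpressionTsv(path), "duplicate column")

  writeLines(c("id\tgA\tgB", "s1\t1", "s2\t3\t4"), path)
  expect_error(readExpressionTsv(path))
})

test_that("the Series Matrix parser extracts table and characteristics", {
  path <- system.file("extdata", "synthetic_series_matrix.txt",
                      package = "TieSig")
  ed <- readGeoSeriesMatrix(path)
  expect_identical(dim(exprsMatrix(ed)), c(5L, 4L))
  expect_identical(probeIds(ed), paste0("probe_", 1:4))
  expect_identical(sampleIds(ed), paste0("GSM", 1:5))
  expect_identical(exprsMatrix(ed)["GSM2", "probe_1"], 8.5)
  expect_null(phenotype(ed))
  chars <- S4Vectors::metadata(ed)$characteristics
  expect_identical(chars$characteristics_ch1,
                   paste("infection:", c("none", "hrv", "none", "rsv",
                                         "none")))

  broken <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"x\"", "\"ID_REF\"\t\"GSM1\""), broken)
  expect_error(readGeoSeriesMatrix(broken), "delimiters")
})

test_that("signature CSV round-trips, deduplicates and checks gene ids", {
  ss <- SignatureSet(list(c("p3", "p1"), c("p2", "p4"), "p5"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeSignatureSet(ss, path)
  back <- readSignatureSet(path)
  expect_identical(sigKeys(back), sigKeys(ss))

  ## empty set: header-only file
  writeSignatureSet(SignatureSet(list()), path)
  expect_identical(readLines(path), "signature_genes")
  expect_length(readSignatureSet(path), 0)

  ## duplicate rows are dropped with a warning
  writeLines(c("signature_genes", "p1,p2", "p2,p1"), path)
  expect_warning(dd <- readSignatureSet(path), "duplicate")
  expect_length(dd, 1)

  ## unknown probes against a dataset are reported
  ed <- ExpressionDataset(makeToyMatrix())
  writeLines(c("signature_genes", "gA,zz9"), path)
  expect_warning(readSignatureSet(path, data = ed), "zz9")

  writeLines(c("p1,p2"), path)
  expect_error(readSignatureSet(path), "header")
})

test_that("a simulate+discover pipeline recovers the ground truth end to end", {
  outDir <- withr::local_tempdir()
  config <- list(stages = c("simulate", "discover", "summarize"),
                 seed = 42,
                 outDir = outDir,
                 simulate = list(type = "tied", nSamples = 400, nGenes = 40,
                                 classSizes = c(2, 2)),
                 discover = list())
  res <- runPipeline(config)

  sigs <- readSignatureSet(file.path(outDir, "signatures.csv"))
  truth <- readSignatureSet(file.path(outDir, "ground_truth_signatures.csv"))
  expect_length(sigs, 4)
  expect_identical(sigKeys(sigs), sigKeys(truth))

  summaryTab <- read.delim(file.path(outDir, "signature_summary.tsv"))
  expect_true(all(c("gene", "percent") %in% names(summaryTab)))

  log <- jsonlite::read_json(file.path(outDir, "run_log.json"),
                             simplifyVector = TRUE)
  expect_identical(log$seed, 42L)
  expect_identical(log$stages, c("simulate", "discover", "summarize"))

  ## idempotence: a re-run reproduces byte-identical artifacts
  before <- vapply(list.files(outDir, full.names = TRUE), tools::md5sum,
                   character(1))
  runPipeline(config)
  after <- vapply(list.files(outDir, full.names = TRUE), tools::md5sum,
                  character(1))
  expect_identical(before, after)
})

test_that("pipeline configs are validated", {
  outDir <- withr::local_tempdir()
  expect_error(runPipeline(list(stages = "transmogrify", outDir = outDir)),
               "unknown stage")
  expect_error(runPipeline(list(outDir = outDir)), "at least one stage")
  expect_error(runPipeline(list(stages = "discover", outDir = outDir)),
               "failed")
})

test_that("audit and evaluate stages emit their artifacts", {
  outDir <- withr::local_tempdir()
  config <- list(stages = c("simulate", "audit"),
                 seed = 7,
                 outDir = outDir,
                 simulate = list(type = "cohort", nGenes = 120),
                 audit = list(method = "cohort_uninfected_mean",
                              nPermutations = 15))
  res <- runPipeline(config)
  tab <- read.delim(file.path(outDir, "audit.tsv"))
  expect_identical(tab$method, "cohort_uninfected_mean")
  counts <- read.csv(file.path(outDir, "audit_counts.csv"))
  expect_identical(nrow(counts), 15L)
  expect_equal(tab$mean, mean(counts$count), tolerance = 1e-10)
})
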