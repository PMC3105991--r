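## Readers and writers for the package's plain-text interchange formats
## (delimited expression matrices, GEO Series Matrix text, signature CSV)
## and the configuration-driven pipeline runner.

#' Read a delimited expression matrix
#'
#' Reads a rectangular TSV/CSV with a header row and an id column into an
#' \code{\link{ExpressionDataset}}.  Values must be finite reals; missing
#' values, ragged rows, duplicate ids and non-numeric cells are rejected
#' with named errors (the source matrices are complete after normalization,
#' so nothing is imputed and values are never transformed on load).
#'
#' @param path file path.
#' @param orientation \code{"samplesInRows"} (default) or
#'   \code{"genesInRows"}.
#' @param sep field separator (default tab).
#' @param phenotype,cohort optional per-sample labels attached after
#'   loading.
#' @return an \code{\link{ExpressionDataset}}.
#' @export
readExpressionTsv <- function(path, orientation = c("samplesInRows",
                                                    "genesInRows"),
                              sep = "\t", phenotype = NULL, cohort = NULL) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          fill = FALSE, quote = "\"")
  rowIds <- as.character(df[[1]])
  if (anyDuplicated(rowIds))
    stop("duplicate row id(s): ",
         paste(unique(rowIds[duplicated(rowIds)]), collapse = ", "))
  colIds <- colnames(df)[-1]
  if (anyDuplicated(colIds))
    stop("duplicate column id(s): ",
         paste(unique(colIds[duplicated(colIds)]), collapse = ", "))
  df <- df[, -1, drop = FALSE]
  colnames(df) <- colIds
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop("non-numeric value in column '", colnames(df)[j], "', row '",
           rowIds[bad], "'")
    }
    if (anyNA(v))
      stop("missing value in column '", colnames(df)[j], "', row '",
           rowIds[which(is.na(v))[1]], "'")
  }
  M <- as.matrix(df)
  rownames(M) <- rowIds
  if (orientation == "genesInRows")
    M <- t(M)
  ExpressionDataset(M, phenotype = phenotype, cohort = cohort,
                    metadata = list(source = path))
}

#' Write an expression matrix as TSV
#'
#' @param data an \code{\link{ExpressionDataset}} or samples-by-genes
#'   matrix.
#' @param path output file path.
#' @param orientation orientation of the written matrix.
#' @return invisibly, \code{path}.
#' @export
writeExpressionTsv <- function(data, path,
                               orientation = c("samplesInRows",
                                               "genesInRows")) {
  orientation <- match.arg(orientation)
  M <- .getX(data)
  if (orientation == "genesInRows")
    M <- t(M)
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a GEO Series Matrix text file
#'
#' Parses the plain-text Series Matrix layout: the expression table between
#' the \code{!series_matrix_table_begin} / \code{!series_matrix_table_end}
#' markers plus the \code{!Sample_*} metadata lines.  Sample
#' characteristics are exposed verbatim; mapping them to a phenotype or
#' cohort is left to the caller (supply the derived labels via
#' \code{\link{phenotype<-}} / \code{\link{cohort<-}}).
#'
#' @param path file path.
#' @return an \code{\link{ExpressionDataset}} (no phenotype attached) whose
#'   metadata holds a \code{characteristics} data.frame, one row per
#'   sample.
#' @export
readGeoSeriesMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beginAt <- grep("^!series_matrix_table_begin", lines)
  endAt <- grep("^!series_matrix_table_end", lines)
  if (length(beginAt) != 1L || length(endAt) != 1L || endAt <= beginAt)
    stop("not a Series Matrix file: table delimiters missing")
  tableLines <- lines[(beginAt + 1L):(endAt - 1L)]
  tc <- textConnection(tableLines)
  on.exit(close(tc))
  tab <- utils::read.table(tc, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "\"", comment.char = "")
  probes <- as.character(tab[[1]])
  if (anyDuplicated(probes))
    stop("duplicate probe id(s) in series matrix table")
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- probes

  metaLines <- grep("^!Sample_", lines, value = TRUE)
  chars <- list()
  for (ln in metaLines) {
    parts <- strsplit(ln, "\t")[[1]]
    key <- sub("^!Sample_", "", parts[1])
    vals <- gsub("^\"|\"$", "", parts[-1])
    nm <- key
    k <- 1L
    while (nm %in% names(chars)) {
      k <- k + 1L
      nm <- paste0(key, ".", k)
    }
    chars[[nm]] <- vals
  }
  characteristics <- if (length(chars))
    as.data.frame(chars, stringsAsFactors = FALSE)
  else data.frame()
  ExpressionDataset(t(M),
                    metadata = list(source = path,
                                    characteristics = characteristics))
}

#' Write and read signature collections as CSV
#'
#' One signature per row, comma-separated gene/probe ids, beneath a single
#' header line.  Round-trips preserve the canonicalized sets exactly;
#' duplicate rows on read are dropped with a warning, and gene ids unknown
#' to a supplied dataset are reported with a warning.
#'
#' @param sigs a \code{\link{SignatureSet}}.
#' @param path file path.
#' @param data optional \code{\link{ExpressionDataset}} used to check gene
#'   ids on read.
#' @return \code{writeSignatureSet} returns \code{path} invisibly;
#'   \code{readSignatureSet} returns a \code{\link{SignatureSet}}.
#' @export
writeSignatureSet <- function(sigs, path) {
  stopifnot(methods::is(sigs, "SignatureSet"))
  lines <- c("signature_genes",
             vapply(signatures(sigs), paste, character(1), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSignatureSet
#' @export
readSignatureSet <- function(path, data = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || lines[1] != "signature_genes")
    stop("not a signature CSV: header line missing")
  lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  sigs <- lapply(strsplit(lines, ","), function(g) sort(unique(trimws(g))))
  keys <- vapply(sigs, paste, character(1), collapse = ",")
  if (anyDuplicated(keys)) {
    warning(sum(duplicated(keys)), " duplicate signature row(s) dropped")
    sigs <- sigs[!duplicated(keys)]
  }
  if (!is.null(data)) {
    unknown <- setdiff(unique(unlist(sigs)), probeIds(data))
    if (length(unknown))
      warning("gene id(s) absent from dataset: ",
              paste(unknown, collapse = ", "))
  }
  SignatureSet(sigs)
}

#' Write a signature participation summary as TSV
#'
#' Two columns: probe id and the percentage of signatures the probe appears
#' in, sorted by decreasing participation.
#'
#' @inheritParams writeSignatureSet
#' @return invisibly, \code{path}.
#' @export
writeSignatureSummary <- function(sigs, path) {
  s <- summarizeSignatures(sigs)
  utils::write.table(s$participation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## ----- pipeline runner ----------------------------------------------------

.pipelineStages <- c("simulate", "preprocess", "discover", "summarize",
                     "redundancy", "audit", "evaluate")

#' Run a configured analysis pipeline
#'
#' Executes a list of stages against one dataset and writes every artifact
#' (matrices, signature CSVs, summaries, audit tables, JSON reports) plus a
#' machine-readable run log into \code{outDir}.  Re-running with the same
#' configuration reproduces identical outputs: all randomness flows from the
#' single top-level seed and the log carries no volatile fields.
#'
#' Config fields: \code{stages} (subset of \code{simulate}, \code{preprocess},
#' \code{discover}, \code{summarize}, \code{redundancy}, \code{audit},
#' \code{evaluate}), \code{seed}, \code{outDir}, \code{input} (path of a
#' samples-in-rows TSV, with optional \code{phenotypePath} /
#' \code{cohortPath} one-label-per-line files; unnecessary when
#' \code{simulate} runs first), \code{simulate} (\code{type} \code{"tied"}
#' or \code{"cohort"} plus generator arguments), \code{preprocess}
#' (\code{method}), \code{discover} (\code{alpha}, \code{maxK},
#' \code{maxRemovalCardinality}), \code{redundancy} / \code{evaluate}
#' (\code{cvFolds}, \code{cvRepeats}), \code{audit} (\code{method},
#' \code{nPermutations}, \code{fdrQ}).
#'
#' @param config named list, or path of a JSON file holding one.
#' @return invisibly, a list with the in-memory stage results and the paths
#'   written.
#' @export
runPipeline <- function(config) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || !length(stages))
    stop("config must name at least one stage")
  unknown <- setdiff(stages, .pipelineStages)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  outDir <- config$outDir
  if (is.null(outDir))
    stop("config must name outDir")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  data <- NULL
  results <- list()
  paths <- character(0)
  emit <- function(p) paths <<- c(paths, p)

  loadInput <- function() {
    inp <- config$input
    if (is.null(inp))
      stop("no simulate stage and no input configured")
    ph <- if (!is.null(inp$phenotypePath))
      as.integer(readLines(inp$phenotypePath))
    co <- if (!is.null(inp$cohortPath)) readLines(inp$cohortPath)
    readExpressionTsv(inp$path, phenotype = ph, cohort = co)
  }

  for (stage in stages) {
    res <- tryCatch(switch(stage,
      simulate = {
        sc <- config$simulate
        type <- if (is.null(sc$type)) "tied" else sc$type
        if (type == "tied") {
          args <- sc[setdiff(names(sc), "type")]
          args$seed <- seed
          sp <- do.call(equivalenceSpec, args)
          gen <- generateTiedLike(sp)
          data <- gen$data
          emit(writeExpressionTsv(gen$data, file.path(outDir,
                                                      "expression.tsv")))
          emit(writeSignatureSet(gen$groundTruth,
                                 file.path(outDir,
                                           "ground_truth_signatures.csv")))
        } else if (type == "cohort") {
          args <- sc[setdiff(names(sc), "type")]
          args$seed <- seed
          sp <- do.call(cohortSpec, args)
          data <- generateCohortData(sp)
          emit(writeExpressionTsv(data, file.path(outDir,
                                                  "expression.tsv")))
        } else {
          stop("unknown simulate type: ", type)
        }
        labels <- data.frame(sample = sampleIds(data),
                             phenotype = phenotype(data))
        if (!is.null(cohort(data)))
          labels$cohort <- as.character(cohort(data))
        labPath <- file.path(outDir, "labels.tsv")
        utils::write.table(labels, labPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(labPath)
        data
      },
      preprocess = {
        if (is.null(data)) data <- loadInput()
        spec <- preprocessSpec(config$preprocess$method)
        data <- applyPreprocessing(data, spec)
        emit(writeExpressionTsv(data, file.path(outDir,
                                                "preprocessed.tsv")))
        data
      },
      discover = {
        if (is.null(data)) data <- loadInput()
        dc <- config$discover
        base <- gllParams(alpha = if (is.null(dc$alpha)) 1e-5 else dc$alpha,
                          maxK = if (is.null(dc$maxK)) 1L else dc$maxK)
        tp <- tieStarParams(
          maxRemovalCardinality = if (is.null(dc$maxRemovalCardinality)) 5L
                                  else dc$maxRemovalCardinality,
          baseParams = base)
        sigs <- tieStar(data, tp)
        emit(writeSignatureSet(sigs, file.path(outDir, "signatures.csv")))
        sigs
      },
      summarize = {
        sigs <- results$discover
        if (is.null(sigs))
          sigs <- readSignatureSet(file.path(outDir, "signatures.csv"))
        emit(writeSignatureSummary(sigs,
                                   file.path(outDir,
                                             "signature_summary.tsv")))
        summarizeSignatures(sigs)
      },
      redundancy = {
        if (is.null(data)) data <- loadInput()
        sigs <- results$discover
        if (is.null(sigs))
          sigs <- readSignatureSet(file.path(outDir, "signatures.csv"))
        rc <- config$redundancy
        ep <- evalParams(cvFolds = if (is.null(rc$cvFolds)) 10L
                                   else rc$cvFolds,
                         cvRepeats = if (is.null(rc$cvRepeats)) 10L
                                     else rc$cvRepeats,
                         seed = seed)
        rep1 <- assessRedundancy(signatures(sigs)[[1]], data, ep)
        out <- file.path(outDir, "redundancy.json")
        jsonlite::write_json(rep1[c("redundant", "retained",
                                    "aucOriginal", "aucReduced",
                                    "delongP")],
                             out, auto_unbox = TRUE, digits = NA)
        emit(out)
        rep1
      },
      audit = {
        if (is.null(data)) data <- loadInput()
        ac <- config$audit
        method <- if (is.null(ac$method)) "none" else ac$method
        res <- auditBias(data, method,
                         nPermutations = if (is.null(ac$nPermutations)) 200L
                                         else ac$nPermutations,
                         fdrQ = if (is.null(ac$fdrQ)) 0.2 else ac$fdrQ,
                         seed = seed)
        tabPath <- file.path(outDir, "audit.tsv")
        utils::write.table(
          data.frame(method = method, mean = res$mean, sd = res$sd,
                     stderr = res$stderr, lower95 = res$interval[1],
                     upper95 = res$interval[2]),
          tabPath, sep = "\t", quote = FALSE, row.names = FALSE)
        emit(tabPath)
        cntPath <- file.path(outDir, "audit_counts.csv")
        utils::write.table(data.frame(permutation = seq_along(res$counts),
                                      count = res$counts),
                           cntPath, sep = ",", quote = FALSE,
                           row.names = FALSE)
        emit(cntPath)
        res
      },
      evaluate = {
        if (is.null(data)) data <- loadInput()
        sigs <- results$discover
        if (is.null(sigs))
          sigs <- readSignatureSet(file.path(outDir, "signatures.csv"))
        ec <- config$evaluate
        ep <- evalParams(cvFolds = if (is.null(ec$cvFolds)) 10L
                                   else ec$cvFolds,
                         cvRepeats = if (is.null(ec$cvRepeats)) 10L
                                     else ec$cvRepeats,
                         seed = seed)
        perf <- repeatedCvAuc(data, signatures(sigs)[[1]], ep)
        out <- file.path(outDir, "evaluation.json")
        jsonlite::write_json(list(meanAuc = perf$meanAuc,
                                  perRepeat = perf$perRepeat),
                             out, auto_unbox = TRUE, digits = NA)
        emit(out)
        perf
      }),
      error = function(e) {
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    results[[stage]] <- res
  }

  log <- list(package = "TieSig",
              version = as.character(utils::packageVersion("TieSig")),
              seed = seed,
              stages = stages,
              config = config[setdiff(names(config), c("stages", "outDir",
                                                       "seed"))],
              outputs = basename(paths))
  logPath <- file.path(outDir, "run_log.json")
  jsonlite::write_json(log, logPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(results = results, paths = c(paths, logPath)))
}
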