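#' Descriptors of the six GEO HCC cohorts
#'
#' Study-design descriptors of the six public hepatocellular-carcinoma
#' expression cohorts the method was developed on: accession, platform,
#' preprocessing mode, sample counts per group, pairing status, the
#' reported positive-pair count Q, and the number of decimals each
#' cohort's PPPN is conventionally reported at.
#'
#' @return `data.frame` with one row per cohort and columns `dataset`,
#'   `platform`, `mode`, `n_tumor`, `n_normal`, `paired`, `q_reported`,
#'   `t_digits`.
#' @export
hccStudyDatasets <- function() {
    data.frame(
        dataset = c("GSE5093", "GSE3500", "GSE4024",
                    "GSE1898", "GSE65484", "GSE65485"),
        platform = c("microarray", "microarray", "microarray",
                     "microarray", "aCGH", "NGS"),
        mode = c("paired-channels", "reference-ratio", "paired-channels",
                 "paired-channels", "log-inverse", "fpkm"),
        n_tumor = c(20L, 105L, 98L, 182L, 14L, 50L),
        n_normal = c(20L, 76L, 98L, 182L, 14L, 5L),
        paired = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
        q_reported = c(343L, 5150L, 5283L, 19543L, 146L, 238L),
        t_digits = c(0L, 0L, 0L, 0L, 1L, 1L),
        stringsAsFactors = FALSE)
}

.PIPELINE_MODES <- c("paired-channels", "reference-ratio",
                     "precomputed-matrix", "fpkm", "log-inverse")

#' Pipeline configuration
#'
#' Validates the configuration driving [runPipeline()]. `mode` selects the
#' preprocessing route: `"paired-channels"` and `"reference-ratio"` start
#' from two-channel spot tables; `"precomputed-matrix"` and `"fpkm"` take
#' a non-negative matrix as is; `"log-inverse"` first undoes a log
#' transform.
#'
#' @param datasetId label used in outputs and logs.
#' @param mode one of `"paired-channels"`, `"reference-ratio"`,
#'   `"precomputed-matrix"`, `"fpkm"`, `"log-inverse"`.
#' @param paired whether matched tumor/normal pairs exist (enables PPS).
#' @param matrixPath,metadataPath input files for the matrix modes.
#' @param spotPaths named list/vector of spot-table paths for the
#'   two-channel modes; for `"paired-channels"` each file is one
#'   tumor/normal hybridization; for `"reference-ratio"` names give the
#'   sample ids and `sampleGroups` their groups.
#' @param sampleGroups named character vector (sample id -> group) for
#'   `"reference-ratio"`.
#' @param referenceChannel reference channel (1 or 2) for
#'   `"reference-ratio"`.
#' @param channelGroups channel-to-group assignment for
#'   `"paired-channels"`.
#' @param backgroundFactor well-measured threshold multiple; default 1.5.
#' @param minReplicates replicate filter threshold; default 2.
#' @param logBase base of the deposited log transform; default 2.
#' @param alpha significance level; default 0.05.
#' @return validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(datasetId, mode, paired = FALSE,
                           matrixPath = NULL, metadataPath = NULL,
                           spotPaths = NULL, sampleGroups = NULL,
                           referenceChannel = 1,
                           channelGroups = c(ch1 = "tumor", ch2 = "normal"),
                           backgroundFactor = 1.5, minReplicates = 2L,
                           logBase = 2, alpha = 0.05) {
    mode <- match.arg(mode, .PIPELINE_MODES)
    if (mode %in% c("precomputed-matrix", "fpkm", "log-inverse")) {
        if (is.null(matrixPath) || is.null(metadataPath))
            stop("mode '", mode, "' requires matrixPath and metadataPath",
                 call. = FALSE)
    } else if (is.null(spotPaths)) {
        stop("mode '", mode, "' requires spotPaths", call. = FALSE)
    }
    if (mode == "reference-ratio" && is.null(sampleGroups))
        stop("reference-ratio mode requires sampleGroups", call. = FALSE)
    structure(list(datasetId = datasetId, mode = mode, paired = paired,
                   matrixPath = matrixPath, metadataPath = metadataPath,
                   spotPaths = spotPaths, sampleGroups = sampleGroups,
                   referenceChannel = referenceChannel,
                   channelGroups = channelGroups,
                   backgroundFactor = backgroundFactor,
                   minReplicates = as.integer(minReplicates),
                   logBase = logBase, alpha = alpha),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Field names mirror the arguments of [pipelineConfig()].
#'
#' @param path path to a YAML file.
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    y$channelGroups <- if (is.null(y$channelGroups))
        c(ch1 = "tumor", ch2 = "normal") else unlist(y$channelGroups)
    if (!is.null(y$sampleGroups)) y$sampleGroups <- unlist(y$sampleGroups)
    do.call(pipelineConfig, y)
}

## One spot table -> filtered, background-corrected spots.
.preprocess_spots <- function(path, config) {
    spots <- readTwoChannelTable(path)
    spots <- flagFilter(spots)
    spots <- wellMeasuredFilter(spots, factor = config$backgroundFactor)
    backgroundCorrect(spots)
}

## Assemble per-sample expression vectors (named by gene) into a matrix
## over the union of genes; genes unmeasured in a sample are missing.
.assemble_matrix <- function(vectors) {
    genes <- sort(unique(unlist(lapply(vectors, names))))
    vals <- vapply(vectors, function(v) v[genes], numeric(length(genes)))
    rownames(vals) <- genes
    vals
}

.build_expression_matrix <- function(config) {
    switch(config$mode,
        "precomputed-matrix" = ,
        "fpkm" = readExpressionMatrix(config$matrixPath, config$metadataPath),
        "log-inverse" = inverseLogTransform(
            readExpressionMatrix(config$matrixPath, config$metadataPath),
            base = config$logBase),
        "paired-channels" = {
            vectors <- list(); group <- character(); pid <- character()
            for (i in seq_along(config$spotPaths)) {
                corrected <- .preprocess_spots(config$spotPaths[[i]], config)
                chan <- channelExpression(corrected, config$channelGroups)
                hyb <- if (!is.null(names(config$spotPaths)))
                    names(config$spotPaths)[i] else sprintf("hyb%02d", i)
                for (g in colnames(chan)) {
                    vectors[[paste(hyb, g, sep = "_")]] <- chan[, g]
                    group <- c(group, g); pid <- c(pid, hyb)
                }
            }
            ExpressionMatrix(.assemble_matrix(vectors), group = group,
                             pairId = pid)
        },
        "reference-ratio" = {
            vectors <- lapply(config$spotPaths, function(p)
                ratioExpression(.preprocess_spots(p, config),
                                referenceChannel = config$referenceChannel))
            ids <- names(config$spotPaths)
            if (is.null(ids))
                stop("reference-ratio mode requires named spotPaths",
                     call. = FALSE)
            ExpressionMatrix(.assemble_matrix(vectors),
                             group = unname(config$sampleGroups[ids]))
        })
}

#' Run the full diversity pipeline on one dataset
#'
#' Read -> preprocess (mode-dependent) -> replicate filter -> imputation ->
#' per-sample SDIG -> pair statistics -> one-sided Welch test, with
#' stage-by-stage gene/sample counts reported via `message()`. When
#' `outDir` is given, writes `diversity.tsv` (per-sample SDIG),
#' `summary.tsv` (one report row plus mean-T row) and `boxplot.tsv`
#' (per-group five-number summaries). Deterministic given its inputs.
#'
#' @param config a [pipelineConfig()], or a path to a YAML file for
#'   [readPipelineConfig()].
#' @param outDir optional output directory, created if absent.
#' @return the [datasetReport()] list, invisibly when writing files.
#' @export
runPipeline <- function(config, outDir = NULL) {
    if (is.character(config)) config <- readPipelineConfig(config)
    stopifnot(inherits(config, "PipelineConfig"))
    em <- .build_expression_matrix(config)
    message(sprintf("[%s] assembled matrix: %d genes x %d samples",
                    config$datasetId, nrow(em), ncol(em)))
    em <- replicateFilter(em, minReplicates = config$minReplicates)
    em <- imputeMissing(em)
    message(sprintf("[%s] after filtering/imputation: %d genes",
                    config$datasetId, nrow(em)))
    report <- datasetReport(em, paired = config$paired,
                            datasetId = config$datasetId,
                            alpha = config$alpha)
    if (!is.null(outDir)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        utils::write.table(as.data.frame(report$diversity),
                           file.path(outDir, "diversity.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        writeSummaryTable(report$summary, file.path(outDir, "summary.tsv"))
        utils::write.table(report$boxplot,
                           file.path(outDir, "boxplot.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        return(invisible(report))
    }
    report
}
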