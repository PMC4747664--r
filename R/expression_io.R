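#' Default column-name mapping for two-channel spot tables
#'
#' GEO two-channel sample tables conventionally carry the quantities used by
#' background correction under upper-case headers; the mapping is
#' config-driven because platforms differ.
#'
#' @return named character vector mapping internal field names to file
#'   column headers.
#' @export
defaultSpotDialect <- function() {
    c(spot_id = "ID_REF", gene_id = "IDENTIFIER",
      ch1i_mean = "CH1I_MEAN", ch1b_median = "CH1B_MEDIAN",
      ch2i_mean = "CH2I_MEAN", ch2b_median = "CH2B_MEDIAN",
      flag = "FLAG")
}

.read_delim <- function(path, sep = "\t", header = TRUE) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.table(path, sep = sep, header = header,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      quote = "\"", comment.char = "", na.strings = c("", "NA"))
}

#' Read a two-channel microarray spot table
#'
#' Parses one hybridization's spot table into a
#' [TwoChannelSpotTable-class]. Rows whose intensity or background fields
#' fail numeric parsing are rejected (never silently dropped: the rejected
#' count is reported via `message()`); a flag value outside \{0, -50, -100\}
#' is a format error naming the offending row.
#'
#' @param path path to a delimited spot table with a header row.
#' @param dialect named character vector mapping the internal fields
#'   (`spot_id`, `gene_id`, `ch1i_mean`, `ch1b_median`, `ch2i_mean`,
#'   `ch2b_median`, `flag`) to file column headers; defaults to
#'   [defaultSpotDialect()].
#' @param sep field separator.
#' @return a [TwoChannelSpotTable-class].
#' @export
readTwoChannelTable <- function(path, dialect = defaultSpotDialect(),
                                sep = "\t") {
    raw <- .read_delim(path, sep = sep)
    missing_cols <- setdiff(unname(dialect[.SPOT_FIELDS]), colnames(raw))
    if (length(missing_cols))
        stop("spot table ", path, " is missing mapped column(s): ",
             paste(missing_cols, collapse = ", "), call. = FALSE)
    tab <- raw[, unname(dialect[.SPOT_FIELDS]), drop = FALSE]
    colnames(tab) <- .SPOT_FIELDS

    num_fields <- c("ch1i_mean", "ch1b_median", "ch2i_mean", "ch2b_median")
    for (col in num_fields)
        tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
    bad_num <- Reduce(`|`, lapply(tab[num_fields], is.na))
    if (any(bad_num)) {
        message(sprintf("readTwoChannelTable: rejected %d of %d rows with unparseable numeric fields",
                        sum(bad_num), nrow(tab)))
        tab <- tab[!bad_num, , drop = FALSE]
    }

    fl <- suppressWarnings(as.numeric(tab$flag))
    bad_flag <- which(is.na(fl) | !(fl %in% .VALID_FLAGS))
    if (length(bad_flag))
        stop(sprintf("invalid flag value '%s' at data row %d of %s (allowed: %s)",
                     tab$flag[bad_flag[1]], bad_flag[1], path,
                     paste(.VALID_FLAGS, collapse = ", ")), call. = FALSE)
    tab$flag <- as.integer(fl)
    TwoChannelSpotTable(tab)
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is genes-in-rows, samples-in-columns, first column gene
#' identifiers, header row sample identifiers; empty cells become missing
#' values (`NA`), never 0. The metadata file must map every sample column
#' to a `group` (`tumor` / `normal`) and may give a `pair_id`.
#'
#' @param path path to the delimited matrix file.
#' @param metadataPath path to a delimited table with columns `sample_id`,
#'   `group` and optionally `pair_id`.
#' @param sep field separator for both files.
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, metadataPath, sep = "\t") {
    raw <- .read_delim(path, sep = sep)
    gene_ids <- as.character(raw[[1]])
    vals <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- gene_ids

    neg <- which(!is.na(vals) & vals < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative expression value at gene '%s', sample '%s'",
                     rownames(vals)[neg[1, 1]], colnames(vals)[neg[1, 2]]),
             call. = FALSE)

    meta <- .read_delim(metadataPath, sep = sep)
    if (!all(c("sample_id", "group") %in% colnames(meta)))
        stop("metadata must have columns 'sample_id' and 'group'",
             call. = FALSE)
    absent <- setdiff(colnames(vals), meta$sample_id)
    if (length(absent))
        stop("sample(s) absent from metadata: ",
             paste(absent, collapse = ", "), call. = FALSE)
    meta <- meta[match(colnames(vals), meta$sample_id), , drop = FALSE]
    bad <- setdiff(stats::na.omit(unique(meta$group)), .GROUP_LEVELS)
    if (length(bad))
        stop(sprintf("unrecognized group label '%s' (allowed: %s)",
                     bad[1], paste(.GROUP_LEVELS, collapse = ", ")),
             call. = FALSE)
    ExpressionMatrix(vals, group = meta$group,
                     pairId = if ("pair_id" %in% colnames(meta))
                         meta$pair_id else NULL)
}

#' Read a GEO series-matrix style file
#'
#' Minimal reader for the series-matrix text dialect: `!`-prefixed metadata
#' lines and a tab-delimited value block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Group and
#' pairing are left unset for the caller to supply. If a metadata line
#' indicates log2-transformed values, the matrix is returned unchanged with
#' `metadata(x)$log_scale = TRUE` as a hint that
#' [inverseLogTransform()] should be applied downstream.
#'
#' @param path path to a (plain-text, uncompressed) series-matrix file.
#' @return an [ExpressionMatrix-class] with unset group labels.
#' @export
readSeriesMatrix <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    lines <- readLines(path, warn = FALSE)
    beg <- grep("^!series_matrix_table_begin", lines, ignore.case = TRUE)
    fin <- grep("^!series_matrix_table_end", lines, ignore.case = TRUE)
    if (!length(beg) || !length(fin) || fin[1] <= beg[1] + 1L)
        stop("not a series-matrix file (missing table begin/end markers): ",
             path, call. = FALSE)
    block <- lines[(beg[1] + 1L):(fin[1] - 1L)]
    tab <- utils::read.table(text = block, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             quote = "\"", na.strings = c("", "NA", "null"))
    vals <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- as.character(tab[[1]])
    em <- ExpressionMatrix(vals)
    meta_lines <- lines[seq_len(beg[1] - 1L)]
    if (any(grepl("log2|log 2|log-2", meta_lines, ignore.case = TRUE)))
        metadata(em)$log_scale <- TRUE
    em
}

#' Write a Table-2-style dataset summary
#'
#' One row per dataset (dataset id, pairing status, PPS or NA, Q, T, group
#' mean SDIGs, P value) followed by a final row holding the mean of the T
#' column. Numeric cells are written at full precision so the file can be
#' re-parsed losslessly.
#'
#' @param rows `data.frame` with columns `dataset`, `structure`, `pps`,
#'   `q`, `t`, `mean_normal`, `mean_tumor`, `p_value`.
#' @param path output path (TSV).
#' @return `path`, invisibly.
#' @export
writeSummaryTable <- function(rows, path) {
    need <- c("dataset", "structure", "pps", "q", "t",
              "mean_normal", "mean_tumor", "p_value")
    if (nrow(rows) > 0 && !all(need %in% colnames(rows)))
        stop("summary rows must have columns: ",
             paste(need, collapse = ", "), call. = FALSE)
    out <- if (nrow(rows)) {
        rows <- rows[, need, drop = FALSE]
        mean_row <- data.frame(dataset = "Mean", structure = NA, pps = NA,
                               q = NA, t = mean(rows$t), mean_normal = NA,
                               mean_tumor = NA, p_value = NA)
        rbind(rows, mean_row)
    } else {
        stats::setNames(data.frame(matrix(nrow = 0, ncol = length(need))),
                        need)
    }
    utils::write.table(format(out, digits = 15, trim = TRUE, nsmall = 0),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Re-read a summary table written by [writeSummaryTable()]
#'
#' @param path path to the TSV file.
#' @return `data.frame` with the dataset rows and the trailing mean row.
#' @export
readSummaryTable <- function(path) {
    tab <- .read_delim(path)
    for (col in c("pps", "q", "t", "mean_normal", "mean_tumor", "p_value"))
        if (col %in% colnames(tab))
            tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
    tab
}
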