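# Programmatic fixtures: all inputs are written to tempfiles at test time.

write_spot_fixture <- function(df, path = tempfile(fileext = ".tsv"),
                               headers = exprDiversity::defaultSpotDialect()) {
    colnames(df) <- unname(headers[colnames(df)])
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

spot_df <- function(ch1i, ch1b, ch2i, ch2b, flag = 0L,
                    gene = sprintf("g%d", seq_along(ch1i))) {
    data.frame(spot_id = seq_along(ch1i), gene_id = gene,
               ch1i_mean = ch1i, ch1b_median = ch1b,
               ch2i_mean = ch2i, ch2b_median = ch2b, flag = flag)
}

write_matrix_fixture <- function(values, group, pair_id = NULL,
                                 dir = tempfile()) {
    dir.create(dir)
    mpath <- file.path(dir, "matrix.tsv")
    tab <- data.frame(gene_id = rownames(values), values,
                      check.names = FALSE)
    write.table(tab, mpath, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    meta <- data.frame(sample_id = colnames(values), group = group)
    if (!is.null(pair_id)) meta$pair_id <- pair_id
    dpath <- file.path(dir, "meta.tsv")
    write.table(meta, dpath, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "")
    list(matrix = mpath, metadata = dpath)
}

demo_matrix <- function() {
    m <- matrix(c(1, 2, 3, 4,
                  4, 3, 2, 1), nrow = 4,
                dimnames = list(paste0("g", 1:4), c("T1", "N1")))
    m
}

write_series_matrix_fixture <- function(values, path = tempfile(),
                                        log2_note = FALSE) {
    lines <- c("!Series_title\t\"synthetic fixture\"",
               if (log2_note)
                   "!Sample_data_processing\t\"log2 transformed signal\"",
               "!series_matrix_table_begin",
               paste(c("ID_REF", colnames(values)), collapse = "\t"),
               vapply(seq_len(nrow(values)), function(i)
                   paste(c(rownames(values)[i], values[i, ]),
                         collapse = "\t"), character(1)),
               "!series_matrix_table_end")
    writeLines(lines, path)
    path
}

# Independent textbook evaluation of the one-sided Welch test.
welch_oracle <- function(x, y) {
    nx <- length(x); ny <- length(y)
    vx <- sum((x - mean(x))^2) / (nx - 1)
    vy <- sum((y - mean(y))^2) / (ny - 1)
    se2 <- vx / nx + vy / ny
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    list(t = tstat, df = df, p = pt(tstat, df, lower.tail = FALSE))
}
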