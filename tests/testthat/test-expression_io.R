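test_that("spot tables parse identically and validate flags", {
    df <- spot_df(ch1i = c(100, 80, 50), ch1b = c(20, 20, 10),
                  ch2i = c(60, 90, 40), ch2b = c(30, 20, 10),
                  flag = c(0L, -50L, -100L))
    tab <- readTwoChannelTable(write_spot_fixture(df))
    expect_s4_class(tab, "TwoChannelSpotTable")
    expect_equal(nSpots(tab), 3L)
    expect_equal(spotData(tab)$flag, c(0L, -50L, -100L))
    expect_equal(spotData(tab)$ch1i_mean[1], 100.0)
    expect_equal(spotData(tab)$ch1b_median[1], 20.0)

    bad <- df
    bad$flag[2] <- 7L
    expect_error(readTwoChannelTable(write_spot_fixture(bad)),
                 "flag value '7' at data row 2")
})

test_that("a missing mapped column is a format error naming the column", {
    df <- spot_df(ch1i = 100, ch1b = 20, ch2i = 60, ch2b = 30)
    path <- write_spot_fixture(df)
    lines <- readLines(path)
    lines[1] <- sub("\tCH1B_MEDIAN", "\tSOMETHING", lines[1])
    writeLines(lines, path)
    expect_error(readTwoChannelTable(path), "CH1B_MEDIAN")
})

test_that("rows with unparseable numerics are rejected, counted, not silently dropped", {
    df <- spot_df(ch1i = c("100", "oops", "50"), ch1b = c(20, 20, 10),
                  ch2i = c(60, 90, 40), ch2b = c(30, 20, 10))
    expect_message(tab <- readTwoChannelTable(write_spot_fixture(df)),
                   "rejected 1 of 3")
    expect_equal(nSpots(tab), 2L)   # kept + rejected == in
})

test_that("expression matrices read with metadata, missing cells and validation", {
    m <- demo_matrix()
    fx <- write_matrix_fixture(m, group = c("tumor", "normal"))
    em <- readExpressionMatrix(fx$matrix, fx$metadata)
    expect_s4_class(em, "ExpressionMatrix")
    expect_equal(dim(em), c(4L, 2L))
    expect_equal(unname(exprValues(em)), unname(m))
    expect_equal(unname(sampleGroup(em)), c("tumor", "normal"))

    m2 <- m; m2[2, 1] <- NA
    fx2 <- write_matrix_fixture(m2, group = c("tumor", "normal"))
    em2 <- readExpressionMatrix(fx2$matrix, fx2$metadata)
    expect_equal(sum(is.na(exprValues(em2))), 1L)
    expect_true(is.na(exprValues(em2)["g2", "T1"]))

    fx3 <- write_matrix_fixture(m, group = c("Tumour", "normal"))
    expect_error(readExpressionMatrix(fx3$matrix, fx3$metadata),
                 "allowed: tumor, normal")

    m3 <- m; m3[1, 2] <- -1
    fx4 <- write_matrix_fixture(m3, group = c("tumor", "normal"))
    expect_error(readExpressionMatrix(fx4$matrix, fx4$metadata),
                 "negative expression value at gene 'g1', sample 'N1'")

    meta_short <- read.table(fx$metadata, header = TRUE, sep = "\t")
    fx5 <- write_matrix_fixture(m, group = "tumor")
    write.table(meta_short[1, ], fx5$metadata, sep = "\t", quote = FALSE,
                row.names = FALSE)
    expect_error(readExpressionMatrix(fx5$matrix, fx5$metadata),
                 "absent from metadata: N1")
})

test_that("series-matrix dialect parses, flags log scale, and round-trips", {
    v <- matrix(c(1.5, 2.5, 3.5, 4.5), nrow = 2,
                dimnames = list(c("gA", "gB"), c("GSM1", "GSM2")))
    em <- readSeriesMatrix(write_series_matrix_fixture(v))
    expect_equal(dim(em), c(2L, 2L))
    expect_equal(exprValues(em), v)
    expect_true(all(is.na(sampleGroup(em))))
    expect_null(S4Vectors::metadata(em)$log_scale)

    em2 <- readSeriesMatrix(write_series_matrix_fixture(v, log2_note = TRUE))
    expect_equal(exprValues(em2), v)      # values untouched, hint attached
    expect_true(S4Vectors::metadata(em2)$log_scale)

    nomark <- tempfile()
    writeLines(c("!Series_title\t\"x\"", "gA\t1\t2"), nomark)
    expect_error(readSeriesMatrix(nomark), "table begin/end markers")
})

test_that("summary tables write a mean-T row and round-trip numerically", {
    rows <- data.frame(
        dataset = c("simA", "simB"), structure = c("Paired", "Non-paired"),
        pps = c(100, NA), q = c(343, 238), t = c(85.75, 95.2),
        mean_normal = c(0.98765432101, 0.9862), mean_tumor = c(0.999, 0.9927),
        p_value = c(3.756e-05, 0.0018))
    path <- writeSummaryTable(rows, tempfile(fileext = ".tsv"))
    back <- readSummaryTable(path)
    expect_equal(nrow(back), 3L)
    expect_equal(back$dataset[3], "Mean")
    expect_equal(back$t[3], mean(c(85.75, 95.2)))
    expect_equal(back$t[1:2], rows$t)
    expect_equal(back$mean_normal[1:2], rows$mean_normal, tolerance = 1e-12)
    expect_equal(back$p_value[1:2], rows$p_value, tolerance = 1e-12)
    expect_true(is.na(back$pps[2]))

    # two rows with T 50 and 70 -> mean row 60
    rows2 <- rows; rows2$t <- c(50, 70)
    back2 <- readSummaryTable(writeSummaryTable(rows2, tempfile()))
    expect_equal(back2$t[3], 60)

    # empty input -> header-only file
    empty <- readSummaryTable(writeSummaryTable(rows[0, ], tempfile()))
    expect_equal(nrow(empty), 0L)
    expect_true(all(c("dataset", "q", "t") %in% colnames(empty)))
})
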