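#' Background-correct a two-channel spot table
#'
#' Subtracts the median background pixel intensity from the uncorrected
#' mean pixel intensity in each channel:
#' `ch1d_mean = ch1i_mean - ch1b_median` and
#' `ch2d_mean = ch2i_mean - ch2b_median`. No filtering happens here;
#' negative corrected values are retained and handled by the downstream
#' expression extractors.
#'
#' @param spots a [TwoChannelSpotTable-class].
#' @return a [S4Vectors::DataFrame] of corrected spots with columns
#'   `spot_id`, `gene_id`, `ch1d_mean`, `ch2d_mean`.
#' @export
backgroundCorrect <- function(spots) {
    sp <- spotData(spots)
    DataFrame(spot_id = sp$spot_id, gene_id = sp$gene_id,
              ch1d_mean = sp$ch1i_mean - sp$ch1b_median,
              ch2d_mean = sp$ch2i_mean - sp$ch2b_median)
}

#' Remove flagged spots
#'
#' Spots flagged -50 (no signal) or -100 (poor signal) are removed; only
#' flag = 0 spots are retained. The removal count is reported.
#'
#' @param spots a [TwoChannelSpotTable-class].
#' @return the filtered [TwoChannelSpotTable-class].
#' @export
flagFilter <- function(spots) {
    sp <- spotData(spots)
    keep <- sp$flag == 0L
    message(sprintf("flagFilter: removed %d of %d spots (flag != 0)",
                    sum(!keep), nrow(sp)))
    if (!any(keep))
        warning("flagFilter: no spots remain after flag filtering")
    TwoChannelSpotTable(sp[keep, , drop = FALSE])
}

#' Keep only well-measured spots (1.5x-background rule)
#'
#' A spot is well measured when its uncorrected fluorescence intensity in
#' *each* channel exceeds `factor` times the local (median) background:
#' `ch1i_mean > factor * ch1b_median` and `ch2i_mean > factor * ch2b_median`,
#' strict inequality. Apply after [flagFilter()].
#'
#' @param spots a [TwoChannelSpotTable-class] (flag-filtered).
#' @param factor background multiple a channel must exceed; default 1.5.
#' @param strict if `TRUE` (default) a spot exactly at `factor` times
#'   background is removed.
#' @return the filtered [TwoChannelSpotTable-class].
#' @export
wellMeasuredFilter <- function(spots, factor = 1.5, strict = TRUE) {
    sp <- spotData(spots)
    cmp <- if (strict) `>` else `>=`
    keep <- cmp(sp$ch1i_mean, factor * sp$ch1b_median) &
            cmp(sp$ch2i_mean, factor * sp$ch2b_median)
    message(sprintf("wellMeasuredFilter: removed %d of %d spots (< %gx background)",
                    sum(!keep), nrow(sp), factor))
    TwoChannelSpotTable(sp[keep, , drop = FALSE])
}

## Collapse duplicate spots for the same gene by averaging non-missing values.
.collapse_by_gene <- function(gene_id, value) {
    means <- tapply(value, gene_id, function(v)
        if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    out <- as.numeric(means)
    names(out) <- names(means)
    out
}

#' Expression values as sample/reference intensity ratio
#'
#' For reference designs (one channel carries a common reference RNA), the
#' gene expression value is the corrected sample-channel intensity divided
#' by the corrected reference-channel intensity, e.g. `ch2d_mean/ch1d_mean`
#' when channel 1 is the reference. Spots whose reference-channel corrected
#' intensity is <= 0 are dropped (the ratio is undefined or sign-flipped);
#' the dropped count is reported. Duplicate spots for one gene are averaged
#' after filtering.
#'
#' @param corrected corrected spots from [backgroundCorrect()].
#' @param referenceChannel which channel (1 or 2) holds the reference.
#' @return named numeric vector of per-gene expression values.
#' @export
ratioExpression <- function(corrected, referenceChannel = 1) {
    if (!referenceChannel %in% c(1, 2))
        stop("referenceChannel must be 1 or 2", call. = FALSE)
    ref <- if (referenceChannel == 1) corrected$ch1d_mean else corrected$ch2d_mean
    smp <- if (referenceChannel == 1) corrected$ch2d_mean else corrected$ch1d_mean
    keep <- ref > 0
    if (any(!keep))
        message(sprintf("ratioExpression: dropped %d of %d spots with reference intensity <= 0",
                        sum(!keep), length(keep)))
    if (!any(keep))
        stop("ratioExpression: no spots with positive reference intensity",
             call. = FALSE)
    ratio <- smp[keep] / ref[keep]
    ratio[ratio < 0] <- NA_real_   # negative sample-channel intensity
    .collapse_by_gene(corrected$gene_id[keep], ratio)
}

#' Expression values from the two channels of a paired hybridization
#'
#' For designs where tumor and matched non-tumor RNA are hybridized as the
#' two channels of one array, the corrected channel intensities *are* the
#' two samples' expression values. Negative corrected intensities are set
#' missing (a negative expression value has no proportion interpretation).
#' Duplicate spots per gene are averaged over non-missing values.
#'
#' @param corrected corrected spots from [backgroundCorrect()].
#' @param channelGroups named character vector assigning `ch1` and `ch2`
#'   to `"tumor"` / `"normal"`.
#' @return two-column numeric matrix (columns `tumor`, `normal`), one row
#'   per gene.
#' @export
channelExpression <- function(corrected,
                              channelGroups = c(ch1 = "tumor", ch2 = "normal")) {
    if (!setequal(names(channelGroups), c("ch1", "ch2")) ||
        !setequal(unname(channelGroups), .GROUP_LEVELS))
        stop("channelGroups must assign ch1 and ch2 to 'tumor' and 'normal'",
             call. = FALSE)
    ch1 <- ifelse(corrected$ch1d_mean < 0, NA_real_, corrected$ch1d_mean)
    ch2 <- ifelse(corrected$ch2d_mean < 0, NA_real_, corrected$ch2d_mean)
    v1 <- .collapse_by_gene(corrected$gene_id, ch1)
    v2 <- .collapse_by_gene(corrected$gene_id, ch2)
    out <- cbind(v1, v2)
    colnames(out) <- unname(channelGroups[c("ch1", "ch2")])
    out[, .GROUP_LEVELS, drop = FALSE]
}

#' Remove genes without enough replicate measurements
#'
#' Genes with fewer than `minReplicates` non-missing measurements across
#' all samples of the dataset are removed (noise/artifact control). The
#' removed fraction is reported, in genes and in cells.
#'
#' @param x an [ExpressionMatrix-class].
#' @param minReplicates minimum number of non-missing values per gene;
#'   default 2.
#' @return the filtered [ExpressionMatrix-class].
#' @export
replicateFilter <- function(x, minReplicates = 2L) {
    v <- exprValues(x)
    nobs <- rowSums(!is.na(v))
    keep <- nobs >= minReplicates
    if (!any(keep))
        stop("replicateFilter: no gene has >= ", minReplicates,
             " replicate measurements", call. = FALSE)
    message(sprintf(
        "replicateFilter: removed %d of %d genes (%.2f%% of genes, %.2f%% of cells)",
        sum(!keep), nrow(v), 100 * mean(!keep),
        100 * sum(!is.na(v[!keep, , drop = FALSE])) / sum(!is.na(v))))
    x[keep, ]
}

#' Impute missing expression values by gene means
#'
#' Each missing cell is replaced by the mean of the gene's observed values
#' within the same sample group; when the gene has no observed value in
#' that group, the gene's overall observed mean is used. Deterministic and
#' parameter-free; requires every gene to have at least one observed value
#' (guaranteed after [replicateFilter()]).
#'
#' @param x an [ExpressionMatrix-class].
#' @return an [ExpressionMatrix-class] with no missing values.
#' @export
imputeMissing <- function(x) {
    v <- exprValues(x)
    if (!anyNA(v)) return(x)
    if (any(rowSums(!is.na(v)) == 0L))
        stop("imputeMissing: gene(s) with no observed value; run replicateFilter first",
             call. = FALSE)
    grp <- sampleGroup(x)
    overall <- rowMeans(v, na.rm = TRUE)
    for (g in unique(grp)) {
        cols <- if (is.na(g)) is.na(grp) else !is.na(grp) & grp == g
        sub <- v[, cols, drop = FALSE]
        gmean <- rowMeans(sub, na.rm = TRUE)        # NaN when no in-group obs
        fill <- ifelse(is.nan(gmean), overall, gmean)
        idx <- which(is.na(sub), arr.ind = TRUE)
        if (nrow(idx)) sub[idx] <- fill[idx[, 1]]
        v[, cols] <- sub
    }
    assay(x, "expr") <- v
    validObject(x)
    x
}

#' Undo a log transform of expression values
#'
#' Maps every value v to `base^v`, for datasets deposited on a log scale.
#' The result is strictly positive; a non-finite result (overflow) is an
#' error naming the offending cell.
#'
#' @param x an [ExpressionMatrix-class] on log scale.
#' @param base log base; default 2 (the usual deposition convention).
#' @return an [ExpressionMatrix-class] on the linear scale.
#' @export
inverseLogTransform <- function(x, base = 2) {
    v <- exprValues(x)
    out <- base^v
    bad <- which(!is.na(out) & !is.finite(out), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("inverseLogTransform: non-finite result at gene '%s', sample '%s'",
                     rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]]),
             call. = FALSE)
    assay(x, "expr") <- out
    metadata(x)$log_scale <- NULL
    validObject(x)
    x
}

#' @importFrom SummarizedExperiment assay<-
NULL
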