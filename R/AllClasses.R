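#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData colData<-
NULL

## Quality flags carried by two-channel spot tables: 0 = good signal,
## -50 = no signal, -100 = poor signal.  Anything else is a parse error.
.VALID_FLAGS <- c(0L, -50L, -100L)
.SPOT_FIELDS <- c("spot_id", "gene_id", "ch1i_mean", "ch1b_median",
                  "ch2i_mean", "ch2b_median", "flag")
.GROUP_LEVELS <- c("tumor", "normal")

#' TwoChannelSpotTable: raw spot measurements for one hybridization
#'
#' Per-spot measurements from a two-channel cDNA microarray hybridization:
#' uncorrected mean pixel intensities (`ch1i_mean`, `ch2i_mean`), median
#' background pixel intensities (`ch1b_median`, `ch2b_median`), and an
#' integer quality flag (0 good, -50 no signal, -100 poor signal).
#'
#' @slot spots a [S4Vectors::DataFrame] with one row per spot and the
#'   columns `spot_id`, `gene_id`, `ch1i_mean`, `ch1b_median`, `ch2i_mean`,
#'   `ch2b_median`, `flag`.
#' @seealso [readTwoChannelTable()], [backgroundCorrect()], [flagFilter()]
#' @export
setClass("TwoChannelSpotTable", representation(spots = "DataFrame"))

setValidity("TwoChannelSpotTable", function(object) {
    sp <- object@spots
    missing_cols <- setdiff(.SPOT_FIELDS, colnames(sp))
    if (length(missing_cols))
        return(sprintf("missing spot column(s): %s",
                       paste(missing_cols, collapse = ", ")))
    for (col in c("ch1i_mean", "ch1b_median", "ch2i_mean", "ch2b_median")) {
        v <- sp[[col]]
        if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)))
            return(sprintf("column '%s' must be finite numeric", col))
        if (any(v < 0))
            return(sprintf("column '%s' must be non-negative", col))
    }
    fl <- sp[["flag"]]
    if (!is.numeric(fl) || anyNA(fl))
        return("column 'flag' must be integer with no missing values")
    bad <- which(!(fl %in% .VALID_FLAGS))
    if (length(bad))
        return(sprintf("invalid flag value %s at row %d (allowed: %s)",
                       format(fl[bad[1]]), bad[1],
                       paste(.VALID_FLAGS, collapse = ", ")))
    TRUE
})

#' Construct a TwoChannelSpotTable
#'
#' @param spots a `data.frame` or `DataFrame` holding the per-spot fields
#'   `spot_id`, `gene_id`, `ch1i_mean`, `ch1b_median`, `ch2i_mean`,
#'   `ch2b_median`, `flag`.
#' @return a validated [TwoChannelSpotTable-class] object.
#' @examples
#' spots <- data.frame(spot_id = 1:2, gene_id = c("g1", "g2"),
#'                     ch1i_mean = c(100, 80), ch1b_median = c(20, 20),
#'                     ch2i_mean = c(60, 90),  ch2b_median = c(30, 20),
#'                     flag = c(0L, -50L))
#' TwoChannelSpotTable(spots)
#' @export
TwoChannelSpotTable <- function(spots) {
    spots <- as(spots, "DataFrame")
    if ("flag" %in% colnames(spots))
        spots$flag <- as.integer(spots$flag)
    new("TwoChannelSpotTable", spots = spots)
}

#' @describeIn TwoChannelSpotTable-class per-spot measurements as a DataFrame
#' @param x a `TwoChannelSpotTable`.
#' @export
spotData <- function(x) {
    stopifnot(is(x, "TwoChannelSpotTable"))
    x@spots
}

#' @describeIn TwoChannelSpotTable-class number of spots
#' @export
nSpots <- function(x) nrow(spotData(x))

setMethod("show", "TwoChannelSpotTable", function(object) {
    fl <- spotData(object)$flag
    cat(sprintf("TwoChannelSpotTable with %d spots (%d genes)\n",
                nSpots(object),
                length(unique(spotData(object)$gene_id))))
    cat(sprintf("  flags: %d good (0), %d no-signal (-50), %d poor (-100)\n",
                sum(fl == 0L), sum(fl == -50L), sum(fl == -100L)))
})

#' ExpressionMatrix: non-negative expression values with sample groups
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay `"expr"`
#' of non-negative (or missing) expression values, genes in rows and samples
#' in columns, with per-sample `group` labels (`"tumor"` / `"normal"`, or
#' `NA` when not yet assigned) and an optional `pair_id` linking each tumor
#' sample to its matched normal.
#'
#' @seealso [ExpressionMatrix()], [sdigPerSample()], [replicateFilter()]
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    if (!("expr" %in% names(assays(object))))
        return("assay 'expr' is required")
    v <- assay(object, "expr")
    if (!is.numeric(v))
        return("assay 'expr' must be numeric")
    if (nrow(v) < 1L)
        return("at least one gene is required")
    obs <- v[!is.na(v)]
    if (any(!is.finite(obs)))
        return("non-missing expression values must be finite")
    if (any(obs < 0))
        return("expression values must be non-negative")
    cd <- colData(object)
    if (!("group" %in% colnames(cd)))
        return("colData column 'group' is required")
    grp <- cd$group
    bad <- grp[!is.na(grp) & !(grp %in% .GROUP_LEVELS)]
    if (length(bad))
        return(sprintf("unrecognized group label '%s' (allowed: %s)",
                       bad[1], paste(.GROUP_LEVELS, collapse = ", ")))
    if ("pair_id" %in% colnames(cd)) {
        pid <- cd$pair_id
        for (g in .GROUP_LEVELS) {
            ids <- pid[!is.na(pid) & !is.na(grp) & grp == g]
            if (anyDuplicated(ids))
                return(sprintf("pair_id duplicated within group '%s'", g))
        }
    }
    TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, genes in rows and samples in columns;
#'   `NA` marks a missing measurement (0 is a legal expression value and is
#'   never used as a missing marker).
#' @param group character vector of per-sample labels, `"tumor"` or
#'   `"normal"` (`NA` allowed for unassigned samples, e.g. straight from a
#'   series-matrix file).
#' @param pairId optional per-sample identifiers matching each tumor sample
#'   with its normal counterpart; each id must occur at most once per group.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 4, 3, 2, 1), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), c("T1", "N1")))
#' ExpressionMatrix(m, group = c("tumor", "normal"), pairId = c("p1", "p1"))
#' @export
ExpressionMatrix <- function(values, group = NULL, pairId = NULL) {
    values <- as.matrix(values)
    if (is.null(rownames(values)))
        rownames(values) <- paste0("gene", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- paste0("sample", seq_len(ncol(values)))
    if (is.null(group))
        group <- rep(NA_character_, ncol(values))
    cd <- DataFrame(group = as.character(group), row.names = colnames(values))
    if (!is.null(pairId))
        cd$pair_id <- as.character(pairId)
    se <- SummarizedExperiment(assays = list(expr = values), colData = cd)
    new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix-class the expression value matrix
#' @param x an `ExpressionMatrix`.
#' @export
exprValues <- function(x) assay(x, "expr")

#' @describeIn ExpressionMatrix-class per-sample group labels
#' @export
sampleGroup <- function(x) {
    g <- colData(x)$group
    names(g) <- colnames(x)
    g
}

#' @describeIn ExpressionMatrix-class per-sample pair identifiers (or NULL)
#' @export
pairId <- function(x) {
    p <- colData(x)$pair_id
    if (is.null(p)) return(NULL)
    names(p) <- colnames(x)
    p
}

setMethod("show", "ExpressionMatrix", function(object) {
    grp <- sampleGroup(object)
    v <- exprValues(object)
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%d tumor, %d normal)\n",
                nrow(object), ncol(object),
                sum(grp == "tumor", na.rm = TRUE),
                sum(grp == "normal", na.rm = TRUE)))
    nmiss <- sum(is.na(v))
    if (nmiss)
        cat(sprintf("  %d missing cells (%.2f%%)\n", nmiss,
                    100 * nmiss / length(v)))
    if (isTRUE(metadata(object)$log_scale))
        cat("  values flagged as log-scale; apply inverseLogTransform()\n")
})

#' PairSummary: positive-pair statistics for one dataset
#'
#' Cross-product dominance statistics between tumor and normal per-sample
#' SDIG values: the positive-pair count Q (pairs where tumor SDIG strictly
#' exceeds normal SDIG over all M x N combinations), the proportion of
#' positive pair number T = 100 Q / (M N) (PPPN, percent), its complement
#' PNPN, and -- for paired designs -- the proportion of positive samples PPS
#' computed on matched pairs only.
#'
#' @slot nTumor integer, number of tumor samples (M).
#' @slot nNormal integer, number of normal samples (N).
#' @slot positivePairs integer, Q.
#' @slot pppn numeric, T in percent, full precision.
#' @slot pnpn numeric, 100 - T.
#' @slot pps numeric percent, or `NA` for unpaired datasets.
#' @export
setClass("PairSummary",
         representation(nTumor = "integer", nNormal = "integer",
                        positivePairs = "integer", pppn = "numeric",
                        pnpn = "numeric", pps = "numeric"))

setValidity("PairSummary", function(object) {
    M <- object@nTumor; N <- object@nNormal; Q <- object@positivePairs
    if (M < 1L || N < 1L) return("both groups must be non-empty")
    if (Q < 0L || Q > M * N) return("Q must lie in [0, M*N]")
    if (abs(object@pppn + object@pnpn - 100) > 1e-9)
        return("pppn + pnpn must equal 100")
    if (!is.na(object@pps) && (object@pps < 0 || object@pps > 100))
        return("pps must lie in [0, 100]")
    TRUE
})

#' @describeIn PairSummary-class positive-pair count Q
#' @param x a `PairSummary`.
#' @export
positivePairs <- function(x) x@positivePairs

#' @describeIn PairSummary-class PPPN (T) in percent, full precision
#' @export
pppnValue <- function(x) x@pppn

#' @describeIn PairSummary-class PNPN in percent
#' @export
pnpnValue <- function(x) x@pnpn

#' @describeIn PairSummary-class PPS in percent (NA when unpaired)
#' @export
ppsValue <- function(x) x@pps

setMethod("show", "PairSummary", function(object) {
    cat(sprintf("PairSummary: M = %d tumor, N = %d normal samples\n",
                object@nTumor, object@nNormal))
    cat(sprintf("  Q = %d of %d pairs; T (PPPN) = %.4g%%; PNPN = %.4g%%\n",
                object@positivePairs, object@nTumor * object@nNormal,
                object@pppn, object@pnpn))
    cat(sprintf("  PPS = %s\n",
                if (is.na(object@pps)) "NA (unpaired)"
                else sprintf("%.4g%%", object@pps)))
})

#' GroupTestResult: one-sided Welch t-test of tumor vs normal mean SDIG
#'
#' @slot meanTumor,meanNormal group means of SDIG.
#' @slot statistic Welch t statistic for the alternative
#'   `mean(tumor) > mean(normal)`.
#' @slot df Welch-Satterthwaite degrees of freedom.
#' @slot pValue one-sided (upper-tail) P value.
#' @slot alpha significance level.
#' @slot significant logical, `pValue < alpha`.
#' @export
setClass("GroupTestResult",
         representation(meanTumor = "numeric", meanNormal = "numeric",
                        statistic = "numeric", df = "numeric",
                        pValue = "numeric", alpha = "numeric",
                        significant = "logical"))

setValidity("GroupTestResult", function(object) {
    if (object@pValue < 0 || object@pValue > 1)
        return("pValue must lie in [0, 1]")
    if (object@df <= 0) return("degrees of freedom must be positive")
    if (!identical(object@significant, object@pValue < object@alpha))
        return("significant flag inconsistent with pValue and alpha")
    TRUE
})

setMethod("show", "GroupTestResult", function(object) {
    cat("One-sided Welch t-test (alternative: mean tumor SDIG > mean normal)\n")
    cat(sprintf("  mean SDIG: tumor %.4f, normal %.4f\n",
                object@meanTumor, object@meanNormal))
    cat(sprintf("  t = %.4f, df = %.2f, P = %.4g%s\n",
                object@statistic, object@df, object@pValue,
                if (object@significant) " *" else ""))
})
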