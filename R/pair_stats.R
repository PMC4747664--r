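#' Count positive SDIG pairs over the tumor x normal cross product
#'
#' A pair (tumor sample j, normal sample k) is positive when the tumor
#' sample's SDIG strictly exceeds the normal sample's; ties are not
#' positive. All M x N combinations are considered. Implemented by
#' sorting + binary search; agrees exactly with the double-loop
#' definition.
#'
#' @param tumorD numeric vector of tumor-sample SDIG values (length M).
#' @param normalD numeric vector of normal-sample SDIG values (length N).
#' @return integer Q, the positive-pair count, in `[0, M*N]`.
#' @export
countPositivePairs <- function(tumorD, normalD) {
    if (!length(tumorD) || !length(normalD))
        stop("both groups must be non-empty", call. = FALSE)
    if (anyNA(tumorD) || anyNA(normalD))
        stop("SDIG values must not be missing", call. = FALSE)
    sn <- sort(normalD)
    # findInterval with left.open counts normals strictly below each tumor D
    sum(findInterval(tumorD, sn, left.open = TRUE))
}

#' Proportion of positive pair number (PPPN, T)
#'
#' `T = 100 * Q / (M * N)` percent: the share of tumor/normal SDIG pairs in
#' which the tumor sample dominates. Returned at full precision; use
#' [displayRound()] for report formatting.
#'
#' @param Q positive-pair count(s).
#' @param M number of tumor samples.
#' @param N number of normal samples.
#' @return T in percent; vectorized over equal-length inputs.
#' @examples
#' pppn(238, 50, 5)    # 95.2
#' pppn(343, 20, 20)   # 85.75
#' @export
pppn <- function(Q, M, N) {
    if (any(M < 1) || any(N < 1)) stop("M and N must be >= 1", call. = FALSE)
    if (any(Q < 0) || any(Q > M * N))
        stop("Q must lie in [0, M*N]", call. = FALSE)
    100 * Q / (M * N)
}

#' Proportion of positive samples (PPS) for paired designs
#'
#' Among matched tumor/normal pairs only (never the cross product), the
#' percent of pairs whose tumor SDIG strictly exceeds the paired normal
#' SDIG. For unpaired designs the statistic does not exist and `NA` is
#' returned (not an error), mirroring an "NA" report cell.
#'
#' @param tumorD,normalD SDIG values named by pair id, or unnamed vectors
#'   of equal length already in pair order.
#' @param paired logical; `FALSE` marks an unpaired design.
#' @return PPS in percent, or `NA_real_` when unpaired.
#' @export
pps <- function(tumorD, normalD, paired = TRUE) {
    if (!paired) return(NA_real_)
    if (length(tumorD) != length(normalD) || !length(tumorD))
        stop("paired design requires equally many tumor and normal values",
             call. = FALSE)
    if (!is.null(names(tumorD)) && !is.null(names(normalD))) {
        if (!setequal(names(tumorD), names(normalD)))
            stop("pair ids do not match between groups", call. = FALSE)
        normalD <- normalD[names(tumorD)]
    }
    100 * mean(tumorD > normalD)
}

#' Summarize a dataset's diversity results as pair statistics
#'
#' Builds the [PairSummary-class] for one dataset from per-sample SDIG
#' values: Q over the full cross product, T (PPPN) and PNPN = 100 - T, and
#' PPS on the matched pairs when the dataset is paired.
#'
#' @param diversity per-sample results from [sdigPerSample()] (columns
#'   `sample_id`, `group`, `D`, optionally `pair_id`).
#' @param paired logical; when `TRUE`, `pair_id` must be present and
#'   complete.
#' @return a [PairSummary-class].
#' @export
summarizeDataset <- function(diversity, paired = FALSE) {
    grp <- diversity$group
    tum <- diversity[!is.na(grp) & grp == "tumor", , drop = FALSE]
    nor <- diversity[!is.na(grp) & grp == "normal", , drop = FALSE]
    if (!nrow(tum) || !nrow(nor))
        stop("both tumor and normal samples are required", call. = FALSE)
    M <- nrow(tum); N <- nrow(nor)
    Q <- countPositivePairs(tum$D, nor$D)
    T_pct <- pppn(Q, M, N)
    pps_val <- if (paired) {
        if (is.null(diversity$pair_id) || anyNA(tum$pair_id) ||
            anyNA(nor$pair_id))
            stop("paired = TRUE requires a complete pair_id column",
                 call. = FALSE)
        pps(stats::setNames(tum$D, tum$pair_id),
            stats::setNames(nor$D, nor$pair_id))
    } else NA_real_
    new("PairSummary", nTumor = as.integer(M), nNormal = as.integer(N),
        positivePairs = as.integer(Q), pppn = T_pct, pnpn = 100 - T_pct,
        pps = pps_val)
}

#' Round-half-up display rounding for report cells
#'
#' Statistics are stored at full precision; published tables round each
#' cell to a fixed number of decimals with halves rounded up (so e.g.
#' 85.75 displays as 86 at zero decimals). This helper reproduces that
#' display convention without touching the stored value.
#'
#' @param x numeric value(s).
#' @param digits decimals to keep; default 0.
#' @return numeric value(s) rounded half-up at `digits` decimals.
#' @examples
#' displayRound(85.75)        # 86
#' displayRound(74.4898, 1)   # 74.5
#' @export
displayRound <- function(x, digits = 0) {
    m <- 10^digits
    sign(x) * floor(abs(x) * m + 0.5) / m
}
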