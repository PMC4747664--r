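#' One-sided Welch t-test of tumor vs normal mean SDIG
#'
#' Tests the alternative that mean SDIG in the tumor group exceeds that in
#' the normal group, without assuming equal variances:
#' `t = (mean_T - mean_N) / sqrt(s_T^2/n_T + s_N^2/n_N)` with sample
#' variances (n - 1 denominator), Welch-Satterthwaite degrees of freedom,
#' and an upper-tail P value. Delegates to [stats::t.test()].
#'
#' @param tumorD numeric SDIG values for the tumor group (>= 2 values).
#' @param normalD numeric SDIG values for the normal group (>= 2 values).
#' @param alpha significance level; default 0.05.
#' @return a [GroupTestResult-class].
#' @export
welchOneSided <- function(tumorD, normalD, alpha = 0.05) {
    if (length(tumorD) < 2L || length(normalD) < 2L)
        stop("each group needs at least 2 values", call. = FALSE)
    if (stats::var(tumorD) == 0 && stats::var(normalD) == 0)
        stop("degenerate input: both group variances are zero", call. = FALSE)
    tt <- stats::t.test(tumorD, normalD, alternative = "greater",
                        var.equal = FALSE)
    p <- unname(tt$p.value)
    new("GroupTestResult",
        meanTumor = mean(tumorD), meanNormal = mean(normalD),
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        pValue = p, alpha = alpha, significant = p < alpha)
}

#' Five-number summary (boxplot statistics)
#'
#' Minimum, first quartile, median, third quartile and maximum, with
#' quartiles by the linear-interpolation convention
#' ([stats::quantile()] type 7).
#'
#' @param x numeric vector.
#' @return named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @export
fiveNumberSummary <- function(x) {
    q <- stats::quantile(x, probs = c(0, 0.25, 0.5, 0.75, 1),
                         names = FALSE, type = 7)
    stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Full per-dataset report: diversity, pair statistics and group test
#'
#' Runs the analysis stages on a preprocessed (fully imputed) expression
#' matrix and assembles one report row -- dataset id, pairing status, PPS,
#' Q, T, group mean SDIGs, one-sided Welch P value -- plus the per-sample
#' diversity table and per-group five-number summaries for boxplot-style
#' display.
#'
#' @param x an [ExpressionMatrix-class], preprocessed and imputed.
#' @param paired logical; compute PPS on matched pairs.
#' @param datasetId label for the report row.
#' @param alpha significance level for the Welch test.
#' @return list with elements `summary` (one-row `data.frame`),
#'   `diversity` (per-sample DataFrame), `boxplot` (per-group five-number
#'   `data.frame`) and `test` (the [GroupTestResult-class]).
#' @export
datasetReport <- function(x, paired = FALSE, datasetId = "dataset",
                          alpha = 0.05) {
    div <- sdigPerSample(x)
    ps <- summarizeDataset(div, paired = paired)
    tum <- div$D[div$group == "tumor"]
    nor <- div$D[div$group == "normal"]
    test <- welchOneSided(tum, nor, alpha = alpha)
    summary <- data.frame(
        dataset = datasetId,
        structure = if (paired) "Paired" else "Non-paired",
        pps = ppsValue(ps),
        q = positivePairs(ps),
        t = pppnValue(ps),
        mean_normal = test@meanNormal,
        mean_tumor = test@meanTumor,
        p_value = test@pValue,
        significant = test@significant)
    boxplot <- do.call(rbind, lapply(.GROUP_LEVELS, function(g) {
        data.frame(dataset = datasetId, group = g,
                   t(fiveNumberSummary(div$D[div$group == g])))
    }))
    list(summary = summary, diversity = div, boxplot = boxplot, test = test)
}
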