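#' Simulation configuration for synthetic expression cohorts
#'
#' Bundles and validates the knobs of the synthetic-data generators. The
#' evenness of each group's expression profiles is controlled by the
#' concentration of a symmetric Dirichlet distribution on the gene-
#' proportion simplex: larger `alpha` gives more even profiles and hence a
#' higher expected SDIG (closed form: `E[D] = 1 - (alpha + 1)/(S*alpha + 1)`,
#' see [expectedSdig()]).
#'
#' @param S number of genes (>= 2).
#' @param nTumor,nNormal samples per group.
#' @param alphaTumor,alphaNormal Dirichlet concentrations (> 0); the study
#'   design this emulates has the tumor group more even, i.e.
#'   `alphaTumor > alphaNormal`.
#' @param intensityScale total expression scale each proportion vector is
#'   multiplied by (arbitrary units; SDIG is scale invariant).
#' @param depthSdLog sd (log scale) of the per-sample lognormal depth
#'   factor; exercises scale invariance end to end.
#' @param flagRates probabilities of flag values 0, -50, -100 (sum to 1),
#'   in that order, for spot-table simulation.
#' @param backgroundLevel mean background intensity for spot tables.
#' @param missingRate probability a matrix cell is masked missing.
#' @param paired attach pair ids (requires `nTumor == nNormal`).
#' @param seed integer RNG seed.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(S = 1000L, nTumor = 20L, nNormal = 20L,
                             alphaTumor = 2.0, alphaNormal = 0.5,
                             intensityScale = 1e4, depthSdLog = 0.5,
                             flagRates = c(0.8, 0.1, 0.1),
                             backgroundLevel = 100, missingRate = 0,
                             paired = FALSE, seed = 1L) {
    stopifnot(S >= 2, nTumor >= 1, nNormal >= 1,
              alphaTumor > 0, alphaNormal > 0,
              intensityScale > 0, depthSdLog >= 0,
              length(flagRates) == 3, all(flagRates >= 0),
              abs(sum(flagRates) - 1) < 1e-9,
              backgroundLevel > 0, missingRate >= 0, missingRate <= 1)
    if (paired && nTumor != nNormal)
        stop("paired design requires nTumor == nNormal", call. = FALSE)
    structure(list(S = as.integer(S), nTumor = as.integer(nTumor),
                   nNormal = as.integer(nNormal), alphaTumor = alphaTumor,
                   alphaNormal = alphaNormal, intensityScale = intensityScale,
                   depthSdLog = depthSdLog, flagRates = flagRates,
                   backgroundLevel = backgroundLevel,
                   missingRate = missingRate, paired = paired,
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Expected SDIG under a symmetric Dirichlet evenness model
#'
#' For proportions drawn from a symmetric Dirichlet(`alpha`) over `S`
#' genes, `E[sum p_i^2] = (alpha + 1) / (S * alpha + 1)`, so the expected
#' index is `1 - (alpha + 1)/(S*alpha + 1)`.
#'
#' @param S number of genes.
#' @param alpha Dirichlet concentration.
#' @return expected SDIG.
#' @export
expectedSdig <- function(S, alpha) 1 - (alpha + 1) / (S * alpha + 1)

#' Draw expression-proportion vectors from a symmetric Dirichlet
#'
#' Standard gamma-normalisation construction: S independent
#' Gamma(`alpha`, 1) draws per sample, normalised to sum to 1.
#'
#' @param S number of genes (>= 2).
#' @param alpha concentration (> 0); large alpha approaches the uniform
#'   profile `1/S`, small alpha concentrates expression in few genes.
#' @param n number of samples.
#' @param seed optional integer seed for reproducibility.
#' @return `S x n` matrix, each column a proportion vector summing to 1.
#' @export
simulateProportions <- function(S, alpha, n, seed = NULL) {
    stopifnot(S >= 2, alpha > 0, n >= 1)
    if (!is.null(seed)) set.seed(seed)
    g <- matrix(stats::rgamma(S * n, shape = alpha, rate = 1), nrow = S)
    # guard against a column of all-underflowed zeros at tiny alpha
    zero <- colSums(g) == 0
    if (any(zero))
        g[cbind(sample.int(S, sum(zero), replace = TRUE), which(zero))] <-
            .Machine$double.xmin
    sweep(g, 2, colSums(g), "/")
}

#' Simulate a tumor/normal expression matrix with known ground truth
#'
#' Per-sample proportion vectors (Dirichlet, group-specific concentration)
#' are scaled by `intensityScale` and a per-sample lognormal depth factor,
#' and missing cells are injected at `missingRate`. The returned ground
#' truth carries the groups' closed-form expected SDIG values.
#'
#' @param config a [simulationConfig()].
#' @return list with `matrix` (an [ExpressionMatrix-class]) and `truth`
#'   (list: `expectedSdigTumor`, `expectedSdigNormal`, per-sample true
#'   SDIG values computed from the noiseless proportions).
#' @export
simulateExpressionMatrix <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    S <- config$S
    nT <- config$nTumor; nN <- config$nNormal
    p_t <- simulateProportions(S, config$alphaTumor, nT)
    p_n <- simulateProportions(S, config$alphaNormal, nN)
    props <- cbind(p_t, p_n)
    depth <- stats::rlnorm(nT + nN, meanlog = log(config$intensityScale),
                           sdlog = config$depthSdLog)
    vals <- sweep(props, 2, depth, "*")
    rownames(vals) <- sprintf("gene%04d", seq_len(S))
    colnames(vals) <- c(sprintf("T%02d", seq_len(nT)),
                        sprintf("N%02d", seq_len(nN)))
    if (config$missingRate > 0) {
        mask <- matrix(stats::runif(length(vals)) < config$missingRate,
                       nrow = S)
        vals[mask] <- NA_real_
    }
    group <- c(rep("tumor", nT), rep("normal", nN))
    pid <- if (config$paired)
        c(sprintf("p%02d", seq_len(nT)), sprintf("p%02d", seq_len(nN)))
    else NULL
    em <- ExpressionMatrix(vals, group = group, pairId = pid)
    truth <- list(
        expectedSdigTumor = expectedSdig(S, config$alphaTumor),
        expectedSdigNormal = expectedSdig(S, config$alphaNormal),
        trueSdig = stats::setNames(
            apply(props, 2, function(p) 1 - sum(p^2)), colnames(vals)))
    list(matrix = em, truth = truth)
}

#' Simulate a two-channel spot table with known post-filter truth
#'
#' Spots are built as `intensity = background * signal factor`, with
#' per-channel lognormal signal factors centred near 2x background, gamma-
#' distributed backgrounds around `backgroundLevel`, and flags assigned at
#' `flagRates`. The generator records, from its own sampled factors, which
#' spots survive the flag filter and the 1.5x-background rule -- an
#' independent oracle for the preprocessing filters.
#'
#' @param config a [simulationConfig()]; `S` is the number of genes, with
#'   one spot per gene.
#' @param wellMeasuredFactor the background multiple the survival
#'   bookkeeping assumes; default 1.5.
#' @return list with `table` (a [TwoChannelSpotTable-class]) and
#'   `survivors` (logical vector: flag 0 and both channels above
#'   `wellMeasuredFactor` times background).
#' @export
simulateTwoChannelTable <- function(config, wellMeasuredFactor = 1.5) {
    stopifnot(inherits(config, "SimulationConfig"))
    set.seed(config$seed)
    S <- config$S
    bg1 <- stats::rgamma(S, shape = 50, rate = 50 / config$backgroundLevel)
    bg2 <- stats::rgamma(S, shape = 50, rate = 50 / config$backgroundLevel)
    f1 <- stats::rlnorm(S, meanlog = log(2), sdlog = 0.7)
    f2 <- stats::rlnorm(S, meanlog = log(2), sdlog = 0.7)
    flag <- sample(.VALID_FLAGS, S, replace = TRUE, prob = config$flagRates)
    tab <- data.frame(spot_id = seq_len(S),
                      gene_id = sprintf("gene%04d", seq_len(S)),
                      ch1i_mean = bg1 * f1, ch1b_median = bg1,
                      ch2i_mean = bg2 * f2, ch2b_median = bg2,
                      flag = flag)
    survivors <- flag == 0L & f1 > wellMeasuredFactor & f2 > wellMeasuredFactor
    list(table = TwoChannelSpotTable(tab), survivors = survivors)
}
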