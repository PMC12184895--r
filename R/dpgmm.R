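#' Standardize a VAF vector for mixture fitting
#'
#' Centres and scales the non-missing values of a per-mutation VAF vector
#' to mean 0 and standard deviation 1, recording the affine transform so
#' component means can be mapped back to the allele-frequency scale.
#'
#' @param y numeric vector of VAFs (may contain \code{NA} for uncovered
#'   cells).
#' @return a list with \code{z} (standardized values, missing entries
#'   dropped), \code{center}, \code{scale} and \code{index} (positions of
#'   the retained entries in \code{y}). If the non-missing values are
#'   constant, \code{scale} is 0 and \code{z} is empty: such a vector is a
#'   single component by construction and the mixture fit short-circuits.
#' @export
standardizeVaf <- function(y) {
    idx <- which(!is.na(y))
    if (length(idx) < 2L)
        stop("need at least 2 non-missing values to standardize")
    v <- y[idx]
    ctr <- mean(v)
    scl <- stats::sd(v)
    if (scl == 0)
        return(list(z = numeric(0), center = ctr, scale = 0, index = idx))
    list(z = (v - ctr) / scl, center = ctr, scale = scl, index = idx)
}

.autoIter <- function(cfg, n) {
    nIter <- cfg@nIter
    if (is.na(nIter)) nIter <- if (n < 100L) 10000L else 5000L
    nBurnin <- cfg@nBurnin
    if (is.na(nBurnin)) nBurnin <- nIter %/% 2L
    stopifnot(nBurnin < nIter)
    list(nIter = nIter, nBurnin = nBurnin)
}

.singleComponentFit <- function(y, mutation, nCells) {
    v <- y[!is.na(y)]
    new("DpgmmFit", mutation = mutation, nComponents = 1L, weights = 1,
        means = mean(v), variances = stats::var(v) %||% 0,
        top2MeanDiff = NA_real_, center = mean(v),
        scale = if (length(v) > 1L) stats::sd(v) else 0,
        nCells = as.integer(nCells),
        kPosterior = stats::setNames(0L, "1"))
}

`%||%` <- function(a, b) {
    if (is.null(a) || (length(a) == 1L && is.na(a))) b else a
}

#' Fit a Dirichlet-process Gaussian mixture to one mutation's VAFs
#'
#' Models the cross-cell VAF vector of a mutation as a Gaussian mixture
#' with an unknown number of components under a Dirichlet-process prior,
#' fitted by collapsed Gibbs sampling (Neal's Algorithm 3) with a
#' conjugate Normal-Inverse-Gamma base measure on standardized data. The
#' number of occupied clusters is tallied over post-burn-in sweeps
#' (clusters occupied by fewer than \code{minComponentWeight} of the cells
#' are treated as MCMC dust); the posterior is summarized by the component
#' assignment of the last retained sweep whose occupied-cluster count
#' equals the posterior mode. Component weights, means and variances are
#' computed from that assignment and means are back-transformed to the
#' VAF scale, on which the top-two-component separation
#' (\code{top2MeanDiff}) is reported.
#'
#' @param y numeric vector of per-cell VAFs (\code{NA} = uncovered, these
#'   are excluded, not imputed as 0).
#' @param config a \linkS4class{DpgmmConfig}.
#' @param mutation optional mutation identifier carried into the result.
#' @return a \linkS4class{DpgmmFit}.
#' @examples
#' set.seed(7)
#' y <- c(rnorm(100, 0.02, 0.01), rnorm(100, 0.40, 0.05))
#' fit <- fitDpgmm(y, DpgmmConfig(nIter = 2000, seed = 1))
#' fit
#' @export
fitDpgmm <- function(y, config = DpgmmConfig(), mutation = NA_character_) {
    stopifnot(is(config, "DpgmmConfig"))
    nObs <- sum(!is.na(y))
    if (nObs < config@minCells)
        stop("too few non-missing cells (", nObs, " < ", config@minCells,
             ") to fit mutation ", mutation)
    std <- standardizeVaf(y)
    if (std$scale == 0)
        return(.singleComponentFit(y, mutation, nObs))
    if (!is.na(config@seed)) set.seed(config@seed)
    it <- .autoIter(config, nObs)
    minOcc <- max(1L, as.integer(ceiling(config@minComponentWeight * nObs)))
    res <- .dpgmmGibbs(std$z, config@alpha, it$nIter, it$nBurnin, minOcc)
    assign <- res$assignment
    tab <- table(assign)
    keep <- as.integer(names(tab)[tab >= minOcc])
    if (!length(keep)) keep <- as.integer(names(tab)[which.max(tab)])
    stats <- lapply(keep, function(cl) {
        zi <- std$z[assign == cl]
        c(n = length(zi), mean = mean(zi),
          var = if (length(zi) > 1L) stats::var(zi) else 0)
    })
    n <- vapply(stats, `[[`, 0, "n")
    w <- n / sum(n)
    mu <- vapply(stats, `[[`, 0, "mean") * std$scale + std$center
    s2 <- vapply(stats, `[[`, 0, "var") * std$scale^2
    ord <- order(w, decreasing = TRUE)
    w <- w[ord]; mu <- mu[ord]; s2 <- s2[ord]
    diff <- if (length(mu) >= 2L) abs(mu[1L] - mu[2L]) else NA_real_
    new("DpgmmFit", mutation = mutation, nComponents = length(w),
        weights = unname(w), means = unname(mu), variances = unname(s2),
        top2MeanDiff = diff, center = std$center, scale = std$scale,
        nCells = as.integer(nObs), kPosterior = .asIntTally(res$kCounts))
}

.asIntTally <- function(x) {
    out <- as.integer(x)
    names(out) <- names(x)
    out
}

#' Select lineage-informative mutations
#'
#' Fits the DP Gaussian mixture (\code{\link{fitDpgmm}}) to every mutation
#' in a (QC-filtered) dataset and selects those whose VAF distribution has
#' at least two components with the two largest-weight component means
#' separated by more than \code{informativeCutoff} on the VAF scale. A
#' well-separated multimodal VAF distribution marks cell subsets carrying
#' distinct heteroplasmy levels, i.e. distinct clones.
#'
#' Mutations with fewer than \code{minCells} covered cells are skipped
#' (reported with \code{nComponents = NA}). Given a seed in the config the
#' selection is deterministic: mutations are fitted in row order from one
#' seeded RNG stream.
#'
#' @param x a \linkS4class{MitoVafExperiment}, typically after
#'   \code{\link{applyErrorFilter}} and \code{\link{applyFrequencyFilter}}.
#' @param config a \linkS4class{DpgmmConfig}.
#' @return a list with \code{selected} (character vector of mutation ids)
#'   and \code{fits} (a \code{DataFrame} with one row per attempted
#'   mutation: \code{nComponents}, \code{top2MeanDiff}, \code{informative},
#'   and list-columns \code{weights}, \code{means}, \code{variances}).
#' @export
selectInformative <- function(x, config = DpgmmConfig()) {
    stopifnot(is(x, "MitoVafExperiment"))
    v <- vaf(x)
    if (!is.na(config@seed)) set.seed(config@seed)
    cfgNoSeed <- config
    cfgNoSeed@seed <- NA_integer_
    fits <- vector("list", nrow(v))
    names(fits) <- rownames(v)
    for (i in seq_len(nrow(v))) {
        y <- v[i, ]
        if (sum(!is.na(y)) < config@minCells) {
            fits[[i]] <- NULL
            next
        }
        fits[[i]] <- fitDpgmm(y, cfgNoSeed, mutation = rownames(v)[i])
    }
    attempted <- !vapply(fits, is.null, TRUE)
    getOr <- function(f, slot, default) {
        if (is.null(f)) default else methods::slot(f, slot)
    }
    nc <- vapply(fits, getOr, 0L, "nComponents", NA_integer_)
    dif <- vapply(fits, getOr, 0, "top2MeanDiff", NA_real_)
    informative <- !is.na(nc) & nc >= 2L & !is.na(dif) &
        dif > config@informativeCutoff
    res <- S4Vectors::DataFrame(
        mutation = rownames(v),
        nComponents = nc,
        top2MeanDiff = dif,
        informative = informative,
        row.names = rownames(v))
    res$weights <- IRanges::NumericList(
        lapply(fits, getOr, "weights", numeric(0)))
    res$means <- IRanges::NumericList(
        lapply(fits, getOr, "means", numeric(0)))
    res$variances <- IRanges::NumericList(
        lapply(fits, getOr, "variances", numeric(0)))
    selected <- rownames(v)[informative]
    if (!length(selected))
        warning("no mutation passed the informativeness criteria")
    if (any(!attempted))
        message(sum(!attempted), " mutation(s) skipped: fewer than ",
                config@minCells, " covered cells")
    list(selected = selected, fits = res)
}
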