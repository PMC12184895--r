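#' Probability of a call arising from sequencing error
#'
#' Under a random per-base error rate \code{e}, an erroneous alternate
#' base at a site is one specific substitution out of three, so each read
#' supports it with probability \code{e/3}. The probability of observing
#' at least \code{m} identical alternate reads among \code{n} by error
#' alone is
#' \deqn{p(m) = 1 - \sum_{i=0}^{m-1} \mathrm{Binom}(i \mid n, e/3),}
#' with \eqn{p(0) = 1}. This is the false-positive probability of calling
#' a variant from \code{m} supporting reads at depth \code{n}.
#'
#' @param m integer vector of alternate-read counts (\code{0 <= m <= n}).
#' @param n integer vector of read depths (recycled with \code{m}).
#' @param model an \linkS4class{ErrorModel}.
#' @return numeric vector of probabilities in \code{[0, 1]},
#'   non-increasing in \code{m} at fixed \code{n}.
#' @examples
#' errorProb(0, 30)                      # 1: no evidence required
#' errorProb(1, 30)                      # 1 - (1 - e/3)^30
#' errorProb(3, 100)
#' @export
errorProb <- function(m, n, model = ErrorModel()) {
    stopifnot(is(model, "ErrorModel"))
    r <- vctrs_recycle(m, n)
    m <- r[[1L]]; n <- r[[2L]]
    if (any(n < 0)) stop("depth n must be non-negative")
    if (any(m < 0)) stop("m must be non-negative")
    if (any(m > n)) stop("m must not exceed the depth n")
    p <- 1 - stats::pbinom(m - 1, n, model@e / 3)
    p[m == 0] <- 1
    pmin(pmax(p, 0), 1)
}

## base-R recycling with a length check (no vctrs dependency)
vctrs_recycle <- function(a, b) {
    la <- length(a); lb <- length(b)
    if (la != lb && la != 1L && lb != 1L)
        stop("lengths ", la, " and ", lb, " cannot be recycled")
    n <- max(la, lb)
    list(rep_len(a, n), rep_len(b, n))
}

#' Minimum alternate reads needed to beat the false-positive rate
#'
#' The smallest alternate-read count \code{k} at depth \code{n} whose
#' sequencing-error probability \code{\link{errorProb}} falls at or below
#' the model's false-positive rate:
#' \deqn{k = \min \{ m : p(m) \le \mathrm{FPR} \}.}
#' When even \code{k = n} cannot beat the bound (e.g. \code{n = 0}), the
#' unattainable value \code{n + 1} is returned, flagged with the
#' \code{"unattainable"} attribute, meaning the site cannot yield a
#' trustworthy call at that depth.
#'
#' @param n integer vector of read depths.
#' @param model an \linkS4class{ErrorModel}.
#' @return integer vector of thresholds, non-decreasing in \code{n};
#'   attribute \code{"unattainable"} is a logical vector marking depths
#'   where no count passes.
#' @examples
#' minAltReads(30)
#' minAltReads(c(10, 100, 1000, 10000))
#' @export
minAltReads <- function(n, model = ErrorModel()) {
    stopifnot(is(model, "ErrorModel"))
    n <- as.integer(n)
    if (any(n < 0)) stop("depth n must be non-negative")
    ## p(m) <= fpr  <=>  pbinom(m-1, n, e/3) >= 1 - fpr; qbinom gives the
    ## smallest quantile q with pbinom(q) >= 1 - fpr, hence k = q + 1.
    q <- stats::qbinom(1 - model@fpr, n, model@e / 3)
    k <- as.integer(q) + 1L
    unattainable <- errorProb(pmin(k, n), n, model) > model@fpr
    k[unattainable] <- n[unattainable] + 1L
    k[k < 1L] <- 1L
    structure(k, unattainable = unattainable)
}

#' Zero sub-threshold variant calls and drop empty mutations
#'
#' Applies the sequencing-error power model per matrix entry: a cell's
#' call for a mutation is zeroed (VAF and alt count set to 0) when its
#' alternate-read count falls below \code{\link{minAltReads}} at that
#' cell's depth. Depths are unchanged and uncovered entries stay missing.
#' Mutations left with no positive cell are removed. The threshold is
#' per-entry because it depends on the per-cell depth. The operation is
#' idempotent.
#'
#' @param x a \linkS4class{MitoVafExperiment}.
#' @param model an \linkS4class{ErrorModel}.
#' @return the filtered \linkS4class{MitoVafExperiment}.
#' @export
applyErrorFilter <- function(x, model = ErrorModel()) {
    stopifnot(is(x, "MitoVafExperiment"))
    d <- readDepth(x)
    a <- altCounts(x)
    v <- vaf(x)
    if (!length(d)) return(x)
    depths <- sort(unique(as.vector(d)))
    k <- minAltReads(depths, model)
    kmat <- matrix(k[match(d, depths)], nrow(d), ncol(d))
    zero <- !is.na(d) & a < kmat
    a[zero] <- 0L
    v[zero & !is.na(v)] <- 0
    keep <- rowSums(a > 0, na.rm = TRUE) > 0
    if (!any(keep))
        warning("no mutation survives the sequencing-error filter")
    assay(x, "alt", withDimnames = FALSE) <- a
    assay(x, "vaf", withDimnames = FALSE) <- v
    x[keep, ]
}

#' Remove mutations with uninformative cell-level frequency
#'
#' A cell is positive for a mutation when its VAF exceeds
#' \code{positiveVaf}. Mutations whose positive fraction (among cells with
#' non-missing VAF) falls outside
#' \code{[minCellFraction, maxCellFraction]}, or that are covered in fewer
#' than \code{minCellsCovered} cells, are removed: near-absent variants
#' carry no lineage signal, and near-universal (germline-like) variants
#' cannot separate lineages. When \code{group} names a \code{colData}
#' column, the same bounds are additionally applied within each group
#' (sample-level filtering for multi-donor data) and a mutation is kept
#' only if it passes in at least one group.
#'
#' @param x a \linkS4class{MitoVafExperiment}.
#' @param filter a \linkS4class{FrequencyFilter}.
#' @param group optional \code{colData} column name for per-sample
#'   filtering; \code{NULL} (default) filters across all cells only.
#' @return the filtered \linkS4class{MitoVafExperiment} (possibly with 0
#'   rows, with a warning).
#' @export
applyFrequencyFilter <- function(x, filter = FrequencyFilter(),
                                 group = NULL) {
    stopifnot(is(x, "MitoVafExperiment"), is(filter, "FrequencyFilter"))
    v <- vaf(x)
    if (!nrow(v)) return(x)
    passFor <- function(cols) {
        vv <- v[, cols, drop = FALSE]
        covered <- rowSums(!is.na(vv))
        pos <- rowSums(vv > filter@positiveVaf, na.rm = TRUE)
        frac <- ifelse(covered > 0, pos / covered, 0)
        covered >= filter@minCellsCovered &
            frac >= filter@minCellFraction &
            frac <= filter@maxCellFraction
    }
    keep <- passFor(seq_len(ncol(v)))
    if (!is.null(group)) {
        g <- colData(x)[[group]]
        if (is.null(g)) stop("no colData column named '", group, "'")
        inGroup <- Reduce(`|`, lapply(split(seq_len(ncol(v)), g), passFor))
        keep <- keep & inGroup
    }
    if (!any(keep))
        warning("all mutations removed by the frequency filter")
    x[keep, ]
}
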