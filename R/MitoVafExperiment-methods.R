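#' Construct a MitoVafExperiment
#'
#' Bundles aligned mutation x cell matrices of variant allele frequencies,
#' read depths and alternate-read counts into a validated
#' \linkS4class{MitoVafExperiment}. Matrices are aligned by dimnames, the
#' row names must be canonical mutation identifiers
#' (\code{"MT_<pos>_<ref>-<alt>"}), and VAF entries at uncovered sites
#' (depth 0) are stored as \code{NA}.
#'
#' @param vaf numeric matrix of allele fractions in \code{[0, 1]} with
#'   mutation row names and cell column names.
#' @param depth integer matrix of total read counts, same dimnames.
#' @param alt optional integer matrix of alternate-supporting reads; when
#'   missing it is reconstructed as \code{round(vaf * depth)}.
#' @param cellAnnotations optional named vector or data.frame of per-cell
#'   labels (clone, donor, ...) merged into \code{colData}.
#' @return a \linkS4class{MitoVafExperiment}.
#' @examples
#' v <- matrix(c(0.5, 0, 0.2, 1), 2, 2,
#'             dimnames = list(c("MT_100_A-G", "MT_16389_G-A"),
#'                             c("cell1", "cell2")))
#' d <- matrix(30L, 2, 2, dimnames = dimnames(v))
#' mve <- MitoVafExperiment(v, d)
#' altCounts(mve)
#' @export
MitoVafExperiment <- function(vaf, depth, alt = NULL, cellAnnotations = NULL) {
    vaf <- as.matrix(vaf)
    depth <- .alignTo(vaf, as.matrix(depth), "depth")
    storage.mode(depth) <- "integer"
    if (is.null(alt)) {
        alt <- round(vaf * depth)
        alt[is.na(alt)] <- 0
    } else {
        alt <- .alignTo(vaf, as.matrix(alt), "alt")
    }
    storage.mode(alt) <- "integer"
    vaf[!is.na(depth) & depth == 0L] <- NA_real_
    rn <- rownames(vaf)
    if (is.null(rn)) {
        if (nrow(vaf) > 0) stop("mutation (row) names are required")
        rn <- character(0)
    }
    rd <- parseMutationId(rn)
    cd <- S4Vectors::DataFrame(row.names = colnames(vaf))
    if (!is.null(cellAnnotations)) {
        if (is.data.frame(cellAnnotations) || is(cellAnnotations, "DataFrame")) {
            ann <- cellAnnotations[match(colnames(vaf),
                                         rownames(cellAnnotations)), ,
                                   drop = FALSE]
            rownames(ann) <- colnames(vaf)
            cd <- cbind(cd, S4Vectors::DataFrame(ann))
        } else {
            cd$clone <- unname(cellAnnotations[colnames(vaf)])
        }
    }
    se <- SummarizedExperiment(
        assays = list(vaf = vaf, depth = depth, alt = alt),
        rowData = rd, colData = cd)
    new("MitoVafExperiment", se)
}

## align matrix m to the dimnames of ref, by identifier not order
.alignTo <- function(ref, m, what) {
    if (!identical(dim(ref), dim(m)))
        stop("shape mismatch between vaf and ", what, " matrices (",
             nrow(ref), "x", ncol(ref), " vs ", nrow(m), "x", ncol(m), ")")
    if (!is.null(rownames(m)) && !is.null(rownames(ref))) {
        if (!setequal(rownames(m), rownames(ref)) ||
            !setequal(colnames(m), colnames(ref)))
            stop(what, " matrix dimnames do not match the vaf matrix")
        m <- m[rownames(ref), colnames(ref), drop = FALSE]
    } else {
        dimnames(m) <- dimnames(ref)
    }
    m
}

#' Accessors for MitoVafExperiment assays and identifiers
#'
#' \code{vaf}, \code{readDepth} and \code{altCounts} return the three
#' aligned assay matrices; \code{mutationIds} and \code{cellIds} the row
#' and column identifiers; \code{cellAnnotations} the \code{colData}.
#'
#' @param x a \linkS4class{MitoVafExperiment}.
#' @param ... unused.
#' @return a matrix, character vector, or \code{DataFrame}.
#' @aliases vaf readDepth altCounts mutationIds cellIds cellAnnotations
#' @name vaf
NULL

#' @rdname vaf
#' @export
setMethod("vaf", "MitoVafExperiment", function(x, ...) assay(x, "vaf"))

#' @rdname vaf
#' @export
setMethod("readDepth", "MitoVafExperiment", function(x, ...)
    assay(x, "depth"))

#' @rdname vaf
#' @export
setMethod("altCounts", "MitoVafExperiment", function(x, ...) assay(x, "alt"))

#' @rdname vaf
#' @export
setMethod("mutationIds", "MitoVafExperiment", function(x, ...) rownames(x))

#' @rdname vaf
#' @export
setMethod("cellIds", "MitoVafExperiment", function(x, ...) colnames(x))

#' @rdname vaf
#' @export
setMethod("cellAnnotations", "MitoVafExperiment", function(x, ...) colData(x))

setMethod("show", "MitoVafExperiment", function(object) {
    cat("MitoVafExperiment:", nrow(object), "mutations x", ncol(object),
        "cells\n")
    v <- vaf(object)
    cov <- sum(!is.na(v))
    cat(sprintf("  covered entries: %d/%d (%.1f%%)\n", cov, length(v),
                if (length(v)) 100 * cov / length(v) else 100))
    if (ncol(colData(object)))
        cat("  cell annotations:",
            paste(colnames(colData(object)), collapse = ", "), "\n")
    if (nrow(object))
        cat("  mutations:", paste(utils::head(rownames(object), 3L),
                                  collapse = ", "),
            if (nrow(object) > 3L) "..." else "", "\n")
    invisible(NULL)
})

setMethod("show", "ErrorModel", function(object) {
    cat(sprintf("ErrorModel: e = %g, FPR = %g\n", object@e, object@fpr))
})

setMethod("show", "DpgmmFit", function(object) {
    cat("DpgmmFit", if (!is.na(object@mutation)) object@mutation else "",
        "\n")
    cat("  components:", object@nComponents,
        " cells:", object@nCells, "\n")
    if (object@nComponents >= 1L) {
        cat("  weights: ", paste(sprintf("%.3f", object@weights),
                                 collapse = " "), "\n")
        cat("  means:   ", paste(sprintf("%.3f", object@means),
                                 collapse = " "), "\n")
    }
    if (!is.na(object@top2MeanDiff))
        cat(sprintf("  top-two mean difference: %.4f\n",
                    object@top2MeanDiff))
    invisible(NULL)
})

#' Parameter-object constructors
#'
#' Convenience constructors with the package defaults: sequencing-error
#' model (\code{e} = 1e-3, \code{fpr} = 5e-7), cell-frequency filter, and
#' the DP mixture configuration.
#'
#' @param e,fpr sequencing error rate and false-positive rate.
#' @return a validated parameter object.
#' @examples
#' ErrorModel()
#' FrequencyFilter(maxCellFraction = 0.9)
#' @export
ErrorModel <- function(e = 1e-3, fpr = 5e-7) new("ErrorModel", e = e, fpr = fpr)

#' @rdname ErrorModel
#' @param minCellFraction,maxCellFraction bounds on the positive-cell
#'   fraction.
#' @param minCellsCovered minimum number of covered cells.
#' @param positiveVaf VAF above which a cell counts as positive.
#' @export
FrequencyFilter <- function(minCellFraction = 0.01, maxCellFraction = 0.65,
                            minCellsCovered = 5L, positiveVaf = 0.01) {
    new("FrequencyFilter", minCellFraction = minCellFraction,
        maxCellFraction = maxCellFraction,
        minCellsCovered = as.integer(minCellsCovered),
        positiveVaf = positiveVaf)
}

#' @rdname ErrorModel
#' @param alpha DP concentration parameter.
#' @param nIter,nBurnin Gibbs sweeps and burn-in (\code{NA} = automatic).
#' @param seed RNG seed (\code{NA} = use current RNG state).
#' @param minComponentWeight occupancy below which a cluster is discarded.
#' @param informativeCutoff minimum top-two component separation (VAF
#'   scale).
#' @param minCells minimum non-missing values to attempt a fit.
#' @export
DpgmmConfig <- function(alpha = 0.05, nIter = NA, nBurnin = NA, seed = NA,
                        minComponentWeight = 0.02, informativeCutoff = 0.05,
                        minCells = 10L) {
    new("DpgmmConfig", alpha = alpha, nIter = as.integer(nIter),
        nBurnin = as.integer(nBurnin), seed = as.integer(seed),
        minComponentWeight = minComponentWeight,
        informativeCutoff = informativeCutoff,
        minCells = as.integer(minCells))
}

#' @rdname ErrorModel
#' @param nCells,nClones simulated cells and clones.
#' @param lambdaClone Poisson rate of extra clone-specific mutations per
#'   edge.
#' @param germlineLambda Poisson rate of the germline mutation count.
#' @param germlineCarrierProb per-cell carriage probability of each
#'   germline mutation.
#' @param cellPrivateLambda Poisson rate of private mutations per cell.
#' @param hetBeta Beta shape parameters of new-mutation heteroplasmy.
#' @param germlineVafRange uniform range of germline VAF.
#' @param depth sequencing depth per site.
#' @param errorRate per-base sequencing error rate.
#' @param genomeLength MT genome length.
#' @param depthModel \code{"fixed"} or \code{"poisson"}.
#' @param germlineMode \code{"independent"} or \code{"strict"}.
#' @param newick optional rooted clone tree (Newick string).
#' @export
SimConfig <- function(nCells = 100L, nClones = 6L, lambdaClone = 1,
                      germlineLambda = 10, germlineCarrierProb = 0.8,
                      cellPrivateLambda = 0.1, hetBeta = c(2, 5),
                      germlineVafRange = c(0.5, 1), depth = 30L,
                      errorRate = 1e-3, genomeLength = 16569L,
                      depthModel = "fixed", germlineMode = "independent",
                      newick = NA_character_) {
    new("SimConfig", nCells = as.integer(nCells),
        nClones = as.integer(nClones), lambdaClone = lambdaClone,
        germlineLambda = germlineLambda,
        germlineCarrierProb = germlineCarrierProb,
        cellPrivateLambda = cellPrivateLambda, hetBeta = hetBeta,
        germlineVafRange = germlineVafRange, depth = as.integer(depth),
        errorRate = errorRate, genomeLength = as.integer(genomeLength),
        depthModel = depthModel, germlineMode = germlineMode,
        newick = newick)
}
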