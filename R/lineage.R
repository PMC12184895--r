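#' Mitochondrial allele-frequency distance between cells or clones
#'
#' For observations \eqn{i, j} over informative mutations \eqn{x}, the
#' distance is the mean absolute allele-frequency difference over the
#' sites where at least one of the pair shows sufficient allele frequency
#' (\code{> minAf}):
#' \deqn{d_{i,j} = \frac{\sum_x |AF_{x,i} - AF_{x,j}| \,
#'   (I_{AF_{x,i} > 0.01} \vee I_{AF_{x,j} > 0.01})}
#'   {\sum_x (I_{AF_{x,i} > 0.01} \vee I_{AF_{x,j} > 0.01})}.}
#' Sites below the floor in both members contribute nothing, so shared
#' absence of a variant is not treated as similarity. The distance lies
#' in \code{[0, 1]}; when every allele frequency exceeds the floor it
#' reduces to the Manhattan distance divided by the number of mutations.
#'
#' Missing VAFs (uncovered sites) count as 0 for the indicator; a site is
#' excluded from a pair only when it is missing in both members. A pair
#' with no contributing site has no allele-frequency evidence at all and
#' is assigned the maximal distance 1, with a warning.
#'
#' @param x a \linkS4class{MitoVafExperiment} restricted to the
#'   informative mutations (or any VAF matrix, mutations x cells).
#' @param minAf allele-frequency floor for the indicator (default 0.01).
#' @return a \code{stats::dist} over cells with attributes
#'   \code{"metric" = "mito"} and \code{"minAf"}.
#' @seealso \code{\link{altDistance}}, \code{\link{clusterLineage}}
#' @export
mitoDistance <- function(x, minAf = 0.01) {
    v <- if (is(x, "MitoVafExperiment")) vaf(x) else as.matrix(x)
    if (!nrow(v)) stop("no mutations: cannot compute a distance")
    n <- ncol(v)
    miss <- is.na(v)
    v0 <- v
    v0[miss] <- 0
    ind <- v0 > minAf
    d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
    degenerate <- FALSE
    for (i in seq_len(n - 1L)) {
        vi <- v0[, i]; ii <- ind[, i]; mi <- miss[, i]
        for (j in seq.int(i + 1L, n)) {
            use <- (ii | ind[, j]) & !(mi & miss[, j])
            den <- sum(use)
            if (den == 0L) {
                d[i, j] <- d[j, i] <- 1
                degenerate <- TRUE
            } else {
                d[i, j] <- d[j, i] <-
                    sum(abs(vi[use] - v0[use, j])) / den
            }
        }
    }
    if (degenerate)
        warning("pair(s) with no site above the allele-frequency floor; ",
                "distance set to 1")
    out <- stats::as.dist(d)
    attr(out, "metric") <- "mito"
    attr(out, "minAf") <- minAf
    out
}

#' Euclidean or correlation distance over VAF profiles
#'
#' Standard alternatives to the mitochondrial distance: Euclidean
#' distance between cells' VAF columns, or 1 minus the Pearson
#' correlation. Missing entries are handled pairwise-complete; a
#' zero-variance column under the correlation metric yields distance 1
#' for its pairs, with a warning.
#'
#' @param x a \linkS4class{MitoVafExperiment} or VAF matrix
#'   (mutations x cells).
#' @param metric \code{"euclidean"} or \code{"correlation"}.
#' @return a \code{stats::dist} with attribute \code{"metric"}.
#' @export
altDistance <- function(x, metric = c("euclidean", "correlation")) {
    metric <- match.arg(metric)
    v <- if (is(x, "MitoVafExperiment")) vaf(x) else as.matrix(x)
    if (!nrow(v)) stop("no mutations: cannot compute a distance")
    if (metric == "euclidean") {
        out <- stats::dist(t(v), method = "euclidean")
    } else {
        if (nrow(v) < 2L)
            stop("correlation distance requires >= 2 mutations")
        suppressWarnings(
            cc <- stats::cor(v, use = "pairwise.complete.obs"))
        if (anyNA(cc)) {
            warning("zero-variance VAF column(s): correlation distance ",
                    "set to 1 for affected pairs")
            cc[is.na(cc)] <- 0
        }
        diag(cc) <- 1
        out <- stats::as.dist(1 - cc)
    }
    attr(out, "metric") <- metric
    out
}

#' Hierarchical clustering of cells from a distance matrix
#'
#' Agglomerative clustering on a precomputed distance, returning the
#' dendrogram and, when \code{k} is given, the flat clusters obtained by
#' cutting it. Ward linkage presumes Euclidean geometry and is rejected
#' for the mitochondrial metric. \code{stats::hclust} agglomeration is
#' deterministic: equal-height candidates merge lowest-index first.
#'
#' @param d a \code{stats::dist} (e.g. from \code{\link{mitoDistance}}).
#' @param linkage one of \code{"average"} (default), \code{"complete"},
#'   \code{"single"}, \code{"ward.D2"}.
#' @param k optional number of flat clusters (\code{1 <= k <= n}).
#' @return a \linkS4class{LineageResult}.
#' @export
clusterLineage <- function(d, linkage = c("average", "complete", "single",
                                          "ward.D2"), k = NULL) {
    linkage <- match.arg(linkage)
    stopifnot(inherits(d, "dist"))
    if (startsWith(linkage, "ward") &&
        identical(attr(d, "metric"), "mito"))
        stop("ward linkage requires Euclidean geometry; ",
             "use average/complete/single with the mito metric")
    hc <- stats::hclust(d, method = linkage)
    cl <- integer(0)
    if (!is.null(k)) {
        n <- attr(d, "Size")
        if (k < 1L || k > n) stop("k must lie in 1..", n)
        cl <- stats::cutree(hc, k = k)
    }
    new("LineageResult", hclust = hc, clusters = cl,
        k = if (is.null(k)) NA_integer_ else as.integer(k),
        linkage = linkage)
}

setMethod("show", "LineageResult", function(object) {
    cat("LineageResult:", length(object@hclust$labels), "cells,",
        object@linkage, "linkage\n")
    if (!is.na(object@k))
        cat("  flat clusters (k =", object@k, "):",
            paste(table(object@clusters), collapse = "/"), "cells\n")
    invisible(NULL)
})

#' Export heatmap-ready lineage artifacts
#'
#' Writes the VAF matrix with columns (cells) in dendrogram leaf order,
#' the flat cluster assignments (one line per cell) and the dendrogram in
#' Newick format, for downstream heatmap/tree rendering.
#'
#' @param x the \linkS4class{MitoVafExperiment} the clustering was
#'   computed from.
#' @param result a \linkS4class{LineageResult}.
#' @param outPrefix path prefix; files \code{<prefix>_vaf_ordered.csv},
#'   \code{<prefix>_clusters.csv} and \code{<prefix>_dendrogram.nwk} are
#'   written.
#' @return invisibly, the named vector of paths written.
#' @export
exportHeatmapData <- function(x, result, outPrefix) {
    stopifnot(is(x, "MitoVafExperiment"), is(result, "LineageResult"))
    hc <- result@hclust
    leaves <- hc$labels[hc$order]
    if (!all(leaves %in% cellIds(x)))
        stop("clustering labels do not match the dataset's cells")
    v <- vaf(x)[, leaves, drop = FALSE]
    dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
    vafPath <- paste0(outPrefix, "_vaf_ordered.csv")
    data.table::fwrite(data.frame(mutation = rownames(v), v,
                                  check.names = FALSE), vafPath, na = "NA")
    clPath <- paste0(outPrefix, "_clusters.csv")
    cl <- if (length(result@clusters)) result@clusters[leaves]
          else stats::setNames(rep(NA_integer_, length(leaves)), leaves)
    data.table::fwrite(data.frame(cell = leaves, cluster = unname(cl)),
                       clPath)
    nwkPath <- paste0(outPrefix, "_dendrogram.nwk")
    ape::write.tree(ape::as.phylo(hc), file = nwkPath)
    invisible(c(vaf = vafPath, clusters = clPath, newick = nwkPath))
}
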