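#' Build a clonal tree with per-edge mutation placement
#'
#' Constructs a rooted clonal tree and places clone-specific mutations on
#' its edges: every time a parent node produces a descendant, the new
#' edge acquires \code{1 + Poisson(lambdaClone)} mutations, so each
#' lineage carries at least one private marker. Mutation positions are
#' drawn uniformly without replacement from the mitochondrial genome
#' (each site mutates at most once anywhere in the tree; no parallel or
#' back mutations) and each mutation's heteroplasmy is drawn from
#' \code{Beta(hetBeta)}. Germline mutations (\code{Poisson(germlineLambda)}
#' of them, population VAF uniform on \code{germlineVafRange}) are
#' attached at the root.
#'
#' By default the tree has \code{nClones} clones under the root, each
#' split into two subclones, mirroring a population in which major clones
#' harbour finer subclonal structure. Any rooted Newick string may be
#' supplied instead (e.g. a star over the clones for a flat population).
#'
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{CloneTree}.
#' @seealso \code{\link{assignCells}}, \code{\link{simulateDataset}}
#' @export
buildCloneTree <- function(config = SimConfig()) {
    stopifnot(is(config, "SimConfig"))
    nwk <- config@newick
    if (is.na(nwk)) {
        clones <- sprintf("C%d", seq_len(config@nClones))
        sub <- vapply(clones, function(cl)
            sprintf("(%sa,%sb)%s", cl, cl, cl), "")
        nwk <- paste0("(", paste(sub, collapse = ","), ")root;")
    }
    tr <- ape::read.tree(text = nwk)
    if (is.null(tr) || is.na(ape::Ntip(tr)))
        stop("could not parse the Newick tree")
    if (is.null(tr$node.label))
        tr$node.label <- sprintf("node%d", seq_len(tr$Nnode))
    labels <- c(tr$tip.label, tr$node.label)
    if (anyDuplicated(labels)) stop("tree node labels must be unique")
    edges <- tr$edge
    nPerEdge <- 1L + stats::rpois(nrow(edges), config@lambdaClone)
    nGerm <- stats::rpois(1L, config@germlineLambda)
    total <- sum(nPerEdge) + nGerm
    if (total > config@genomeLength)
        stop("more mutations requested than genomic positions")
    pos <- sample.int(config@genomeLength, total)
    ids <- .randomMutationIds(pos)
    cs <- seq_len(sum(nPerEdge))
    em <- data.frame(
        node = rep(labels[edges[, 2L]], nPerEdge),
        mutation = ids[cs],
        heteroplasmy = stats::rbeta(length(cs), config@hetBeta[1L],
                                    config@hetBeta[2L]),
        stringsAsFactors = FALSE)
    germ <- data.frame(
        mutation = ids[setdiff(seq_len(total), cs)],
        vaf = stats::runif(nGerm, config@germlineVafRange[1L],
                           config@germlineVafRange[2L]),
        stringsAsFactors = FALSE)
    new("CloneTree", phylo = tr, edgeMutations = em, germline = germ)
}

.randomMutationIds <- function(pos) {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pos), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    makeMutationId(pos, ref, unname(alt))
}

## per-node root-to-node path mutations, as a named list of row indices
## into edgeMutations
.pathMutations <- function(tree) {
    tr <- tree@phylo
    labels <- c(tr$tip.label, tr$node.label)
    root <- ape::Ntip(tr) + 1L
    parent <- integer(ape::Ntip(tr) + tr$Nnode)
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    em <- tree@edgeMutations
    byNode <- split(seq_len(nrow(em)), em$node)
    nodes <- setdiff(seq_along(labels), root)
    paths <- lapply(nodes, function(nd) {
        rows <- integer(0)
        while (nd != root) {
            rows <- c(rows, byNode[[labels[nd]]])
            nd <- parent[nd]
        }
        rows
    })
    names(paths) <- labels[nodes]
    paths
}

## top-level clone (child of the root) each node belongs to
.nodeClone <- function(tree) {
    tr <- tree@phylo
    labels <- c(tr$tip.label, tr$node.label)
    root <- ape::Ntip(tr) + 1L
    parent <- integer(length(labels))
    parent[tr$edge[, 2L]] <- tr$edge[, 1L]
    nodes <- setdiff(seq_along(labels), root)
    clone <- vapply(nodes, function(nd) {
        while (parent[nd] != root) nd <- parent[nd]
        labels[nd]
    }, "")
    stats::setNames(clone, labels[nodes])
}

#' Assign pseudo-cells to clones and draw their true heteroplasmies
#'
#' Cells are assigned uniformly at random to the non-root nodes of the
#' clonal tree and inherit every clone-specific mutation on their
#' root-to-node path at that mutation's heteroplasmy. Each germline
#' mutation is carried by each cell independently with probability
#' \code{germlineCarrierProb} (or by exactly
#' \code{ceiling(p * nCells)} cells in \code{"strict"} mode) at the
#' mutation's population VAF. Finally each cell acquires
#' \code{Poisson(cellPrivateLambda)} private mutations at fresh genomic
#' positions with Beta-distributed heteroplasmy; these carry no
#' clone-tracking signal.
#'
#' @param tree a \linkS4class{CloneTree}.
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{SimTruth} with the true (noise-free)
#'   heteroplasmy matrix.
#' @export
assignCells <- function(tree, config = SimConfig()) {
    stopifnot(is(tree, "CloneTree"), is(config, "SimConfig"))
    nCells <- config@nCells
    cells <- sprintf("cell%03d", seq_len(nCells))
    paths <- .pathMutations(tree)
    nodeClone <- .nodeClone(tree)
    nodeOf <- sample(names(paths), nCells, replace = TRUE)
    em <- tree@edgeMutations
    germ <- tree@germline

    nPriv <- stats::rpois(nCells, config@cellPrivateLambda)
    used <- parseMutationId(c(em$mutation, germ$mutation))$position
    free <- setdiff(seq_len(config@genomeLength), used)
    privPos <- sample(free, sum(nPriv))
    privIds <- .randomMutationIds(privPos)
    privHet <- stats::rbeta(sum(nPriv), config@hetBeta[1L],
                            config@hetBeta[2L])
    privCell <- rep(seq_len(nCells), nPriv)

    muts <- c(em$mutation, germ$mutation, privIds)
    classes <- stats::setNames(
        rep(c("clone_specific", "germline", "cell_private"),
            c(nrow(em), nrow(germ), length(privIds))), muts)
    tv <- matrix(0, length(muts), nCells, dimnames = list(muts, cells))
    for (i in seq_len(nCells)) {
        rows <- paths[[nodeOf[i]]]
        tv[rows, i] <- em$heteroplasmy[rows]
    }
    if (nrow(germ)) {
        carrier <- if (config@germlineMode == "independent") {
            matrix(stats::runif(nrow(germ) * nCells) <
                       config@germlineCarrierProb, nrow(germ), nCells)
        } else {
            nCarry <- min(nCells,
                          ceiling(config@germlineCarrierProb * nCells))
            t(vapply(seq_len(nrow(germ)), function(g) {
                z <- logical(nCells)
                z[sample.int(nCells, nCarry)] <- TRUE
                z
            }, logical(nCells)))
        }
        gRows <- nrow(em) + seq_len(nrow(germ))
        tv[gRows, ] <- carrier * germ$vaf
    }
    if (length(privIds)) {
        pRows <- nrow(em) + nrow(germ) + seq_along(privIds)
        tv[cbind(pRows, privCell)] <- privHet
    }
    new("SimTruth", cellClone = stats::setNames(nodeClone[nodeOf], cells),
        cellNode = stats::setNames(nodeOf, cells),
        mutationClass = classes, trueVaf = tv, tree = tree)
}

#' Generate read counts from true heteroplasmies
#'
#' For each mutation and cell, the observed alternate-read count is drawn
#' from a binomial read-count model,
#' \code{alt ~ Binomial(depth, q)} with
#' \code{q = v (1 - e) + (1 - v) e / 3}, where \code{v} is the cell's true
#' heteroplasmy (0 for non-carriers) and \code{e} the per-base error
#' rate; the \code{e/3} term matches the error convention of the
#' sequencing-error filter. Depth is fixed at \code{config@depth}
#' (or drawn \code{Poisson(depth)} in \code{"poisson"} depth mode, in
#' which case zero-depth entries become missing VAFs).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param config a \linkS4class{SimConfig}.
#' @return a \linkS4class{MitoVafExperiment} with clone and node labels in
#'   \code{colData} and the mutation class in \code{rowData}.
#' @export
simulateReads <- function(truth, config = SimConfig()) {
    stopifnot(is(truth, "SimTruth"), is(config, "SimConfig"))
    v <- truth@trueVaf
    e <- config@errorRate
    q <- v * (1 - e) + (1 - v) * e / 3
    depth <- if (config@depthModel == "fixed") {
        matrix(config@depth, nrow(v), ncol(v))
    } else {
        matrix(stats::rpois(length(v), config@depth), nrow(v), ncol(v))
    }
    dimnames(depth) <- dimnames(v)
    alt <- matrix(stats::rbinom(length(v), as.vector(depth), as.vector(q)),
                  nrow(v), ncol(v), dimnames = dimnames(v))
    vafObs <- ifelse(depth > 0, alt / depth, NA_real_)
    ann <- S4Vectors::DataFrame(clone = unname(truth@cellClone),
                                node = unname(truth@cellNode),
                                row.names = colnames(v))
    out <- MitoVafExperiment(vafObs, depth, alt = alt,
                             cellAnnotations = ann)
    rowData(out)$class <- unname(truth@mutationClass[rownames(out)])
    out
}

#' Simulate a complete ground-truth dataset
#'
#' Chains \code{\link{buildCloneTree}}, \code{\link{assignCells}} and
#' \code{\link{simulateReads}} under one seed.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param seed optional integer seed; \code{NA} uses the current RNG
#'   state.
#' @return a list with \code{dataset} (a
#'   \linkS4class{MitoVafExperiment}) and \code{truth} (a
#'   \linkS4class{SimTruth}).
#' @examples
#' sim <- simulateDataset(SimConfig(nCells = 30), seed = 1)
#' sim$dataset
#' table(sim$truth@mutationClass)
#' @export
simulateDataset <- function(config = SimConfig(), seed = NA) {
    if (!is.na(seed)) set.seed(seed)
    tree <- buildCloneTree(config)
    truth <- assignCells(tree, config)
    ds <- simulateReads(truth, config)
    list(dataset = ds, truth = truth)
}

#' Write and read simulation ground truth
#'
#' \code{writeTruth} writes three comma-separated tables and the clonal
#' tree: \code{<prefix>_cells.csv} (cell, clone, node),
#' \code{<prefix>_mutations.csv} (mutation, class),
#' \code{<prefix>_true_vaf.csv} (true heteroplasmy matrix) and
#' \code{<prefix>_tree.nwk}. \code{readTruth} reconstructs the
#' \linkS4class{SimTruth} (without per-edge mutation assignments).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param outPrefix path prefix for the output files.
#' @return \code{writeTruth}: invisibly, the vector of paths written;
#'   \code{readTruth}: a \linkS4class{SimTruth}.
#' @export
writeTruth <- function(truth, outPrefix) {
    stopifnot(is(truth, "SimTruth"))
    dir.create(dirname(outPrefix), showWarnings = FALSE, recursive = TRUE)
    cellsPath <- paste0(outPrefix, "_cells.csv")
    data.table::fwrite(data.frame(cell = names(truth@cellClone),
                                  clone = unname(truth@cellClone),
                                  node = unname(truth@cellNode)),
                       cellsPath)
    mutPath <- paste0(outPrefix, "_mutations.csv")
    data.table::fwrite(data.frame(mutation = names(truth@mutationClass),
                                  class = unname(truth@mutationClass)),
                       mutPath)
    tvPath <- paste0(outPrefix, "_true_vaf.csv")
    data.table::fwrite(data.frame(mutation = rownames(truth@trueVaf),
                                  truth@trueVaf, check.names = FALSE),
                       tvPath)
    paths <- c(cells = cellsPath, mutations = mutPath, true_vaf = tvPath)
    if (is(truth@tree, "CloneTree")) {
        nwk <- paste0(outPrefix, "_tree.nwk")
        ape::write.tree(truth@tree@phylo, file = nwk)
        paths <- c(paths, tree = nwk)
    }
    invisible(paths)
}

#' @rdname writeTruth
#' @param prefix the path prefix used by \code{writeTruth}.
#' @export
readTruth <- function(prefix) {
    cells <- data.table::fread(paste0(prefix, "_cells.csv"),
                               data.table = FALSE)
    muts <- data.table::fread(paste0(prefix, "_mutations.csv"),
                              data.table = FALSE)
    tv <- data.table::fread(paste0(prefix, "_true_vaf.csv"),
                            data.table = FALSE)
    m <- as.matrix(tv[, -1L, drop = FALSE])
    rownames(m) <- tv[[1L]]
    tree <- NULL
    nwk <- paste0(prefix, "_tree.nwk")
    if (file.exists(nwk)) tree <- ape::read.tree(nwk)
    new("SimTruth",
        cellClone = stats::setNames(cells$clone, cells$cell),
        cellNode = stats::setNames(cells$node, cells$cell),
        mutationClass = stats::setNames(muts$class, muts$mutation),
        trueVaf = m, tree = tree)
}
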