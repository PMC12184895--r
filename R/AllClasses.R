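#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame SimpleList metadata metadata<-
NULL

## MT genome length (rCRS); mutation positions are 1-based on this reference.
MT_GENOME_LENGTH <- 16569L

#' MitoVafExperiment: per-cell mitochondrial variant allele frequencies
#'
#' A \linkS4class{SummarizedExperiment} holding, for each mitochondrial
#' mutation (row) and cell (column), three aligned assays: \code{vaf}
#' (alternate-allele fraction in \code{[0, 1]}, \code{NA} where the site is
#' not covered), \code{depth} (total reads at the site) and \code{alt}
#' (alternate-supporting reads). Row names are canonical mutation
#' identifiers of the form \code{"MT_<position>_<ref>-<alt>"}
#' (e.g. \code{"MT_16389_G-A"}); \code{rowData} carries the parsed
#' \code{position}, \code{ref} and \code{alt} fields. Optional cell
#' annotations (clone, patient, ...) live in \code{colData}.
#'
#' A covered reference-allele site (VAF 0) and an uncovered site are
#' different evidence: VAF is \code{NA} wherever depth is 0, and downstream
#' operations document which convention they use.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @seealso \code{\link{MitoVafExperiment}} (constructor),
#'   \code{\link{readVafDataset}}, \code{\link{vaf}}
#' @export
setClass("MitoVafExperiment", contains = "SummarizedExperiment")

.validMitoVafExperiment <- function(object) {
    msg <- NULL
    an <- assayNames(object)
    need <- c("vaf", "depth", "alt")
    if (!all(need %in% an))
        return(paste0("assays must include ", paste(need, collapse = ", ")))
    v <- assay(object, "vaf")
    d <- assay(object, "depth")
    a <- assay(object, "alt")
    if (is.null(rownames(object)) && nrow(object) > 0)
        msg <- c(msg, "mutation (row) names are required")
    if (is.null(colnames(object)) && ncol(object) > 0)
        msg <- c(msg, "cell (column) names are required")
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "mutation identifiers must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "cell identifiers must be unique")
    if (length(d) && (any(d < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE)))
        msg <- c(msg, "depth and alt counts must be non-negative")
    if (length(d) && any(a > d, na.rm = TRUE)) {
        bad <- which(a > d, arr.ind = TRUE)[1L, ]
        msg <- c(msg, sprintf("alt > depth first at mutation '%s', cell '%s'",
                              rownames(object)[bad[1L]],
                              colnames(object)[bad[2L]]))
    }
    if (length(d)) {
        cov <- !is.na(d) & d > 0
        if (any(is.na(v[cov])))
            msg <- c(msg, "vaf must be non-missing where depth > 0")
        ## allow half a read of slack: alt may have been reconstructed
        ## by rounding vaf * depth
        else if (any(abs(v[cov] - a[cov] / d[cov]) >
                     0.5 / d[cov] + 1e-9))
            msg <- c(msg, "vaf must equal alt/depth where depth > 0")
        if (any(!is.na(v[!cov])))
            msg <- c(msg, "vaf must be NA where depth = 0")
    }
    rd <- rowData(object)
    if (!all(c("position", "ref", "alt") %in% colnames(rd)))
        msg <- c(msg, "rowData must carry position, ref, alt")
    if (is.null(msg)) TRUE else msg
}

setValidity("MitoVafExperiment", .validMitoVafExperiment)

#' Sequencing-error model
#'
#' Parameters of the binomial sequencing-error power model: the per-base
#' error rate \code{e} and the acceptable false-positive rate \code{fpr}
#' used to derive, at each read depth, the minimum number of identical
#' alternate reads that genuine heteroplasmy must show.
#'
#' @slot e numeric(1), per-base sequencing error probability (default 1e-3).
#' @slot fpr numeric(1), tolerated false-positive rate (default 5e-7).
#' @seealso \code{\link{errorProb}}, \code{\link{minAltReads}},
#'   \code{\link{applyErrorFilter}}
#' @export
setClass("ErrorModel", representation(e = "numeric", fpr = "numeric"),
         prototype(e = 1e-3, fpr = 5e-7))

setValidity("ErrorModel", function(object) {
    if (length(object@e) != 1L || length(object@fpr) != 1L)
        return("e and fpr must be scalars")
    if (!(object@e > 0 && object@e < 1)) return("e must lie in (0, 1)")
    if (!(object@fpr > 0 && object@fpr < 1)) return("fpr must lie in (0, 1)")
    TRUE
})

#' Cell-frequency filter settings
#'
#' Bounds on the fraction of cells in which a mutation is detected.
#' Variants positive in almost no cell carry no signal; variants positive
#' in nearly every cell (germline-like) cannot separate lineages either.
#'
#' @slot minCellFraction numeric(1), lower bound on the positive-cell
#'   fraction (default 0.01).
#' @slot maxCellFraction numeric(1), upper bound (default 0.65; germline
#'   variants are expected in >= 80\% of a donor's cells and their
#'   observed positive fraction fluctuates binomially around the carriage
#'   rate, so the bound sits several standard errors below 0.8 to remove
#'   the germline class reliably while keeping clone-restricted
#'   variants).
#' @slot minCellsCovered integer(1), minimum number of cells with non-zero
#'   depth at the site (default 5).
#' @slot positiveVaf numeric(1), VAF above which a cell counts as positive
#'   (default 0.01, the same allele-frequency floor the lineage distance
#'   uses).
#' @seealso \code{\link{applyFrequencyFilter}}
#' @export
setClass("FrequencyFilter",
         representation(minCellFraction = "numeric",
                        maxCellFraction = "numeric",
                        minCellsCovered = "integer",
                        positiveVaf = "numeric"),
         prototype(minCellFraction = 0.01, maxCellFraction = 0.65,
                   minCellsCovered = 5L, positiveVaf = 0.01))

setValidity("FrequencyFilter", function(object) {
    if (object@minCellFraction >= object@maxCellFraction)
        return("minCellFraction must be < maxCellFraction")
    if (object@minCellFraction < 0 || object@maxCellFraction > 1)
        return("cell fractions must lie in [0, 1]")
    if (object@minCellsCovered < 0) return("minCellsCovered must be >= 0")
    if (object@positiveVaf < 0 || object@positiveVaf >= 1)
        return("positiveVaf must lie in [0, 1)")
    TRUE
})

#' Dirichlet-process Gaussian mixture configuration
#'
#' Settings for the per-mutation DP mixture fit by collapsed Gibbs
#' sampling. The number of sweeps defaults to 10,000 when fewer than 100
#' cells contribute values and 5,000 otherwise; burn-in defaults to half
#' the sweeps.
#'
#' @slot alpha numeric(1), DP concentration (default 0.05; small values
#'   keep a single Gaussian from being split into overlapping
#'   components, while well-separated peaks are still recovered).
#' @slot nIter integer(1), Gibbs sweeps; \code{NA} selects the cell-number
#'   based default.
#' @slot nBurnin integer(1), discarded sweeps; \code{NA} means
#'   \code{nIter / 2}.
#' @slot seed integer(1), RNG seed; \code{NA} leaves the current RNG state
#'   untouched.
#' @slot minComponentWeight numeric(1), occupancy fraction below which a
#'   sampled cluster is treated as MCMC dust (default 0.02).
#' @slot informativeCutoff numeric(1), minimum VAF-scale separation of the
#'   two largest-weight components for a mutation to be called
#'   informative (default 0.05, the scale of a typical minor allele
#'   frequency).
#' @slot minCells integer(1), minimum non-missing values to attempt a fit
#'   (default 10).
#' @seealso \code{\link{fitDpgmm}}, \code{\link{selectInformative}}
#' @export
setClass("DpgmmConfig",
         representation(alpha = "numeric", nIter = "integer",
                        nBurnin = "integer", seed = "integer",
                        minComponentWeight = "numeric",
                        informativeCutoff = "numeric",
                        minCells = "integer"),
         prototype(alpha = 0.05, nIter = NA_integer_, nBurnin = NA_integer_,
                   seed = NA_integer_, minComponentWeight = 0.02,
                   informativeCutoff = 0.05, minCells = 10L))

setValidity("DpgmmConfig", function(object) {
    if (object@alpha <= 0) return("alpha must be positive")
    if (!is.na(object@nIter) && !is.na(object@nBurnin) &&
        object@nBurnin >= object@nIter)
        return("nBurnin must be smaller than nIter")
    if (object@minComponentWeight < 0 || object@minComponentWeight >= 0.5)
        return("minComponentWeight must lie in [0, 0.5)")
    if (object@informativeCutoff < 0)
        return("informativeCutoff must be non-negative")
    if (object@minCells < 2L) return("minCells must be >= 2")
    TRUE
})

#' Per-mutation DP mixture fit summary
#'
#' Posterior summary of a single mutation's cross-cell VAF mixture:
#' number of retained components, their weights, means and variances on
#' the original VAF scale, and the separation of the two largest-weight
#' components. Components are ordered by decreasing weight.
#'
#' @slot mutation character(1), canonical mutation id (may be \code{NA}).
#' @slot nComponents integer(1).
#' @slot weights numeric, mixing proportions (positive, sum to 1).
#' @slot means numeric, component means on the VAF scale.
#' @slot variances numeric, component variances on the VAF scale.
#' @slot top2MeanDiff numeric(1), |difference of the two largest-weight
#'   component means| on the VAF scale; \code{NA} when fewer than two
#'   components.
#' @slot center,scale numeric(1), the standardization applied before
#'   sampling (mean and sd of the input VAFs).
#' @slot nCells integer(1), number of non-missing values fitted.
#' @slot kPosterior integer, posterior tally of occupied-cluster counts
#'   over retained sweeps (named by K).
#' @export
setClass("DpgmmFit",
         representation(mutation = "character", nComponents = "integer",
                        weights = "numeric", means = "numeric",
                        variances = "numeric", top2MeanDiff = "numeric",
                        center = "numeric", scale = "numeric",
                        nCells = "integer", kPosterior = "integer"))

setValidity("DpgmmFit", function(object) {
    k <- object@nComponents
    if (k >= 1L && length(object@weights)) {
        if (abs(sum(object@weights) - 1) > 1e-9)
            return("weights must sum to 1")
        if (any(object@weights <= 0)) return("weights must be positive")
        if (is.unsorted(rev(object@weights)))
            return("components must be ordered by decreasing weight")
    }
    if (!is.na(object@top2MeanDiff) && object@top2MeanDiff < 0)
        return("top2MeanDiff must be non-negative")
    TRUE
})

#' Clonal-tree simulation settings
#'
#' Parameters of the ground-truth simulator: a rooted clonal tree whose
#' edges acquire clone-specific mutations, germline variants shared by
#' most cells, rare cell-private variants, and a binomial read-count
#' model at fixed depth.
#'
#' @slot nCells integer(1), pseudo-cells to simulate (default 100).
#' @slot nClones integer(1), clones under the root (default 6).
#' @slot lambdaClone numeric(1), Poisson rate of extra clone-specific
#'   mutations per tree edge, on top of the one guaranteed mutation
#'   (default 1).
#' @slot germlineLambda numeric(1), Poisson rate of the germline mutation
#'   count (default 10).
#' @slot germlineCarrierProb numeric(1), probability a cell carries each
#'   germline mutation (default 0.8).
#' @slot cellPrivateLambda numeric(1), Poisson rate of private mutations
#'   per cell (default 0.1).
#' @slot hetBeta numeric(2), Beta shape parameters of new-mutation
#'   heteroplasmy (default c(2, 5), VAF mass around 0.2).
#' @slot germlineVafRange numeric(2), uniform range of germline VAF
#'   (default c(0.5, 1)).
#' @slot depth integer(1), sequencing depth per site per cell (default 30).
#' @slot errorRate numeric(1), per-base sequencing error rate (default 1e-3).
#' @slot genomeLength integer(1), MT genome length (default 16569).
#' @slot depthModel character(1), \code{"fixed"} or \code{"poisson"}.
#' @slot germlineMode character(1), \code{"independent"} (each cell carries
#'   each germline mutation independently with \code{germlineCarrierProb})
#'   or \code{"strict"} (exactly \code{ceiling(p * nCells)} carriers).
#' @slot newick character(1), rooted clone tree in Newick; \code{NA} builds
#'   the default two-level tree (each clone split into two subclones).
#' @seealso \code{\link{buildCloneTree}}, \code{\link{simulateDataset}}
#' @export
setClass("SimConfig",
         representation(nCells = "integer", nClones = "integer",
                        lambdaClone = "numeric", germlineLambda = "numeric",
                        germlineCarrierProb = "numeric",
                        cellPrivateLambda = "numeric", hetBeta = "numeric",
                        germlineVafRange = "numeric", depth = "integer",
                        errorRate = "numeric", genomeLength = "integer",
                        depthModel = "character", germlineMode = "character",
                        newick = "character"),
         prototype(nCells = 100L, nClones = 6L, lambdaClone = 1,
                   germlineLambda = 10, germlineCarrierProb = 0.8,
                   cellPrivateLambda = 0.1, hetBeta = c(2, 5),
                   germlineVafRange = c(0.5, 1), depth = 30L,
                   errorRate = 1e-3, genomeLength = 16569L,
                   depthModel = "fixed", germlineMode = "independent",
                   newick = NA_character_))

setValidity("SimConfig", function(object) {
    if (object@nCells < 1L) return("nCells must be >= 1")
    if (object@nClones < 2L) return("nClones must be >= 2")
    if (object@lambdaClone < 0 || object@germlineLambda < 0 ||
        object@cellPrivateLambda < 0)
        return("Poisson rates must be non-negative")
    if (object@germlineCarrierProb <= 0 || object@germlineCarrierProb > 1)
        return("germlineCarrierProb must lie in (0, 1]")
    if (length(object@hetBeta) != 2L || any(object@hetBeta <= 0))
        return("hetBeta must be two positive shape parameters")
    if (length(object@germlineVafRange) != 2L ||
        object@germlineVafRange[1L] >= object@germlineVafRange[2L])
        return("germlineVafRange must be an increasing pair")
    if (object@depth < 1L) return("depth must be >= 1")
    if (object@errorRate <= 0 || object@errorRate >= 1)
        return("errorRate must lie in (0, 1)")
    if (!object@depthModel %in% c("fixed", "poisson"))
        return("depthModel must be 'fixed' or 'poisson'")
    if (!object@germlineMode %in% c("independent", "strict"))
        return("germlineMode must be 'independent' or 'strict'")
    TRUE
})

#' Clonal tree with per-edge mutation assignments
#'
#' A rooted tree (\code{ape} \code{phylo}) whose edges carry the
#' clone-specific mutations generated when each parent produced that
#' descendant, plus the germline mutations assigned at the root. Each
#' genomic site mutates at most once anywhere in the tree.
#'
#' @slot phylo an \code{ape::phylo} tree with labelled nodes.
#' @slot edgeMutations data.frame with columns \code{node} (the child node
#'   label of the edge), \code{mutation} (canonical id) and
#'   \code{heteroplasmy}.
#' @slot germline data.frame with columns \code{mutation} and \code{vaf}.
#' @export
setClass("CloneTree",
         representation(phylo = "ANY", edgeMutations = "data.frame",
                        germline = "data.frame"))

setValidity("CloneTree", function(object) {
    if (!inherits(object@phylo, "phylo")) return("phylo slot must be a phylo")
    em <- object@edgeMutations
    if (!all(c("node", "mutation", "heteroplasmy") %in% colnames(em)))
        return("edgeMutations needs node, mutation, heteroplasmy")
    if (!all(c("mutation", "vaf") %in% colnames(object@germline)))
        return("germline needs mutation, vaf")
    allmut <- c(em$mutation, object@germline$mutation)
    if (anyDuplicated(allmut)) return("a site may mutate only once")
    TRUE
})

#' Ground truth of a simulated dataset
#'
#' @slot cellClone named character, clone label per cell (top-level clone).
#' @slot cellNode named character, tree node each cell was assigned to.
#' @slot mutationClass named character, one of \code{"clone_specific"},
#'   \code{"germline"}, \code{"cell_private"}.
#' @slot trueVaf numeric matrix (mutations x cells) of underlying
#'   heteroplasmies (0 for non-carriers).
#' @slot tree the generating \linkS4class{CloneTree}.
#' @export
setClass("SimTruth",
         representation(cellClone = "character", cellNode = "character",
                        mutationClass = "character", trueVaf = "matrix",
                        tree = "ANY"))

setValidity("SimTruth", function(object) {
    if (!all(object@mutationClass %in%
             c("clone_specific", "germline", "cell_private")))
        return("unknown mutation class")
    if (nrow(object@trueVaf) != length(object@mutationClass))
        return("trueVaf rows must match mutationClass")
    if (ncol(object@trueVaf) != length(object@cellClone))
        return("trueVaf columns must match cellClone")
    TRUE
})

#' Hierarchical lineage clustering result
#'
#' @slot hclust the \code{stats::hclust} dendrogram.
#' @slot clusters named integer, flat cluster per cell when \code{k} was
#'   requested (otherwise empty).
#' @slot k integer(1), requested number of flat clusters (\code{NA} if none).
#' @slot linkage character(1), agglomeration method used.
#' @export
setClass("LineageResult",
         representation(hclust = "ANY", clusters = "integer", k = "integer",
                        linkage = "character"))
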