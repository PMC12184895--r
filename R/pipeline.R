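#' Run the full lineage-tracing pipeline
#'
#' Chains the analysis stages on a per-cell VAF dataset: sequencing-error
#' filtering, cell-frequency filtering, DP-mixture selection of
#' informative mutations, the mitochondrial distance and hierarchical
#' clustering. All intermediate artifacts are written under
#' \code{outDir}, together with a JSON manifest recording the
#' parameters, the seed and the mutation counts after each stage (these
#' counts are non-increasing by construction).
#'
#' @param x a \linkS4class{MitoVafExperiment}, or the path to a VAF
#'   matrix (then \code{depthPath} is required and the files are read
#'   with \code{\link{readVafDataset}}).
#' @param depthPath,altPath,annotationPath input files when \code{x} is a
#'   path.
#' @param errorModel an \linkS4class{ErrorModel}.
#' @param filter a \linkS4class{FrequencyFilter}.
#' @param dpgmm a \linkS4class{DpgmmConfig}.
#' @param metric \code{"mito"}, \code{"euclidean"} or
#'   \code{"correlation"}.
#' @param linkage agglomeration method for
#'   \code{\link{clusterLineage}}.
#' @param k optional number of flat clusters.
#' @param minAf allele-frequency floor of the mitochondrial distance.
#' @param seed integer seed governing every stochastic stage.
#' @param outDir output directory; \code{NULL} skips writing artifacts.
#' @return invisibly, a list with \code{dataset} (filtered),
#'   \code{selected}, \code{fits}, \code{distance}, \code{clustering}
#'   and \code{manifest}.
#' @export
runPipeline <- function(x, depthPath = NULL, altPath = NULL,
                        annotationPath = NULL,
                        errorModel = ErrorModel(),
                        filter = FrequencyFilter(),
                        dpgmm = DpgmmConfig(),
                        metric = c("mito", "euclidean", "correlation"),
                        linkage = "average", k = NULL, minAf = 0.01,
                        seed = 1L, outDir = NULL) {
    metric <- match.arg(metric)
    stage <- "input"
    tryCatch({
        if (is.character(x)) {
            if (is.null(depthPath))
                stop("a depth matrix file is required")
            x <- readVafDataset(x, depthPath, altPath, annotationPath)
        }
        stopifnot(is(x, "MitoVafExperiment"))
        nInput <- nrow(x)

        stage <- "qc"
        ef <- applyErrorFilter(x, errorModel)
        nAfterError <- nrow(ef)
        ff <- applyFrequencyFilter(ef, filter)
        nAfterFreq <- nrow(ff)

        stage <- "select"
        dpgmm@seed <- as.integer(seed)
        sel <- selectInformative(ff, dpgmm)
        nSelected <- length(sel$selected)

        stage <- "cluster"
        distance <- clustering <- NULL
        if (nSelected >= 1L) {
            sub <- ff[sel$selected, ]
            distance <- switch(metric,
                mito = mitoDistance(sub, minAf = minAf),
                altDistance(sub, metric = metric))
            clustering <- clusterLineage(distance, linkage = linkage,
                                         k = k)
        } else {
            warning("no informative mutation selected; ",
                    "skipping the clustering stage")
        }

        manifest <- list(
            package = as.character(utils::packageVersion("mitoLineage")),
            seed = seed,
            parameters = list(
                e = errorModel@e, fpr = errorModel@fpr,
                minCellFraction = filter@minCellFraction,
                maxCellFraction = filter@maxCellFraction,
                positiveVaf = filter@positiveVaf,
                alpha = dpgmm@alpha,
                informativeCutoff = dpgmm@informativeCutoff,
                metric = metric, linkage = linkage, minAf = minAf,
                k = if (is.null(k)) NA else k),
            counts = list(n_input = nInput,
                          n_after_error_filter = nAfterError,
                          n_after_freq_filter = nAfterFreq,
                          n_selected = nSelected))
        if (!is.null(outDir)) {
            dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
            writeVafDataset(ff, file.path(outDir, "filtered"))
            writeLines(sel$selected,
                       file.path(outDir, "selected_mutations.txt"))
            fitsDf <- as.data.frame(sel$fits[, c("mutation", "nComponents",
                                                 "top2MeanDiff",
                                                 "informative")])
            data.table::fwrite(fitsDf, file.path(outDir, "dpgmm_fits.csv"))
            if (!is.null(distance))
                data.table::fwrite(
                    data.frame(cell = labels(distance),
                               as.matrix(distance), check.names = FALSE),
                    file.path(outDir, "distance.csv"))
            if (!is.null(clustering))
                exportHeatmapData(ff[sel$selected, ], clustering,
                                  file.path(outDir, "lineage"))
            jsonlite::write_json(manifest,
                                 file.path(outDir, "manifest.json"),
                                 auto_unbox = TRUE, pretty = TRUE,
                                 digits = NA)
        }
        invisible(list(dataset = ff, selected = sel$selected,
                       fits = sel$fits, distance = distance,
                       clustering = clustering, manifest = manifest))
    }, error = function(e) {
        stop("pipeline failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE)
    })
}

#' Seeded simulation benchmark of mutation selection and clustering
#'
#' Repeats, for a number of seeded replicates: simulate a ground-truth
#' dataset, apply the sequencing-error and frequency filters, select
#' informative mutations with the DP mixture and with the VAF-cutoff
#' baseline, cluster cells with the mitochondrial distance cut at the
#' true clone number, and score each method's selection (count and
#' overlap with the true clone-specific mutations) and clustering
#' (Adjusted Rand Index against the true clone labels).
#'
#' @param nReplicates number of simulation replicates.
#' @param config a \linkS4class{SimConfig}.
#' @param errorModel an \linkS4class{ErrorModel}.
#' @param filter a \linkS4class{FrequencyFilter}.
#' @param dpgmm a \linkS4class{DpgmmConfig}.
#' @param baselineThreshold VAF threshold of the baseline (default 0.2).
#' @param seed integer seed for the whole benchmark.
#' @return a data.frame with one row per replicate: \code{nTrue},
#'   \code{dpSelected}, \code{dpOverlap}, \code{dpAri},
#'   \code{cutoffSelected}, \code{cutoffOverlap}, \code{cutoffAri}.
#' @export
runSimulationBenchmark <- function(nReplicates = 20L,
                                   config = SimConfig(),
                                   errorModel = ErrorModel(),
                                   filter = FrequencyFilter(),
                                   dpgmm = DpgmmConfig(),
                                   baselineThreshold = 0.2,
                                   seed = 1L) {
    set.seed(seed)
    seeds <- sample.int(.Machine$integer.max %/% 2L, nReplicates)
    rows <- lapply(seq_len(nReplicates), function(r) {
        sim <- simulateDataset(config, seed = seeds[r])
        truth <- sim$truth
        trueSet <- names(truth@mutationClass)[
            truth@mutationClass == "clone_specific"]
        k <- length(unique(truth@cellClone))

        ef <- applyErrorFilter(sim$dataset, errorModel)
        ff <- suppressWarnings(applyFrequencyFilter(ef, filter))
        dpgmm@seed <- seeds[r]
        sel <- suppressWarnings(selectInformative(ff, dpgmm))

        ariFor <- function(ds, muts) {
            if (length(muts) < 1L) return(NA_real_)
            dm <- suppressWarnings(mitoDistance(ds[muts, ]))
            cl <- clusterLineage(dm, k = k)
            adjustedRandIndex(cl@clusters[names(truth@cellClone)],
                              truth@cellClone)
        }
        base <- vafCutoffBaseline(ef, threshold = baselineThreshold)
        data.frame(
            replicate = r, seed = seeds[r], nTrue = length(trueSet),
            dpSelected = length(sel$selected),
            dpOverlap = length(intersect(sel$selected, trueSet)),
            dpAri = ariFor(ff, sel$selected),
            cutoffSelected = length(base),
            cutoffOverlap = length(intersect(base, trueSet)),
            cutoffAri = ariFor(ef, base))
    })
    do.call(rbind, rows)
}
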