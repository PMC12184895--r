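#' Read a per-cell mitochondrial VAF dataset from delimited text
#'
#' Reads aligned mutation x cell matrices of variant allele frequencies
#' and read depths (plus, optionally, alternate-read counts and a cell
#' annotation table) and assembles a validated
#' \linkS4class{MitoVafExperiment}. Each matrix file is delimited text
#' (comma or tab, auto-detected) with a header row of cell identifiers and
#' a first column of canonical mutation identifiers
#' (\code{"MT_<pos>_<ref>-<alt>"}). Rows and columns are matched across
#' files by identifier, not by order, so files whose rows are permuted
#' load to the same object. Uncovered entries (depth 0) are stored as
#' missing VAF.
#'
#' A sparse alternative is supported for large droplet-derived data: when
#' \code{vafPath} ends in \code{.mtx}, the VAF/depth/alt files are read as
#' Matrix Market triplets and \code{rowNamesPath}/\code{colNamesPath} must
#' supply the mutation and cell identifiers (one per line).
#'
#' @param vafPath path to the VAF matrix (fractions in \code{[0, 1]}).
#' @param depthPath path to the read-depth matrix.
#' @param altPath optional path to the alternate-read-count matrix; when
#'   absent, alt counts are reconstructed as \code{round(vaf * depth)}.
#' @param annotationPath optional two-column delimited file
#'   (cell, label).
#' @param rowNamesPath,colNamesPath identifier files, required for
#'   \code{.mtx} input only.
#' @return a \linkS4class{MitoVafExperiment}.
#' @seealso \code{\link{writeVafDataset}}
#' @export
readVafDataset <- function(vafPath, depthPath, altPath = NULL,
                           annotationPath = NULL, rowNamesPath = NULL,
                           colNamesPath = NULL) {
    for (p in c(vafPath, depthPath, altPath, annotationPath))
        if (!file.exists(p)) stop("file not found: ", p)
    sparse <- grepl("\\.mtx$", vafPath)
    readOne <- function(path, what) {
        if (sparse) {
            m <- as.matrix(Matrix::readMM(path))
            rn <- readLines(rowNamesPath)
            cn <- readLines(colNamesPath)
            if (nrow(m) != length(rn) || ncol(m) != length(cn))
                stop("dimension mismatch between ", path,
                     " and the row/column name files")
            dimnames(m) <- list(rn, cn)
            return(m)
        }
        dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
        if (ncol(dt) < 1L) stop("no columns in ", path)
        rn <- as.character(dt[[1L]])
        m <- as.matrix(dt[, -1L, drop = FALSE])
        rownames(m) <- rn
        if (anyDuplicated(rn))
            stop("duplicate mutation identifiers in ", path)
        m
    }
    v <- readOne(vafPath, "vaf")
    d <- readOne(depthPath, "depth")
    a <- if (!is.null(altPath)) readOne(altPath, "alt") else NULL
    parseMutationId(rownames(v) %||% character(0))  # names the bad row
    ann <- NULL
    if (!is.null(annotationPath)) {
        at <- data.table::fread(annotationPath, header = TRUE,
                                data.table = FALSE)
        if (ncol(at) < 2L) stop("annotation file needs >= 2 columns")
        ann <- data.frame(at[, -1L, drop = FALSE], row.names = at[[1L]])
    }
    MitoVafExperiment(v, d, alt = a, cellAnnotations = ann)
}

#' Write a MitoVafExperiment to delimited text
#'
#' Writes comma-separated \code{vaf.csv}, \code{depth.csv} and
#' \code{alt.csv} matrices (first column \code{mutation}, one column per
#' cell), plus \code{annotations.csv} when cell annotations are present.
#' Reading the files back with \code{\link{readVafDataset}} reproduces the
#' object exactly on the integer matrices and to near machine precision on
#' VAFs; missing entries (depth 0) survive the round trip.
#'
#' @param x a \linkS4class{MitoVafExperiment}.
#' @param outDir output directory, created if needed.
#' @return invisibly, the named vector of file paths written.
#' @export
writeVafDataset <- function(x, outDir) {
    stopifnot(is(x, "MitoVafExperiment"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(outDir)) stop("cannot create directory ", outDir)
    writeOne <- function(m, name) {
        path <- file.path(outDir, paste0(name, ".csv"))
        df <- data.frame(mutation = rownames(m) %||% character(0), m,
                         check.names = FALSE)
        data.table::fwrite(df, path, na = "NA")
        path
    }
    paths <- c(vaf = writeOne(vaf(x), "vaf"),
               depth = writeOne(readDepth(x), "depth"),
               alt = writeOne(altCounts(x), "alt"))
    cd <- colData(x)
    if (ncol(cd)) {
        path <- file.path(outDir, "annotations.csv")
        data.table::fwrite(data.frame(cell = rownames(cd),
                                      as.data.frame(cd),
                                      check.names = FALSE), path)
        paths <- c(paths, annotations = path)
    }
    invisible(paths)
}
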