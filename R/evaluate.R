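#' VAF-cutoff baseline mutation selection
#'
#' The simple heteroplasmy-threshold baseline: a mutation is selected
#' when its VAF reaches \code{threshold} (default 0.2, the GTEx
#' heteroplasmy threshold) in at least one cell, unless it is positive
#' in every covered cell (a universal variant cannot separate lineages).
#'
#' @param x a \linkS4class{MitoVafExperiment}.
#' @param threshold minimum VAF to call a mutation present in a cell.
#' @param positiveVaf VAF above which a cell counts as positive for the
#'   universality exclusion (default 0.01).
#' @return character vector of selected mutation identifiers.
#' @export
vafCutoffBaseline <- function(x, threshold = 0.2, positiveVaf = 0.01) {
    stopifnot(is(x, "MitoVafExperiment"))
    v <- vaf(x)
    if (!nrow(v)) return(character(0))
    hit <- apply(v, 1L, function(r) any(r >= threshold, na.rm = TRUE))
    covered <- rowSums(!is.na(v))
    pos <- rowSums(v > positiveVaf, na.rm = TRUE)
    universal <- covered > 0 & pos == covered
    rownames(v)[hit & !universal]
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie) between two
#' clusterings of the same items: 1 for identical partitions (up to label
#' permutation), with expectation about 0 for independent ones.
#'
#' @param a,b partition label vectors of equal length (any atomic type).
#' @return the ARI, a number \code{<= 1}.
#' @examples
#' adjustedRandIndex(c(1, 1, 2, 2), c("x", "x", "y", "y"))  # 1
#' @export
adjustedRandIndex <- function(a, b) {
    if (length(a) != length(b))
        stop("partitions must have equal length")
    if (length(a) < 2L) stop("need at least 2 items")
    tab <- table(a, b)
    n <- length(a)
    sumIJ <- sum(choose(tab, 2))
    sumI <- sum(choose(rowSums(tab), 2))
    sumJ <- sum(choose(colSums(tab), 2))
    expected <- sumI * sumJ / choose(n, 2)
    maxIdx <- (sumI + sumJ) / 2
    if (maxIdx == expected)  # both partitions trivial
        return(1)
    (sumIJ - expected) / (maxIdx - expected)
}

#' Enumerate sample triplets containing one true sibling pair
#'
#' Sibling clones share the same parental clone (their most recent common
#' ancestor, MRCA). Given each sample's clone and each clone's parent,
#' this enumerates every set of three samples in which exactly one pair
#' is a sibling pair (two samples from distinct clones with the same
#' parent). When the third sample is derived from the pair's MRCA --
#' its clone is the MRCA itself or descends from it -- the triplet is
#' the harder \code{"within_clone"} scenario (the outsider is
#' genetically close to the pair); otherwise it is
#' \code{"between_clones"}. Sets of three mutual siblings contain three
#' sibling pairs and are excluded.
#'
#' @param sampleClone named character, clone per sample.
#' @param cloneParent named character, parent clone per clone (roots may
#'   be \code{NA}).
#' @return a data.frame with columns \code{sib1}, \code{sib2} (the true
#'   sibling pair), \code{other} and \code{scenario}.
#' @export
enumerateTriplets <- function(sampleClone, cloneParent) {
    samples <- names(sampleClone)
    if (is.null(samples)) stop("sampleClone must be named by sample")
    if (any(!unique(sampleClone) %in% names(cloneParent)))
        stop("parentage missing for some clone(s)")
    isSib <- function(s1, s2) {
        c1 <- sampleClone[[s1]]; c2 <- sampleClone[[s2]]
        p1 <- cloneParent[[c1]]; p2 <- cloneParent[[c2]]
        c1 != c2 && !is.na(p1) && !is.na(p2) && p1 == p2
    }
    n <- length(samples)
    out <- list()
    if (n >= 3L) {
        combs <- utils::combn(n, 3L)
        for (t in seq_len(ncol(combs))) {
            trio <- samples[combs[, t]]
            sib <- c(isSib(trio[1L], trio[2L]), isSib(trio[1L], trio[3L]),
                     isSib(trio[2L], trio[3L]))
            if (sum(sib) != 1L) next
            pairIdx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[which(sib)]]
            pair <- trio[pairIdx]
            other <- trio[-pairIdx]
            mrca <- cloneParent[[sampleClone[[pair[1L]]]]]
            oc <- sampleClone[[other]]
            scenario <- if (.inClade(oc, mrca, cloneParent)) "within_clone"
                        else "between_clones"
            out[[length(out) + 1L]] <-
                data.frame(sib1 = pair[1L], sib2 = pair[2L], other = other,
                           scenario = scenario, stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(sib1 = character(0), sib2 = character(0),
                          other = character(0), scenario = character(0)))
    do.call(rbind, out)
}

## is clone `x` equal to `clade` or one of its descendants?
.inClade <- function(x, clade, cloneParent) {
    seen <- character(0)
    while (!is.na(x)) {
        if (x == clade) return(TRUE)
        if (x %in% seen) stop("cycle in clone parentage")
        seen <- c(seen, x)
        x <- if (x %in% names(cloneParent)) cloneParent[[x]] else NA
    }
    FALSE
}

## AUROC with ties handled by midranks (Mann-Whitney convention)
.aucRoc <- function(score, label) {
    r <- rank(score)
    n1 <- sum(label == 1L)
    n0 <- sum(label == 0L)
    (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## ROC points (FPR, TPR) sweeping thresholds from high to low score,
## grouping tied scores
.rocPoints <- function(score, label) {
    o <- order(score, decreasing = TRUE)
    s <- score[o]; l <- label[o]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(l == 1L); fp <- cumsum(l == 0L)
    last <- which(!duplicated(grp, fromLast = TRUE))
    cbind(fpr = c(0, fp[last] / max(1L, sum(label == 0L))),
          tpr = c(0, tp[last] / max(1L, sum(label == 1L))))
}

## precision-recall points and step-interpolated area
.prCurve <- function(score, label) {
    o <- order(score, decreasing = TRUE)
    s <- score[o]; l <- label[o]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(l == 1L)
    k <- seq_along(l)
    last <- which(!duplicated(grp, fromLast = TRUE))
    rec <- tp[last] / max(1L, sum(label == 1L))
    prec <- tp[last] / k[last]
    auc <- sum(diff(c(0, rec)) * prec)
    list(points = cbind(recall = rec, precision = prec), auc = auc)
}

#' Sibling-triplet ROC and precision-recall evaluation
#'
#' Scores every sample pair of every triplet by its (negated) lineage
#' distance, labels the true sibling pair 1 and the other two pairs 0,
#' pools the pairs within each scenario, and sweeps all thresholds to
#' obtain ROC and precision-recall curves. As siblings share their MRCA,
#' their distance is expected to be the smallest of the three. The AUROC
#' equals the Mann-Whitney U normalization of the scores (ties get
#' midranks). A per-triplet top-1 accuracy (fraction of triplets whose
#' smallest distance is the sibling pair, ties splitting credit) is also
#' reported.
#'
#' @param triplets data.frame from \code{\link{enumerateTriplets}}.
#' @param d a \code{stats::dist} (or symmetric matrix) over the samples.
#' @return a named list per scenario present, each with \code{rocPoints},
#'   \code{prPoints}, \code{aucRoc}, \code{aucPr}, \code{top1} and
#'   \code{nTriplets}.
#' @export
tripletAuc <- function(triplets, d) {
    dm <- as.matrix(d)
    need <- unique(unlist(triplets[, c("sib1", "sib2", "other")]))
    if (!all(need %in% rownames(dm)))
        stop("distance matrix is missing some triplet samples")
    out <- list()
    for (sc in c("within_clone", "between_clones")) {
        tt <- triplets[triplets$scenario == sc, , drop = FALSE]
        if (!nrow(tt)) {
            warning("no triplets in scenario ", sc)
            next
        }
        dist3 <- t(apply(tt, 1L, function(r)
            c(dm[r[["sib1"]], r[["sib2"]]],
              dm[r[["sib1"]], r[["other"]]],
              dm[r[["sib2"]], r[["other"]]])))
        label <- rep(c(1L, 0L, 0L), each = nrow(tt))
        score <- -as.vector(dist3)
        top1 <- mean(apply(dist3, 1L, function(x)
            (min(x) == x[1L]) / sum(x == min(x))))
        pr <- .prCurve(score, label)
        out[[sc]] <- list(rocPoints = .rocPoints(score, label),
                          prPoints = pr$points,
                          aucRoc = .aucRoc(score, label),
                          aucPr = pr$auc,
                          top1 = top1,
                          nTriplets = nrow(tt))
    }
    out
}
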