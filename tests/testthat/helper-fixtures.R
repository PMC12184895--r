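# small in-code fixtures shared across test files

# a MitoVafExperiment built from explicit alt/depth matrices
toyExperiment <- function(alt, depth, mutations = NULL, cells = NULL,
                          annotations = NULL) {
    alt <- as.matrix(alt)
    depth <- as.matrix(depth)
    if (is.null(mutations))
        mutations <- makeMutationId(seq_len(nrow(alt)) * 100, "A", "G")
    if (is.null(cells))
        cells <- sprintf("cell%02d", seq_len(ncol(alt)))
    dimnames(alt) <- dimnames(depth) <- list(mutations, cells)
    vafm <- ifelse(depth > 0, alt / depth, NA_real_)
    MitoVafExperiment(vafm, depth, alt = alt,
                      cellAnnotations = annotations)
}

# a clearly separated two-clone VAF experiment: mutation 1 marks clone A,
# mutation 2 marks clone B, at the given heteroplasmies and depth
twoCloneExperiment <- function(nPerClone = 10, het = 0.4, depth = 1000) {
    nA <- nPerClone; nB <- nPerClone
    altA <- c(rep(round(het * depth), nA), rep(0, nB))
    altB <- c(rep(0, nA), rep(round(het * depth), nB))
    alt <- rbind(altA, altB)
    toyExperiment(alt, matrix(depth, 2, nA + nB),
                  annotations = setNames(rep(c("A", "B"), c(nA, nB)),
                                         sprintf("cell%02d",
                                                 seq_len(nA + nB))))
}

# brute-force evaluation of the indicator-gated mean |dAF| distance,
# independent of the package implementation
bruteMitoDistance <- function(v, minAf = 0.01) {
    n <- ncol(v)
    d <- matrix(0, n, n, dimnames = list(colnames(v), colnames(v)))
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        num <- 0; den <- 0
        for (x in seq_len(nrow(v))) {
            ai <- v[x, i]; aj <- v[x, j]
            if (is.na(ai) && is.na(aj)) next
            if (is.na(ai)) ai <- 0
            if (is.na(aj)) aj <- 0
            if (ai > minAf || aj > minAf) {
                num <- num + abs(ai - aj)
                den <- den + 1
            }
        }
        d[i, j] <- if (den == 0) 1 else num / den
    }
    d
}

# pair-counting Adjusted Rand Index, enumerated over all item pairs
bruteAri <- function(a, b) {
    n <- length(a)
    ss <- sd <- ds <- dd <- 0
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
        sameA <- a[i] == a[j]
        sameB <- b[i] == b[j]
        if (sameA && sameB) ss <- ss + 1
        else if (sameA && !sameB) sd <- sd + 1
        else if (!sameA && sameB) ds <- ds + 1
        else dd <- dd + 1
    }
    tot <- ss + sd + ds + dd
    expected <- (ss + sd) * (ss + ds) / tot
    maxIdx <- ((ss + sd) + (ss + ds)) / 2
    if (maxIdx == expected) return(1)
    (ss - expected) / (maxIdx - expected)
}
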