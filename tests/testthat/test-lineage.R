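test_that("mito distance matches hand evaluation of the gated mean |dAF|", {
    v <- cbind(c(0.5, 0.005), c(0.1, 0.5))
    dimnames(v) <- list(makeMutationId(c(100, 200), "A", "G"), c("i", "j"))
    d <- mitoDistance(v)
    # site 1 contributes |0.5 - 0.1|, site 2 |0.005 - 0.5| (one member
    # above the floor suffices); mean over 2 contributing sites
    expect_equal(as.matrix(d)["i", "j"], (0.4 + 0.495) / 2)
})

test_that("mito distance handles identical, empty-evidence and missing", {
    v <- cbind(a = c(0.3, 0.002), b = c(0.3, 0.002), c = c(0.004, 0.001))
    rownames(v) <- makeMutationId(c(1, 2), "A", "G")
    dm <- as.matrix(mitoDistance(v))
    expect_equal(dm["a", "b"], 0)       # identical with evidence
    expect_equal(dm["a", "c"], (0.296 + 0) / 1)  # only site 1 gated in
    # pair with no site above the floor anywhere -> distance 1
    v2 <- cbind(a = c(0.004, 0.002), b = c(0.001, 0.003))
    rownames(v2) <- rownames(v)
    expect_warning(d2 <- mitoDistance(v2), "floor")
    expect_equal(as.matrix(d2)["a", "b"], 1)
    # a site missing in both members is excluded entirely
    v3 <- cbind(a = c(0.3, NA), b = c(0.5, NA))
    rownames(v3) <- rownames(v)
    expect_equal(as.matrix(mitoDistance(v3))["a", "b"], 0.2)
})

test_that("mito distance equals brute-force on random matrices", {
    set.seed(10)
    for (r in 1:20) {
        nm <- sample(2:6, 1)
        nc <- sample(2:6, 1)
        v <- matrix(runif(nm * nc) * sample(c(1, 0.02), 1), nm, nc)
        if (r %% 3 == 0) v[sample(length(v), 2)] <- NA
        dimnames(v) <- list(makeMutationId(seq_len(nm) * 7, "G", "C"),
                            paste0("c", seq_len(nc)))
        got <- suppressWarnings(as.matrix(mitoDistance(v)))
        want <- bruteMitoDistance(v)
        expect_equal(got, want, tolerance = 1e-12)
        expect_true(all(got >= 0 & got <= 1))
        expect_equal(got, t(got))
        expect_true(all(diag(got) == 0))
    }
})

test_that("with every AF above the floor the distance is Manhattan/n", {
    set.seed(3)
    v <- matrix(runif(5 * 4, min = 0.02, max = 1), 5, 4)
    dimnames(v) <- list(makeMutationId(1:5 * 11, "T", "C"),
                        paste0("c", 1:4))
    got <- as.matrix(mitoDistance(v))
    want <- as.matrix(stats::dist(t(v), method = "manhattan")) / nrow(v)
    expect_equal(got, want, tolerance = 1e-12)
})

test_that("permuting cells permutes the distance matrix consistently", {
    set.seed(4)
    v <- matrix(runif(12), 3, 4,
                dimnames = list(makeMutationId(1:3 * 9, "A", "T"),
                                paste0("c", 1:4)))
    d1 <- as.matrix(mitoDistance(v))
    perm <- c(3, 1, 4, 2)
    d2 <- as.matrix(mitoDistance(v[, perm]))
    expect_equal(d2, d1[perm, perm])
})

test_that("euclidean and correlation distances match direct computation", {
    set.seed(5)
    v <- matrix(runif(20), 5, 4,
                dimnames = list(makeMutationId(1:5 * 3, "C", "A"),
                                paste0("c", 1:4)))
    expect_equal(as.matrix(altDistance(v, "euclidean")),
                 as.matrix(stats::dist(t(v))), tolerance = 1e-12)
    got <- as.matrix(altDistance(v, "correlation"))
    want <- 1 - cor(v)
    diag(want) <- 0
    expect_equal(got, want, tolerance = 1e-12)

    # identical columns
    v2 <- v; v2[, 2] <- v2[, 1]
    expect_equal(as.matrix(altDistance(v2, "euclidean"))[1, 2], 0)
    # perfectly correlated (affine) columns
    v3 <- v; v3[, 2] <- 0.5 * v3[, 1] + 0.1
    expect_equal(as.matrix(altDistance(v3, "correlation"))[1, 2], 0,
                 tolerance = 1e-12)
    # zero-variance column
    v4 <- v; v4[, 3] <- 0.2
    expect_warning(d4 <- altDistance(v4, "correlation"), "zero-variance")
    expect_equal(as.matrix(d4)[3, 1], 1)
})

test_that("clustering recovers well-separated clones and honours k", {
    mve <- twoCloneExperiment(nPerClone = 8)
    d <- mitoDistance(mve)
    res <- clusterLineage(d, k = 2)
    truth <- colData(mve)$clone
    expect_equal(adjustedRandIndex(res@clusters, truth), 1)

    # k = n: every cell its own cluster
    resN <- clusterLineage(d, k = 16)
    expect_equal(length(unique(resN@clusters)), 16L)
    # cutting at every k yields exactly k clusters
    for (k in c(1, 3, 7))
        expect_equal(length(unique(clusterLineage(d, k = k)@clusters)), k)

    # two cells: single merger at their distance
    v <- cbind(a = c(0.1, 0.9), b = c(0.8, 0.2))
    rownames(v) <- makeMutationId(1:2, "A", "G")
    d2 <- mitoDistance(v)
    hc <- clusterLineage(d2)@hclust
    expect_equal(hc$height, as.numeric(d2))

    expect_error(clusterLineage(d, linkage = "ward.D2"), "ward")
    expect_error(clusterLineage(d, k = 99), "k must lie")
})

test_that("heatmap export writes leaf-ordered matrix and valid Newick", {
    mve <- twoCloneExperiment(nPerClone = 4)
    res <- clusterLineage(mitoDistance(mve), k = 2)
    pref <- file.path(withr::local_tempdir(), "lin")
    paths <- exportHeatmapData(mve, res, pref)
    expect_true(all(file.exists(paths)))

    ord <- data.table::fread(paths[["vaf"]], data.table = FALSE)
    leaves <- res@hclust$labels[res@hclust$order]
    expect_equal(colnames(ord)[-1], leaves)

    cl <- data.table::fread(paths[["clusters"]], data.table = FALSE)
    expect_equal(nrow(cl), ncol(mve))   # one line per cell

    tr <- ape::read.tree(paths[["newick"]])
    expect_equal(sort(tr$tip.label), sort(cellIds(mve)))
    # re-imported tree reproduces the merge topology
    expect_equal(suppressWarnings(
        ape::dist.topo(tr, ape::as.phylo(res@hclust))), 0,
        ignore_attr = TRUE)
})
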