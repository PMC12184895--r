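test_that("the VAF-cutoff baseline applies the 0.2 rule with exclusions", {
    # row 1: max VAF 0.19 -> excluded; row 2: 0.5 in one cell -> kept;
    # row 3: positive everywhere (universal) -> excluded
    alt <- rbind(c(19L, 0L, 0L), c(50L, 0L, 0L), c(100L, 100L, 100L))
    mve <- toyExperiment(alt, matrix(100L, 3, 3))
    sel <- vafCutoffBaseline(mve, threshold = 0.2)
    expect_identical(sel, "MT_200_A-G")
})

test_that("adjusted Rand index matches exhaustive pair counting", {
    expect_equal(adjustedRandIndex(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
    # invariance to label permutation and to argument order
    a <- c(1, 1, 2, 2, 3, 3)
    b <- c("x", "x", "x", "y", "y", "y")
    expect_equal(adjustedRandIndex(a, ifelse(a == 1, 9, ifelse(a == 2, 7, 5))), 1)
    expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
    # fixed 6-element example against the brute-force oracle
    expect_equal(adjustedRandIndex(a, b), bruteAri(a, b))
    # random partitions of up to 8 elements
    set.seed(14)
    for (r in 1:100) {
        n <- sample(2:8, 1)
        x <- sample(1:3, n, replace = TRUE)
        y <- sample(1:3, n, replace = TRUE)
        expect_equal(adjustedRandIndex(x, y), bruteAri(x, y),
                     tolerance = 1e-12)
    }
    expect_error(adjustedRandIndex(1:3, 1:4), "equal length")
})

test_that("triplet enumeration finds unique sibling pairs and scenarios", {
    # pedigree: P1 -> {A, B}, P2 -> {C}, A -> {A1}; samples one per clone
    parents <- c(A = "P1", B = "P1", C = "P2", A1 = "A",
                 P1 = NA, P2 = NA)
    samples <- c(sa = "A", sb = "B", sc = "C", sa1 = "A1")
    tri <- enumerateTriplets(samples, parents)
    # sibling pair is always (sa, sb); outsiders: sc (between),
    # sa1 (descends from P1 -> within)
    expect_equal(nrow(tri), 2L)
    expect_setequal(tri$other, c("sc", "sa1"))
    expect_equal(tri$scenario[tri$other == "sc"], "between_clones")
    expect_equal(tri$scenario[tri$other == "sa1"], "within_clone")
    expect_true(all(tri$sib1 == "sa" & tri$sib2 == "sb"))

    # a sample inside the parent clone itself also counts as within
    samples2 <- c(sa = "A", sb = "B", sp = "P1")
    tri2 <- enumerateTriplets(samples2, parents)
    expect_equal(tri2$scenario, "within_clone")

    # three mutual siblings: no unique pair, excluded
    parents3 <- c(A = "P", B = "P", C = "P", P = NA)
    tri3 <- enumerateTriplets(c(s1 = "A", s2 = "B", s3 = "C"), parents3)
    expect_equal(nrow(tri3), 0L)
})

test_that("triplet counts equal exhaustive enumeration on a toy pedigree", {
    # 3 parental clones, 6 leaf clones, one sample each
    parents <- c(A = "P1", B = "P1", C = "P2", D = "P2", E = "P3",
                 F = "P3", P1 = NA, P2 = NA, P3 = NA)
    samples <- setNames(names(parents)[1:6], paste0("s", 1:6))
    tri <- enumerateTriplets(samples, parents)
    # each of 3 sibling pairs with each of 4 outside samples
    expect_equal(nrow(tri), 12L)
    expect_true(all(tri$scenario == "between_clones"))
})

test_that("perfectly separated siblings give AUROC and AUPR of 1", {
    parents <- c(A = "P1", B = "P1", C = "P2", D = "P2",
                 P1 = NA, P2 = NA)
    samples <- setNames(c("A", "B", "C", "D"), c("a", "b", "c", "d"))
    tri <- enumerateTriplets(samples, parents)
    d <- matrix(1, 4, 4, dimnames = list(names(samples), names(samples)))
    diag(d) <- 0
    d["a", "b"] <- d["b", "a"] <- 0.1   # siblings closest
    d["c", "d"] <- d["d", "c"] <- 0.1
    expect_warning(res <- tripletAuc(tri, d), "within_clone")
    expect_equal(res$between_clones$aucRoc, 1)
    expect_equal(res$between_clones$aucPr, 1)
    expect_equal(res$between_clones$top1, 1)
    roc <- res$between_clones$rocPoints
    expect_equal(unname(roc[1, ]), c(0, 0))
    expect_equal(unname(roc[nrow(roc), ]), c(1, 1))
})

test_that("random distances give chance-level AUROC", {
    set.seed(20)
    # ~3334 triplets -> 10,000 pooled pairs
    nTri <- 3334
    d3 <- matrix(runif(3 * nTri), nTri, 3)
    label <- rep(c(1L, 0L, 0L), each = nTri)
    score <- -as.vector(d3)
    auc <- mitoLineage:::.aucRoc(score, label)
    expect_lt(abs(auc - 0.5), 0.02)
})

test_that("AUROC equals the Mann-Whitney normalization", {
    set.seed(26)
    for (r in 1:10) {
        n1 <- sample(5:30, 1); n0 <- sample(5:30, 1)
        score <- c(round(rnorm(n1, 1), 1), round(rnorm(n0), 1))  # ties
        label <- rep(c(1L, 0L), c(n1, n0))
        w <- suppressWarnings(
            wilcox.test(score[label == 1], score[label == 0]))
        expect_equal(mitoLineage:::.aucRoc(score, label),
                     unname(w$statistic) / (n1 * n0), tolerance = 1e-12)
    }
})

test_that("a small tied example matches hand-computed curves", {
    # scores (desc): 0.9(+), 0.7(-), 0.5(+ and -, tied), 0.3(-)
    score <- c(0.9, 0.7, 0.5, 0.5, 0.3)
    label <- c(1L, 0L, 1L, 0L, 0L)
    # ranks: 0.3->1, 0.5->2.5, 2.5, 0.7->4, 0.9->5; U = (5+2.5) - 3 = 4.5
    expect_equal(mitoLineage:::.aucRoc(score, label), 4.5 / 6)
    pr <- mitoLineage:::.prCurve(score, label)
    # thresholds: {0.9}: R=.5 P=1; {>=0.7}: R=.5 P=.5;
    # {>=0.5}: R=1 P=.5; {>=0.3}: R=1 P=.4
    expect_equal(unname(pr$points[, "recall"]), c(0.5, 0.5, 1, 1))
    expect_equal(unname(pr$points[, "precision"]), c(1, 0.5, 0.5, 0.4))
    expect_equal(pr$auc, 0.5 * 1 + 0.5 * 0.5)
})
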