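test_that("the default clonal tree places >= 1 mutation on each edge", {
    set.seed(21)
    tree <- buildCloneTree(SimConfig())
    # two-level default: 6 clones, each split into two subclones
    expect_equal(ape::Ntip(tree@phylo), 12L)
    expect_equal(nrow(tree@phylo$edge), 18L)
    perEdge <- table(tree@edgeMutations$node)
    expect_equal(length(perEdge), 18L)
    expect_true(all(perEdge >= 1L))
    # every child of the root carries at least one clone-specific mutation
    clones <- tree@phylo$node.label[-1]
    expect_true(all(clones %in% tree@edgeMutations$node))
    # no position is used twice anywhere in the tree
    pos <- parseMutationId(c(tree@edgeMutations$mutation,
                             tree@germline$mutation))$position
    expect_false(anyDuplicated(pos) > 0)
})

test_that("a star tree yields the analytic clone-specific expectation", {
    star <- "(C1,C2,C3,C4,C5,C6)root;"
    set.seed(99)
    counts <- vapply(1:200, function(i) {
        nrow(buildCloneTree(SimConfig(newick = star))@edgeMutations)
    }, 1L)
    # per edge 1 + Poisson(1): mean 2, var 1 -> total mean 12, var 6
    se <- sqrt(6 / 200)
    expect_lt(abs(mean(counts) - 12), 3 * se + 1e-9)
    set.seed(1)
    tr <- buildCloneTree(SimConfig(newick = star))
    expect_equal(nrow(tr@phylo$edge), 6L)
})

test_that("cells inherit their full root-to-node mutation path", {
    set.seed(33)
    cfg <- SimConfig(nCells = 60)
    tree <- buildCloneTree(cfg)
    truth <- assignCells(tree, cfg)
    tv <- truth@trueVaf
    em <- tree@edgeMutations
    # cells assigned to the same node share identical clone-specific rows
    csRows <- which(truth@mutationClass == "clone_specific")
    for (nd in unique(truth@cellNode)) {
        cells <- names(truth@cellNode)[truth@cellNode == nd]
        if (length(cells) < 2) next
        expect_true(all(tv[csRows, cells] == tv[csRows, cells[1]]))
    }
    # a subclone cell carries its parent clone's edge mutations too
    sub <- names(truth@cellNode)[grepl("a$|b$", truth@cellNode)][1]
    clone <- truth@cellClone[[sub]]
    cloneMuts <- em$mutation[em$node == clone]
    expect_true(all(tv[cloneMuts, sub] > 0))
})

test_that("germline carriage matches the configured probability", {
    set.seed(55)
    cfg <- SimConfig(nCells = 400, germlineLambda = 12)
    tree <- buildCloneTree(cfg)
    truth <- assignCells(tree, cfg)
    g <- names(truth@mutationClass)[truth@mutationClass == "germline"]
    carried <- rowMeans(truth@trueVaf[g, , drop = FALSE] > 0)
    # each is Binomial(400, 0.8)/400; check within 4 sd
    expect_true(all(abs(carried - 0.8) < 4 * sqrt(0.8 * 0.2 / 400)))
    # germline VAF is one population value per mutation, in [0.5, 1]
    for (m in g) {
        v <- truth@trueVaf[m, truth@trueVaf[m, ] > 0]
        expect_equal(length(unique(v)), 1L)
        expect_true(v[1] >= 0.5 && v[1] <= 1)
    }
    # strict mode: exactly ceiling(0.8 n) carriers
    cfg2 <- SimConfig(nCells = 50, germlineMode = "strict")
    truth2 <- assignCells(buildCloneTree(cfg2), cfg2)
    g2 <- names(truth2@mutationClass)[truth2@mutationClass == "germline"]
    if (length(g2))
        expect_true(all(rowSums(truth2@trueVaf[g2, , drop = FALSE] > 0)
                        == 40L))
})

test_that("read counts follow the binomial error model", {
    # non-carrier: E[alt] = depth * e/3
    tree <- new("CloneTree",
                phylo = ape::read.tree(text = "(A,B)root;"),
                edgeMutations = data.frame(node = "A",
                                           mutation = "MT_100_A-G",
                                           heteroplasmy = 0),
                germline = data.frame(mutation = character(0),
                                      vaf = numeric(0)))
    nCells <- 10000
    tv <- matrix(0, 1, nCells,
                 dimnames = list("MT_100_A-G",
                                 sprintf("cell%05d", 1:nCells)))
    truth <- new("SimTruth",
                 cellClone = setNames(rep("A", nCells), colnames(tv)),
                 cellNode = setNames(rep("A", nCells), colnames(tv)),
                 mutationClass = c(MT_100_A.G = "clone_specific"),
                 trueVaf = tv, tree = tree)
    names(truth@mutationClass) <- "MT_100_A-G"
    set.seed(61)
    ds <- simulateReads(truth, SimConfig(nCells = nCells))
    m <- mean(altCounts(ds))
    ev <- 30 * 1e-3 / 3
    se <- sqrt(30 * (1e-3 / 3) * (1 - 1e-3 / 3) / nCells)
    expect_lt(abs(m - ev), 3 * se)

    # carrier at v = 0.2: mean VAF ~ 0.2(1-e) + 0.8 e/3
    truth@trueVaf[1, ] <- 0.2
    set.seed(62)
    ds2 <- simulateReads(truth, SimConfig(nCells = nCells))
    q <- 0.2 * (1 - 1e-3) + 0.8 * 1e-3 / 3
    se2 <- sqrt(q * (1 - q) / (30 * nCells))
    expect_lt(abs(mean(vaf(ds2)) - q), 3 * se2)

    # chi-square goodness of fit of alt counts vs Binomial(30, q)
    obs <- table(factor(altCounts(ds2), levels = 0:30))
    expected <- dbinom(0:30, 30, q) * nCells
    keep <- expected > 5
    chi <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
        (sum(obs[!keep]) - sum(expected[!keep]))^2 /
        max(sum(expected[!keep]), 1e-9)
    pval <- pchisq(chi, df = sum(keep), lower.tail = FALSE)
    expect_gt(pval, 0.01)

    # (near-)noiseless homoplasmic carrier: always depth reads
    truth@trueVaf[1, ] <- 1
    cfgTiny <- SimConfig(nCells = nCells, errorRate = 1e-12)
    set.seed(63)
    ds3 <- simulateReads(truth, cfgTiny)
    expect_true(all(altCounts(ds3) == 30L))
})

test_that("simulated datasets are valid and reproducible under a seed", {
    sim1 <- simulateDataset(SimConfig(nCells = 40), seed = 17)
    sim2 <- simulateDataset(SimConfig(nCells = 40), seed = 17)
    expect_identical(vaf(sim1$dataset), vaf(sim2$dataset))
    expect_identical(sim1$truth@cellClone, sim2$truth@cellClone)
    expect_true(validObject(sim1$dataset))
    # classes restricted to the three-value vocabulary
    expect_true(all(sim1$truth@mutationClass %in%
                    c("clone_specific", "germline", "cell_private")))
    # no position reused across classes
    pos <- parseMutationId(rownames(sim1$dataset))$position
    expect_false(anyDuplicated(pos) > 0)
})

test_that("ground truth round-trips through the text files", {
    sim <- simulateDataset(SimConfig(nCells = 25), seed = 5)
    pref <- file.path(withr::local_tempdir(), "truth")
    paths <- writeTruth(sim$truth, pref)
    expect_true(all(file.exists(paths)))
    cells <- data.table::fread(paths[["cells"]], data.table = FALSE)
    expect_equal(nrow(cells), 25L)      # one row per cell
    back <- readTruth(pref)
    expect_identical(back@cellClone, sim$truth@cellClone)
    expect_identical(back@cellNode, sim$truth@cellNode)
    expect_identical(back@mutationClass, sim$truth@mutationClass)
    expect_equal(back@trueVaf, sim$truth@trueVaf, tolerance = 1e-12)
})
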