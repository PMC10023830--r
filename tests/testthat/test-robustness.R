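# Edge-injection robustness: injection, Kendall tau, Algorithm-style runs.

test_that("injection adds the exact number of sampled non-edges", {
    ring <- ringNet(5)
    set.seed(1)
    g2 <- injectUnknownEdges(ring, 0.2)   # m = round(0.2 * 5) = 1
    expect_equal(numEdges(g2), 6)
    expect_identical(nodeNames(g2), nodeNames(ring))
    expect_equal(numEdges(ring), 5)       # original untouched

    full <- asDdiNet(igraph::make_full_graph(5))
    expect_message(g3 <- injectUnknownEdges(full, 0.3), "unchanged")
    expect_equal(numEdges(g3), numEdges(full))

    set.seed(2)
    g4 <- injectUnknownEdges(ring, 0.2, mode = "edges")
    expect_equal(numEdges(g4), 6)         # round(0.2 * |E|) = 1
})

test_that("DTI injection respects the bipartite structure", {
    dti <- generateDti(syntheticConfig(nDrugs = 15, nTargets = 12,
                                       dtiMeanDegree = 2, seed = 6))
    set.seed(3)
    g2 <- injectUnknownEdges(dti, 0.05)
    expect_gt(numEdges(g2), numEdges(dti))
    kind <- nodeKind(g2)
    ep <- igraph::as_edgelist(asIgraph(g2))
    expect_true(all(kind[ep[, 1]] == "drug" & kind[ep[, 2]] == "target"))
    expect_true(validObject(g2))
})

test_that("ranking tau handles identity, reversal, ties and degeneracy", {
    x <- c(a = 5, b = 3, c = 2, d = 1)
    expect_identical(rankingTau(x, x), 1)
    expect_equal(rankingTau(x, -x), -1)
    set.seed(4)
    for (i in 1:10) {
        u <- c(a = 1, b = 1, c = 3, d = 2, e = 5, f = 4)[sample(6)]
        v <- stats::setNames(sample(1:4, 6, replace = TRUE), names(u))
        expect_equal(rankingTau(u, v), tauOracle(u[letters[1:6]],
                                                 v[letters[1:6]]))
        expect_equal(rankingTau(u, v, variant = "a"),
                     tauOracle(u[letters[1:6]], v[letters[1:6]], "a"))
    }
    const <- c(a = 2, b = 2, c = 2)
    moving <- c(a = 1, b = 2, c = 3)
    expect_true(is.na(rankingTau(const, moving)))
    expect_identical(rankingTau(const, const), 1)
    expect_error(rankingTau(x, x[1:3]), "same node set")
})

test_that("a vanishing rate leaves tau at 1 and alpha at its reference", {
    net <- randomDdiNet(40, 0.15, seed = 31)
    # q small enough that m rounds to zero
    rc <- runRobustness(net, qGrid = 1e-4, R = 5, seed = 2)
    tab <- curveTable(rc)
    expect_equal(tab$tau_mean, 1)
    expect_equal(tab$n_injected_edges, 0)
    expect_equal(tab$alpha_mean, referenceAlpha(rc))
})

test_that("robustness curves are reproducible and complete", {
    dti <- generateDti(syntheticConfig(nDrugs = 18, nTargets = 12,
                                       dtiMeanDegree = 2, seed = 9))
    rc1 <- runRobustness(dti, qGrid = c(0.02, 0.06), R = 8, seed = 5)
    rc2 <- runRobustness(dti, qGrid = c(0.02, 0.06), R = 8, seed = 5)
    expect_identical(curveTable(rc1), curveTable(rc2))
    expect_identical(nrow(replicateTable(rc1)), 16L)
    rc3 <- runRobustness(dti, qGrid = c(0.02, 0.06), R = 8, seed = 6)
    expect_false(identical(curveTable(rc1)$tau_mean,
                           curveTable(rc3)$tau_mean))
})

test_that("degenerate-tau replicates are excluded and counted", {
    # C5 degree vector is constant: every tau_b replicate is degenerate
    ring <- ringNet(5)
    rc <- runRobustness(ring, qGrid = 0.2, R = 6, seed = 3)
    tab <- curveTable(rc)
    expect_identical(tab$n_degenerate, 6L)
    expect_true(is.na(tab$tau_mean))
    # under tau_a the same replicates are all exactly 0
    rcA <- runRobustness(ring, qGrid = 0.2, R = 6, seed = 3,
                         tauVariant = "a")
    expect_equal(curveTable(rcA)$tau_mean, 0)
})

test_that("betweenness runs are gated by the node bound", {
    net <- randomDdiNet(30, 0.2, seed = 41)
    expect_error(runRobustness(net, centrality = "betweenness",
                               qGrid = 0.05, R = 2, seed = 1,
                               nodeBound = 10L),
                 "at most 10 nodes")
    rc <- runRobustness(net, centrality = "betweenness", qGrid = 0.02,
                        R = 3, seed = 1)
    expect_identical(rc@centralityName, "betweenness")
    expect_false(any(is.na(curveTable(rc)$tau_mean)))
})

test_that("single-injection means match exhaustive enumeration", {
    # P6: degree vector (1,2,2,2,2,1); universe C(6,2) - 5 = 10, and
    # q = 0.1 injects exactly one edge per replicate
    p6 <- pathNet(6)
    uni <- nonedgeUniverse(p6)
    expect_identical(universeSize(uni), 10)
    set.seed(1)
    every <- sampleNonedges(uni, 10)
    ref <- centralityValues(degreeCentrality(p6))
    taus <- apply(every, 1, function(pr) {
        g <- igraph::add_edges(asIgraph(p6),
                               match(pr, nodeNames(p6)))
        pert <- igraph::degree(g)
        tauOracle(ref[nodeNames(p6)], pert[nodeNames(p6)])
    })
    # the end-to-end injection ties every degree: degenerate, excluded
    taus <- taus[is.finite(taus)]
    exact <- mean(taus)
    rc <- runRobustness(p6, qGrid = 0.1, R = 100, seed = 7)
    mc <- curveTable(rc)$tau_mean
    expect_lt(abs(mc - exact), 4 * stats::sd(taus) / sqrt(80) + 1e-12)
})
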