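# Node centralities against closed forms and brute-force oracles.

test_that("degree tables match adjacency row sums", {
    net <- randomDdiNet(10, 0.3, seed = 1)
    A <- as.matrix(igraph::as_adjacency_matrix(asIgraph(net)))
    expect_equal(unname(centralityValues(degreeCentrality(net))),
                 unname(rowSums(A)))
})

test_that("star betweenness: center 0.5 under both variants, leaves 0", {
    star <- starNet(3)
    for (variant in c("brandes", "pair_indicator")) {
        b <- centralityValues(betweennessCentrality(star, variant))
        center <- names(which.max(centralityValues(degreeCentrality(star))))
        expect_equal(unname(b[center]), 0.5)
        expect_true(all(b[setdiff(names(b), center)] == 0))
    }
})

test_that("Brandes betweenness equals exhaustive path enumeration", {
    for (seed in 1:12) {
        net <- randomDdiNet(sample(6:10, 1), 0.35, seed + 100)
        b <- centralityValues(betweennessCentrality(net))
        expect_equal(unname(b), betweennessOracle(asIgraph(net)),
                     tolerance = 1e-12)
    }
})

test_that("the pair-indicator variant counts pairs, not path fractions", {
    # square with a diagonal: two shortest paths between the off-diagonal
    # corners; the indicator counts the pair once for each interior node,
    # Brandes splits it
    g <- igraph::make_graph(~ A - B, B - C, C - D, D - A, A - C)
    net <- asDdiNet(g)
    bi <- centralityValues(betweennessCentrality(net, "pair_indicator"))
    bb <- centralityValues(betweennessCentrality(net, "brandes"))
    nm <- nodeNames(net)
    hubs <- names(which(centralityValues(degreeCentrality(net)) == 3))
    spokes <- setdiff(nm, hubs)
    # the B-D pair has two shortest paths, one through each hub
    expect_equal(unname(bi[hubs]), rep(1 / 6, 2))
    expect_equal(unname(bb[hubs]), rep(1 / 12, 2))
    expect_equal(unname(bi[spokes]), rep(0, 2))
})

test_that("closeness uses component scaling", {
    p3 <- pathNet(3)
    cl <- centralityValues(closenessCentrality(p3))
    deg <- centralityValues(degreeCentrality(p3))
    expect_equal(unname(cl[names(which.max(deg))]), 0.5)
    expect_equal(unname(centralityValues(closenessCentrality(
        asDdiNet(igraph::make_full_graph(4))))), rep(1 / 3, 4))
    # ring of 4 plus an edge pair: scaled by (|C|-1)/(|V|-1)
    g <- igraph::disjoint_union(igraph::make_ring(4),
                                igraph::make_full_graph(2))
    cl2 <- centralityValues(closenessCentrality(asDdiNet(g)))
    expect_equal(unname(cl2[1:4]), rep((1 / 4) * (3 / 5), 4))
    expect_equal(unname(cl2[5:6]), rep((1 / 1) * (1 / 5), 2))
})

test_that("eccentricity equals the max of BFS distances", {
    p3 <- pathNet(3)
    ec <- centralityValues(eccentricityCentrality(p3))
    deg <- centralityValues(degreeCentrality(p3))
    expect_equal(unname(ec[names(which.max(deg))]), 1)
    expect_equal(unname(sort(ec)), c(1, 2, 2))
    for (seed in 1:8) {
        net <- randomDdiNet(sample(5:12, 1), 0.3, seed + 200)
        d <- bfsDistOracle(asIgraph(net))
        d[is.infinite(d)] <- NA
        want <- apply(d, 1, max, na.rm = TRUE)
        expect_equal(unname(centralityValues(eccentricityCentrality(net))),
                     unname(want))
    }
})

test_that("eigenvector centrality matches closed forms and eigen()", {
    reg <- asDdiNet(igraph::make_ring(8))
    ev <- centralityValues(eigenvectorCentrality(reg))
    expect_equal(unname(ev), rep(1 / sqrt(8), 8), tolerance = 1e-8)

    star <- starNet(3)
    ev <- centralityValues(eigenvectorCentrality(star))
    center <- names(which.max(centralityValues(degreeCentrality(star))))
    leaf <- setdiff(names(ev), center)[1]
    expect_equal(unname(ev[center] / ev[leaf]), sqrt(3), tolerance = 1e-8)

    for (seed in 1:10) {
        net <- randomDdiNet(sample(6:12, 1), 0.4, seed + 300)
        g <- asIgraph(net)
        comp <- igraph::components(g)
        lcc <- igraph::induced_subgraph(
            g, which(comp$membership == which.max(comp$csize)))
        A <- as.matrix(igraph::as_adjacency_matrix(lcc))
        ref <- eigen(A, symmetric = TRUE)$vectors[, 1]
        ref <- abs(ref) / sqrt(sum(ref^2))
        ours <- centralityValues(eigenvectorCentrality(net))
        ours <- ours[igraph::V(lcc)$name]
        expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
    }
})

test_that("eigenvector converges on bipartite graphs and caps iterations", {
    dti <- generateDti(syntheticConfig(nDrugs = 20, nTargets = 15,
                                       dtiMeanDegree = 2, seed = 4))
    tab <- eigenvectorCentrality(dti)
    expect_true(all(centralityValues(tab) >= 0))
    expect_gt(tab@params$lambda, 0)
    expect_error(eigenvectorCentrality(dti, tol = 0, maxIter = 3L),
                 "did not converge")
})

test_that("PageRank sums to one and agrees with the linear system", {
    net <- randomDdiNet(10, 0.4, seed = 17)
    pr <- centralityValues(pageRankCentrality(net))
    expect_equal(sum(pr), 1, tolerance = 1e-9)

    reg <- asDdiNet(igraph::make_ring(6))
    expect_equal(unname(centralityValues(pageRankCentrality(reg))),
                 rep(1 / 6, 6), tolerance = 1e-9)

    g <- asIgraph(net)
    A <- as.matrix(igraph::as_adjacency_matrix(g))
    d <- rowSums(A)
    n <- nrow(A)
    M <- t(A / d)
    ref <- solve(diag(n) - 0.85 * M, rep(0.15 / n, n))
    ref <- ref / sum(ref)
    expect_equal(unname(pr), unname(ref), tolerance = 1e-6)
})
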