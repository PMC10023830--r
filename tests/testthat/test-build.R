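# DDI/DTI network construction and the non-edge universe.

test_that("one-sided listings are closed symmetrically", {
    recs <- list(drugRecord("A", groups = "approved", interactions = "B"),
                 drugRecord("B", groups = "approved"))
    net <- buildDdi(recs)
    expect_equal(numEdges(net), 1)
    expect_false(net@directed)
    expect_setequal(nodeNames(net), c("A", "B"))
})

test_that("references to filtered-out drugs are pruned and isolates dropped", {
    recs <- list(drugRecord("A", groups = "approved", interactions = "C"),
                 drugRecord("B", groups = "approved"))
    net <- buildDdi(recs)
    expect_equal(numNodes(net), 0)
    expect_equal(numEdges(net), 0)
})

test_that("a 5-ring builds with 5 nodes and 5 edges", {
    ids <- paste0("R", 1:5)
    recs <- lapply(1:5, function(i)
        drugRecord(ids[i], groups = "approved",
                   interactions = ids[i %% 5 + 1]))
    net <- buildDdi(recs)
    expect_equal(numNodes(net), 5)
    expect_equal(numEdges(net), 5)
    expect_true(all(igraph::degree(asIgraph(net)) == 2))
})

test_that("build is independent of record order and reconstructible", {
    cfg <- syntheticConfig(nDrugs = 30, nVersions = 1,
                           ddiDensitySchedule = 0.1, seed = 6)
    net <- generateDdiSeries(cfg)[[1]]
    dir <- withr::local_tempdir()
    p <- writeFixtureXML(net, dir)
    recs <- filterApproved(parseRelease(p[[1]]))
    n1 <- buildDdi(recs)
    n2 <- buildDdi(rev(recs))
    expect_identical(nodeNames(n1), nodeNames(n2))
    expect_setequal(edgeKey(n1), edgeKey(n2))
})

test_that("DTI deduplicates shared targets and keeps the star shape", {
    tg <- function(ids) data.frame(target_id = ids, organism = "Humans",
                                   known_action = "unknown")
    shared <- list(drugRecord("A", groups = "approved", targets = tg("T1")),
                   drugRecord("B", groups = "approved", targets = tg("T1")))
    net <- buildDti(shared)
    expect_equal(sum(nodeKind(net) == "target"), 1)
    expect_equal(numEdges(net), 2)

    star <- buildDti(list(drugRecord("A", groups = "approved",
                                     targets = tg(paste0("T", 1:4)))))
    deg <- centralityValues(degreeCentrality(star))
    expect_equal(unname(deg["A"]), 4)
    expect_true(all(deg[paste0("T", 1:4)] == 1))
})

test_that("drugs with only non-human targets vanish from the DTI", {
    tg <- data.frame(target_id = "T1", organism = "Mouse",
                     known_action = "unknown")
    recs <- filterApproved(list(drugRecord("A", groups = "approved",
                                           targets = tg)))
    expect_equal(numNodes(buildDti(recs)), 0)
})

test_that("the non-edge universe is counted exactly", {
    ring <- ringNet(5)
    u <- nonedgeUniverse(ring)
    expect_identical(universeSize(u), 5)   # C(5,2) - 5
    full <- asDdiNet(igraph::make_full_graph(4))
    expect_identical(universeSize(nonedgeUniverse(full)), 0)
    tg <- function(d, ids) drugRecord(d, groups = "approved",
        targets = data.frame(target_id = ids, organism = "Humans",
                             known_action = ""))
    dti <- buildDti(list(tg("A", c("T1", "T2")), tg("B", c("T2", "T3")),
                         tg("C", "T4")))
    expect_identical(universeSize(nonedgeUniverse(dti)), 3 * 4 - 5)
})

test_that("sampled non-edges are distinct, absent and partition-correct", {
    net <- randomDdiNet(40, 0.2, seed = 21)
    u <- nonedgeUniverse(net)
    set.seed(1)
    pairs <- sampleNonedges(u, 50)
    have <- edgeKey(net)
    keys <- apply(pairs, 1, function(r) paste(sort(r), collapse = "|"))
    expect_identical(anyDuplicated(keys), 0L)
    expect_false(any(keys %in% have))

    dti <- generateDti(syntheticConfig(nDrugs = 25, nTargets = 20,
                                       dtiMeanDegree = 2.2, seed = 8))
    ud <- nonedgeUniverse(dti)
    set.seed(2)
    pd <- sampleNonedges(ud, 100)
    kind <- nodeKind(dti)
    expect_true(all(kind[pd[, "from"]] == "drug"))
    expect_true(all(kind[pd[, "to"]] == "target"))
    expect_false(any(paste(pd[, 1], pd[, 2], sep = "->") %in%
                     edgeKey(dti)))
    expect_error(sampleNonedges(ud, universeSize(ud) + 1), "cannot draw")
})

test_that("rank-decoding enumerates the complement exactly", {
    # drawing the whole universe must return every non-edge once
    net <- randomDdiNet(12, 0.35, seed = 3)
    u <- nonedgeUniverse(net)
    set.seed(4)
    allPairs <- sampleNonedges(u, universeSize(u))
    keys <- apply(allPairs, 1, function(r) paste(sort(r), collapse = "|"))
    nm <- nodeNames(net)
    complement <- setdiff(apply(t(utils::combn(sort(nm), 2)), 1, paste,
                                collapse = "|"),
                          edgeKey(net))
    expect_setequal(keys, complement)
})

test_that("edge lists and GraphML round-trip", {
    net <- randomDdiNet(15, 0.25, seed = 13)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(net, f)
    back <- readEdgeList(f)
    expect_identical(nodeNames(back), sort(nodeNames(net)))
    expect_setequal(edgeKey(back), edgeKey(net))

    dti <- generateDti(syntheticConfig(nDrugs = 15, nTargets = 10,
                                       dtiMeanDegree = 2, seed = 2))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(dti, f2)
    back2 <- readEdgeList(f2)
    expect_true(isBipartite(back2))
    expect_setequal(edgeKey(back2), edgeKey(dti))

    g <- withr::local_tempfile(fileext = ".graphml")
    writeGraphML(net, g)
    reread <- igraph::read_graph(g, format = "graphml")
    expect_equal(igraph::gorder(reread), numNodes(net))
    expect_equal(igraph::gsize(reread), numEdges(net))
})
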