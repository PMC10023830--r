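# Synthetic versioned release generator.

test_that("DDI series hits its density schedule and grows monotonically", {
    cfg <- syntheticConfig(nDrugs = 100, nVersions = 2,
                           ddiDensitySchedule = c(0.02, 0.13), seed = 1)
    nets <- generateDdiSeries(cfg)
    expect_length(nets, 2)
    dens <- vapply(nets, function(n)
        2 * numEdges(n) / (numNodes(n) * (numNodes(n) - 1)), numeric(1))
    expect_lt(max(abs(dens - c(0.02, 0.13))), 0.005)
    # version 2 edge set is a superset of version 1 (pure accretion)
    expect_true(all(edgeKey(nets[[1]]) %in% edgeKey(nets[[2]])))
    # all drugs carry ids and a degree
    expect_true(all(grepl("^SD", nodeNames(nets[[2]]))))
    expect_true(all(igraph::degree(asIgraph(nets[[1]])) >= 1))
})

test_that("a flat density schedule reproduces the same network", {
    cfg <- syntheticConfig(nDrugs = 80, nVersions = 2,
                           ddiDensitySchedule = c(0.05, 0.05), seed = 4)
    nets <- generateDdiSeries(cfg)
    expect_setequal(edgeKey(nets[[1]]), edgeKey(nets[[2]]))
})

test_that("generation is deterministic in the seed", {
    cfg <- syntheticConfig(nDrugs = 70, nTargets = 50, nVersions = 2,
                           ddiDensitySchedule = c(0.03, 0.08), seed = 9)
    expect_identical(lapply(generateDdiSeries(cfg), edgeKey),
                     lapply(generateDdiSeries(cfg), edgeKey))
    expect_identical(edgeKey(generateDti(cfg)), edgeKey(generateDti(cfg)))
    other <- syntheticConfig(nDrugs = 70, nTargets = 50, nVersions = 2,
                             ddiDensitySchedule = c(0.03, 0.08), seed = 10)
    expect_false(identical(edgeKey(generateDti(cfg)),
                           edgeKey(generateDti(other))))
})

test_that("removal fraction filters edges between versions", {
    cfg <- syntheticConfig(nDrugs = 90, nVersions = 2,
                           ddiDensitySchedule = c(0.05, 0.08), seed = 2,
                           removalFraction = 0.1)
    nets <- generateDdiSeries(cfg)
    # some version-1 edges must be gone from version 2
    expect_gt(sum(!(edgeKey(nets[[1]]) %in% edgeKey(nets[[2]]))), 0)
    expect_true(all(igraph::degree(asIgraph(nets[[2]])) >= 1))
})

test_that("the DTI generator respects partition, mean degree and tails", {
    cfg <- syntheticConfig(nDrugs = 500, nTargets = 400,
                           dtiMeanDegree = 3.6, seed = 7)
    dti <- generateDti(cfg)
    expect_true(isBipartite(dti))
    kind <- nodeKind(dti)
    ep <- igraph::as_edgelist(asIgraph(dti))
    expect_true(all(kind[ep[, 1]] == "drug" & kind[ep[, 2]] == "target"))
    meanDeg <- 2 * numEdges(dti) / numNodes(dti)
    expect_lt(abs(meanDeg - 3.6) / 3.6, 0.1)
    # heavy-tailed in-degree on the target side
    indeg <- centralityValues(degreeCentrality(dti, "in"))[kind == "target"]
    a <- plAlpha(fitPowerLaw(indeg))
    expect_gte(a, 2); expect_lte(a, 4)
})

test_that("invalid configurations are rejected", {
    expect_error(syntheticConfig(nDrugs = 50, nTargets = 40,
                                 dtiMeanDegree = 45),
                 "dtiMeanDegree")
    expect_error(syntheticConfig(nVersions = 3,
                                 ddiDensitySchedule = c(0.1, 0.2)),
                 "one entry per version")
    expect_error(syntheticConfig(nVersions = 2,
                                 ddiDensitySchedule = c(0.2, 0.1)),
                 "non-decreasing")
})

test_that("fixtures round-trip through write -> parse -> build", {
    cfg <- syntheticConfig(nDrugs = 40, nTargets = 30, nVersions = 2,
                           ddiDensitySchedule = c(0.05, 0.12), seed = 5)
    nets <- generateDdiSeries(cfg)
    dti <- generateDti(cfg)
    dir <- withr::local_tempdir()
    paths <- writeFixtureXML(list(list(nets[[1]], dti), nets[[2]]), dir,
                             seed = 5)
    recs <- filterApproved(parseRelease(paths[[1]]))
    expect_setequal(edgeKey(buildDdi(recs)), edgeKey(nets[[1]]))
    expect_setequal(edgeKey(buildDti(recs)), edgeKey(dti))
    expect_setequal(nodeNames(buildDti(recs)), nodeNames(dti))
    recs2 <- filterApproved(parseRelease(paths[[2]]))
    expect_setequal(edgeKey(buildDdi(recs2)), edgeKey(nets[[2]]))
    expect_true(file.exists(file.path(dir, "manifest.json")))
})

test_that("identical seeds give byte-identical XML", {
    cfg <- syntheticConfig(nDrugs = 30, nVersions = 1,
                           ddiDensitySchedule = 0.07, seed = 11)
    net <- generateDdiSeries(cfg)[[1]]
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    p1 <- writeFixtureXML(net, d1); p2 <- writeFixtureXML(net, d2)
    expect_identical(readLines(p1[[1]]), readLines(p2[[1]]))
})

test_that("non-approved decoys are written but filtered out downstream", {
    cfg <- syntheticConfig(nDrugs = 20, nVersions = 1,
                           ddiDensitySchedule = 0.1, seed = 3)
    net <- generateDdiSeries(cfg)[[1]]
    decoy <- drugRecord("ZZ99999", groups = "experimental")
    dir <- withr::local_tempdir()
    p <- writeFixtureXML(net, dir, extraDrugs = list(decoy))
    parsed <- parseRelease(p[[1]])
    ids <- vapply(parsed, drugId, character(1))
    expect_true("ZZ99999" %in% ids)
    kept <- vapply(filterApproved(parsed), drugId, character(1))
    expect_false("ZZ99999" %in% kept)
})

test_that("an empty network serializes to valid XML with no drugs", {
    empty <- buildDdi(list(), versionLabel = "v0")
    dir <- withr::local_tempdir()
    p <- writeFixtureXML(empty, dir)
    doc <- xml2::read_xml(p[[1]])
    expect_length(xml2::xml_find_all(doc, ".//drug"), 0)
    expect_length(parseRelease(p[[1]]), 0)
})
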