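# Synthetic versioned DDI/DTI releases.
#
# The generator emulates the regime seen across real database releases: a
# monopartite DDI layer whose density grows version over version (knowledge
# accretion, modelled as edge-superset growth with an optional small removal
# fraction for curation), starting from a power-law degree sequence and
# densified by degree-proportional (preferential) edge addition; and a
# sparse bipartite drug->target layer grown by preferential attachment so
# both partitions end up with heavy-tailed degrees.

#' Synthetic release configuration
#'
#' @param nDrugs,nTargets,nVersions Positive sizes of the generated release
#'   series.
#' @param ddiDensitySchedule Non-decreasing vector of target DDI densities
#'   in (0, 1), one per version. The default interpolates between 0.019 and
#'   0.128, the density span observed between the first and latest releases
#'   being emulated.
#' @param dtiMeanDegree Target mean degree (over all nodes, \eqn{2|E|/|V|})
#'   of the bipartite DTI network; default 3.6.
#' @param degreeExponent Exponent of the seed power-law degree sequence,
#'   in (1, 4]; default 2.5.
#' @param seed Root seed; every generator substream derives from it by a
#'   fixed offset, so partial runs are reproducible.
#' @param removalFraction Fraction of DDI edges removed between consecutive
#'   versions before densification (default 0: pure accretion).
#' @param groupLabelProbabilities Named probabilities that a drug carries
#'   each group label. The default labels every drug \code{approved} (with
#'   15\% also \code{investigational}) so that generated fixtures survive
#'   the approved-drug filter and round-trip exactly.
#'
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(nDrugs = 100, nVersions = 2,
#'                        ddiDensitySchedule = c(0.02, 0.13), seed = 1)
#' @export
syntheticConfig <- function(nDrugs = 300, nTargets = 240, nVersions = 4,
                            ddiDensitySchedule = seq(0.019, 0.128,
                                                     length.out = nVersions),
                            dtiMeanDegree = 3.6, degreeExponent = 2.5,
                            seed = 1L, removalFraction = 0,
                            groupLabelProbabilities = c(
                                approved = 1, investigational = 0.15,
                                experimental = 0, withdrawn = 0,
                                vet_approved = 0)) {
    assertCount(nDrugs, "nDrugs")
    assertCount(nTargets, "nTargets")
    assertCount(nVersions, "nVersions")
    new("SyntheticConfig", nDrugs = as.integer(nDrugs),
        nTargets = as.integer(nTargets), nVersions = as.integer(nVersions),
        ddiDensitySchedule = as.numeric(ddiDensitySchedule),
        dtiMeanDegree = as.numeric(dtiMeanDegree),
        degreeExponent = as.numeric(degreeExponent),
        seed = as.integer(seed),
        removalFraction = as.numeric(removalFraction),
        groupLabelProbabilities = groupLabelProbabilities)
}

#' Draw from a (truncated) power-law distribution
#'
#' Discrete draws use exact inversion of the normalised pmf
#' \eqn{P(k) \propto k^{-\alpha}} on \code{xmin..xmax} (capped at 1e6 when
#' unbounded; the truncated mass is negligible for \eqn{\alpha > 1.5}).
#' Continuous draws use inverse-CDF sampling of the (truncated) Pareto
#' density.
#'
#' @param n Number of draws.
#' @param alpha Exponent (> 1).
#' @param xmin Lower bound (default 1).
#' @param xmax Upper bound (default \code{Inf}).
#' @param discrete Integer support (default) or continuous.
#' @return Numeric vector of draws. Respects the caller's RNG stream.
#' @examples
#' set.seed(1); rPowerLaw(5, 2.5)
#' @export
rPowerLaw <- function(n, alpha, xmin = 1, xmax = Inf, discrete = TRUE) {
    if (alpha <= 1) stop("'alpha' must exceed 1")
    if (discrete) {
        cap <- if (is.finite(xmax)) xmax else xmin + 1e6
        support <- seq(ceiling(xmin), floor(cap))
        w <- support^(-alpha)
        cdf <- cumsum(w) / sum(w)
        support[findInterval(stats::runif(n), cdf) + 1L]
    } else {
        u <- stats::runif(n)
        if (is.finite(xmax)) {
            t <- 1 - (xmax / xmin)^(1 - alpha)
            xmin * (1 - u * t)^(-1 / (alpha - 1))
        } else {
            xmin * (1 - u)^(-1 / (alpha - 1))
        }
    }
}

# --- unordered-pair index arithmetic (1-based, i < j, n nodes) ------------

pairIndexDdi <- function(i, j, n) {
    (i - 1) * n - i * (i - 1) / 2 + (j - i)
}

# First index owned by row i is pairIndexDdi(i, i + 1, n); decode by
# locating the owning row, then the column offset.
decodePairDdi <- function(idx, n) {
    starts <- pairIndexDdi(seq_len(n - 1), seq_len(n - 1) + 1, n)
    i <- findInterval(idx, starts)
    j <- i + (idx - starts[i]) + 1
    cbind(i, j)
}

# --- DDI construction ------------------------------------------------------

# Realize a degree sequence as a simple graph: random stub matching with
# self-loop/multi-edge rejection (offending pairs dropped), then repair any
# node the rejection isolated. Returns a 2-column matrix of vertex indices.
realizeDegreeSequence <- function(degs) {
    n <- length(degs)
    if (sum(degs) %% 2 == 1) {
        k <- sample.int(n, 1)
        degs[k] <- degs[k] + if (degs[k] < n - 1) 1 else -1
    }
    stubs <- sample(rep.int(seq_len(n), degs))
    half <- length(stubs) %/% 2
    a <- stubs[seq_len(half)]
    b <- stubs[half + seq_len(half)]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    lo <- pmin(a, b); hi <- pmax(a, b)
    idx <- pairIndexDdi(lo, hi, n)
    dup <- duplicated(idx)
    cbind(lo[dup == FALSE], hi[dup == FALSE])
}

# Add preferential-attachment edges (endpoints sampled proportional to
# degree) until the graph has mTarget edges. `edges` is an index-pair
# matrix; returns the grown matrix.
densifyPreferential <- function(edges, n, mTarget) {
    have <- new.env(parent = emptyenv(), size = as.integer(2 * mTarget))
    for (k in seq_len(nrow(edges)))
        assign(as.character(pairIndexDdi(edges[k, 1], edges[k, 2], n)),
               TRUE, envir = have)
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    m <- nrow(edges)
    out <- vector("list", 16L); out[[1L]] <- edges; oi <- 1L
    while (m < mTarget) {
        need <- mTarget - m
        a <- sample.int(n, 2 * need + 8L, replace = TRUE, prob = deg + 1e-9)
        b <- sample.int(n, 2 * need + 8L, replace = TRUE, prob = deg + 1e-9)
        ok <- a != b
        a <- a[ok]; b <- b[ok]
        lo <- pmin(a, b); hi <- pmax(a, b)
        idx <- as.character(pairIndexDdi(lo, hi, n))
        fresh <- !duplicated(idx) &
            !vapply(idx, exists, logical(1), envir = have,
                    inherits = FALSE)
        take <- which(fresh)[seq_len(min(need, sum(fresh)))]
        if (length(take)) {
            for (t in take) assign(idx[t], TRUE, envir = have)
            add <- cbind(lo[take], hi[take])
            oi <- oi + 1L
            if (oi > length(out)) out <- c(out, vector("list", 16L))
            out[[oi]] <- add
            deg <- deg + tabulate(c(add[, 1], add[, 2]), nbins = n)
            m <- m + length(take)
        }
    }
    do.call(rbind, out[seq_len(oi)])
}

# Remove k random edges whose endpoints both keep degree >= 1 afterwards.
removeEdgesSafely <- function(edges, n, k) {
    deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
    for (r in seq_len(k)) {
        cand <- which(deg[edges[, 1]] > 1 & deg[edges[, 2]] > 1)
        if (!length(cand)) break
        drop <- cand[sample.int(length(cand), 1)]
        deg[edges[drop, ]] <- deg[edges[drop, ]] - 1
        edges <- edges[-drop, , drop = FALSE]
    }
    edges
}

synDrugIds <- function(n) sprintf("SD%05d", seq_len(n))
synTargetIds <- function(n) sprintf("TG%05d", seq_len(n))

# Group labels per drug, drawn on a dedicated substream so that DDI and DTI
# generators agree on the labels of a given drug id.
synGroups <- function(config) {
    probs <- config@groupLabelProbabilities
    withSeed(subSeed(config@seed, 33L), {
        n <- config@nDrugs
        lab <- matrix(FALSE, n, length(probs),
                      dimnames = list(NULL, names(probs)))
        for (j in seq_along(probs))
            lab[, j] <- stats::runif(n) < probs[j]
        apply(lab, 1L, function(r) paste(names(probs)[r], collapse = ";"))
    })
}

newDdiNetwork <- function(edges, ids, label, groups) {
    used <- sort(unique(c(edges[, 1], edges[, 2])))
    g <- igraph::graph_from_edgelist(
        cbind(ids[edges[, 1]], ids[edges[, 2]]), directed = FALSE)
    g <- igraph::permute(g, match(igraph::V(g)$name,
                                  sort(igraph::V(g)$name)))
    ord <- match(igraph::V(g)$name, ids)
    igraph::V(g)$kind <- "drug"
    igraph::V(g)$displayName <- paste("Synthetic drug",
                                      sub("^SD0*", "", igraph::V(g)$name))
    igraph::V(g)$groups <- groups[ord]
    new("InteractionNetwork", graph = g, bipartite = FALSE,
        directed = FALSE, versionLabel = label)
}

#' Generate a series of versioned synthetic DDI networks
#'
#' Version 1 draws a degree sequence from a discrete power law with exponent
#' \code{degreeExponent} (truncated at \eqn{n - 1}) and realizes it via stub
#' matching with self-loop/multi-edge rejection; each version is then grown
#' to its scheduled density by degree-proportional (preferential) edge
#' addition, so version \eqn{k+1}'s edge set is a superset of version
#' \eqn{k}'s, up to the optional \code{removalFraction} emulating curation.
#' The realised density of every version matches its schedule entry to
#' within half an edge.
#'
#' @param config A [SyntheticConfig-class].
#' @return A list of [InteractionNetwork-class] objects, one per version,
#'   labelled \code{"v1"}, \code{"v2"}, ...
#' @examples
#' nets <- generateDdiSeries(syntheticConfig(nDrugs = 100, nVersions = 2,
#'     ddiDensitySchedule = c(0.02, 0.13), seed = 1))
#' sapply(nets, numEdges)
#' @export
generateDdiSeries <- function(config) {
    validObject(config)
    n <- config@nDrugs
    maxPairs <- n * (n - 1) / 2
    mk <- round(config@ddiDensitySchedule * maxPairs)
    if (any(mk > maxPairs))
        stop("scheduled density unreachable for n = ", n)
    ids <- synDrugIds(n)
    groups <- synGroups(config)
    withSeed(subSeed(config@seed, 11L), {
        degs <- rPowerLaw(n, config@degreeExponent, xmin = 1, xmax = n - 1)
        edges <- realizeDegreeSequence(degs)
        iso <- setdiff(seq_len(n), unique(c(edges[, 1], edges[, 2])))
        for (v in iso) {
            other <- sample(setdiff(seq_len(n), v), 1)
            edges <- rbind(edges, c(min(v, other), max(v, other)))
        }
        nets <- vector("list", config@nVersions)
        for (k in seq_len(config@nVersions)) {
            if (k > 1L && config@removalFraction > 0) {
                edges <- removeEdgesSafely(
                    edges, n, round(config@removalFraction * nrow(edges)))
            }
            if (nrow(edges) > mk[k]) {
                if (k == 1L)
                    edges <- removeEdgesSafely(edges, n,
                                               nrow(edges) - mk[k])
                else
                    stop("scheduled density for version ", k,
                         " is below the inherited edge count; ",
                         "increase the schedule or removalFraction")
            }
            if (nrow(edges) > mk[k])
                stop("cannot thin version ", k,
                     " to its scheduled density without isolating nodes")
            edges <- densifyPreferential(edges, n, mk[k])
            nets[[k]] <- newDdiNetwork(edges, ids, paste0("v", k), groups)
        }
        nets
    })
}

#' Generate a synthetic bipartite DTI network
#'
#' Grows a directed drug-to-target network by bipartite preferential
#' attachment: edges arrive one at a time; at scheduled arrival steps an
#' endpoint is a brand-new node (so every drug and target enters with at
#' least one edge), otherwise it is an existing node sampled proportional
#' to its current degree. The growth process yields heavy-tailed degree
#' distributions on both partitions, and the realised mean degree
#' \eqn{2|E|/|V|} equals the configured \code{dtiMeanDegree} up to rounding
#' of the edge count.
#'
#' @param config A [SyntheticConfig-class].
#' @return A bipartite, directed [InteractionNetwork-class] labelled
#'   \code{"dti"}.
#' @examples
#' dti <- generateDti(syntheticConfig(nDrugs = 120, nTargets = 90, seed = 3))
#' @export
generateDti <- function(config) {
    validObject(config)
    nD <- config@nDrugs
    nT <- config@nTargets
    m <- round(config@dtiMeanDegree * (nD + nT) / 2)
    if (m < max(nD, nT))
        stop("dtiMeanDegree too small: ", m, " edges cannot cover ",
             max(nD, nT), " nodes of one partition")
    drugNew <- floor(seq(1, m, length.out = nD))
    targNew <- floor(seq(1, m, length.out = nT))
    # additive attachment offset: sampling existing endpoints proportional
    # to (degree + a) tempers rich-get-richer growth; with the default
    # sizes (about 3 preferentially acquired edges per node) a = 3 puts
    # the emergent degree exponent near 3, typical of sparse bipartite
    # drug-target networks
    a <- 3
    withSeed(subSeed(config@seed, 22L), {
        degD <- numeric(nD)
        degT <- numeric(nT)
        usedD <- 0L
        usedT <- 0L
        from <- integer(m)
        to <- integer(m)
        seenEdge <- new.env(parent = emptyenv(), size = as.integer(2 * m))
        di <- 1L; ti <- 1L
        for (t in seq_len(m)) {
            newD <- di <= nD && t >= drugNew[di]
            newT <- ti <= nT && t >= targNew[ti]
            # if the existing drug x target grid is saturated, force an
            # early arrival so a free pair always exists
            if (!newD && !newT && t - 1 >= usedD * usedT) {
                if (di <= nD) newD <- TRUE else newT <- TRUE
            }
            if (newD) { usedD <- usedD + 1L; d <- usedD; di <- di + 1L }
            else d <- sample.int(usedD, 1,
                prob = degD[seq_len(usedD)] + a)
            if (newT) { usedT <- usedT + 1L; tt <- usedT; ti <- ti + 1L }
            else tt <- sample.int(usedT, 1,
                prob = degT[seq_len(usedT)] + a)
            if (!newD && !newT) {
                tries <- 0L
                while (!is.null(seenEdge[[paste0(d, "_", tt)]])) {
                    tries <- tries + 1L
                    if (tries > 50L) {
                        # fall back to a uniform non-edge to stay exact
                        repeat {
                            d <- sample.int(usedD, 1)
                            tt <- sample.int(usedT, 1)
                            if (is.null(seenEdge[[paste0(d, "_", tt)]]))
                                break
                        }
                        break
                    }
                    d <- sample.int(usedD, 1,
                                    prob = degD[seq_len(usedD)] + a)
                    tt <- sample.int(usedT, 1,
                                     prob = degT[seq_len(usedT)] + a)
                }
            }
            seenEdge[[paste0(d, "_", tt)]] <- TRUE
            from[t] <- d; to[t] <- tt
            degD[d] <- degD[d] + 1
            degT[tt] <- degT[tt] + 1
        }
        dIds <- synDrugIds(nD)
        tIds <- synTargetIds(nT)
        groups <- synGroups(config)
        vnames <- c(sort(dIds), sort(tIds))
        g <- igraph::make_empty_graph(n = nD + nT, directed = TRUE)
        igraph::V(g)$name <- vnames
        igraph::V(g)$kind <- rep(c("drug", "target"), c(nD, nT))
        igraph::V(g)$displayName <- c(
            paste("Synthetic drug", sub("^SD0*", "", sort(dIds))),
            paste("Synthetic target", sub("^TG0*", "", sort(tIds))))
        igraph::V(g)$groups <- c(groups[match(sort(dIds), dIds)],
                                 rep("", nT))
        g <- igraph::add_edges(g, rbind(match(dIds[from], vnames),
                                        match(tIds[to], vnames)))
        new("InteractionNetwork", graph = g, bipartite = TRUE,
            directed = TRUE, versionLabel = "dti")
    })
}

# --- XML serialization -----------------------------------------------------

xmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

# Serialize the drugs of one or more networks (sharing a version) into
# DrugBank-dialect XML lines. DDI edges are written once, under their
# lexicographically smaller endpoint; the parser's symmetric closure
# restores the undirected edge.
drugElementLines <- function(networks, extraDrugs) {
    drugs <- list()  # id -> list(name, groups, partners, targets)
    ensure <- function(id, name, groups) {
        if (is.null(drugs[[id]]))
            drugs[[id]] <<- list(name = name, groups = groups,
                                 partners = character(),
                                 targets = list())
        invisible(NULL)
    }
    for (net in networks) {
        g <- net@graph
        nm <- igraph::V(g)$name
        disp <- igraph::V(g)$displayName
        if (is.null(disp)) disp <- nm
        grp <- igraph::V(g)$groups
        if (is.null(grp)) grp <- rep("approved", length(nm))
        kind <- igraph::V(g)$kind
        ep <- igraph::ends(g, igraph::E(g), names = FALSE)
        if (!net@bipartite) {
            for (v in which(kind == "drug"))
                ensure(nm[v], disp[v], grp[v])
            if (nrow(ep)) {
                lo <- ifelse(nm[ep[, 1]] < nm[ep[, 2]], ep[, 1], ep[, 2])
                hi <- ifelse(nm[ep[, 1]] < nm[ep[, 2]], ep[, 2], ep[, 1])
                for (k in seq_along(lo)) {
                    id <- nm[lo[k]]
                    drugs[[id]]$partners <-
                        c(drugs[[id]]$partners, nm[hi[k]])
                }
            }
        } else {
            for (v in which(kind == "drug"))
                ensure(nm[v], disp[v], grp[v])
            if (nrow(ep)) {
                for (k in seq_len(nrow(ep))) {
                    id <- nm[ep[k, 1]]
                    drugs[[id]]$targets[[length(drugs[[id]]$targets) + 1L]] <-
                        list(target_id = nm[ep[k, 2]],
                             organism = "Humans", known_action = "unknown")
                }
            }
        }
    }
    for (rec in extraDrugs) {
        drugs[[rec@drugId]] <- list(
            name = rec@name, groups = paste(rec@groups, collapse = ";"),
            partners = rec@interactions,
            targets = lapply(seq_len(nrow(rec@targets)), function(i)
                as.list(rec@targets[i, ])))
    }
    lines <- character()
    for (id in sort(names(drugs))) {
        d <- drugs[[id]]
        lines <- c(lines, "  <drug>",
            sprintf("    <drugbank-id>%s</drugbank-id>", xmlEscape(id)),
            sprintf("    <name>%s</name>", xmlEscape(d$name)))
        gl <- strsplit(d$groups, ";", fixed = TRUE)[[1]]
        gl <- gl[nzchar(gl)]
        lines <- c(lines, "    <groups>",
            sprintf("      <group>%s</group>", xmlEscape(gl)),
            "    </groups>")
        lines <- c(lines, "    <drug-interactions>")
        for (p in sort(unique(d$partners)))
            lines <- c(lines,
                "      <drug-interaction>",
                sprintf("        <drugbank-id>%s</drugbank-id>",
                        xmlEscape(p)),
                "      </drug-interaction>")
        lines <- c(lines, "    </drug-interactions>", "    <targets>")
        for (tg in d$targets)
            lines <- c(lines,
                "      <target>",
                sprintf("        <id>%s</id>", xmlEscape(tg$target_id)),
                sprintf("        <organism>%s</organism>",
                        xmlEscape(tg$organism)),
                sprintf("        <known-action>%s</known-action>",
                        xmlEscape(tg$known_action)),
                "      </target>")
        lines <- c(lines, "    </targets>", "  </drug>")
    }
    lines
}

#' Write networks as DrugBank-dialect XML fixtures
#'
#' Serializes each element of \code{networks} into one XML file in the
#' dialect read by [parseRelease()]; an element may itself be a list of
#' networks (e.g. a DDI and a DTI layer of the same version) merged into a
#' single release file. Parsing a written file and rebuilding the networks
#' reproduces the original node and edge sets exactly, and output is
#' byte-deterministic.
#'
#' @param networks An [InteractionNetwork-class], or a list whose elements
#'   are networks or lists of networks to merge per file.
#' @param dir Output directory (created if needed).
#' @param fileNames Optional file names, one per release; defaults to
#'   \code{<versionLabel>.xml}.
#' @param extraDrugs List of [DrugRecord-class] objects appended verbatim to
#'   every file (e.g. decoy drugs that the approved filter must reject).
#' @param seed Optional seed recorded in the manifest.
#' @return Invisibly, the written file paths. A \code{manifest.json} listing
#'   version labels and files is written alongside.
#' @examples
#' nets <- generateDdiSeries(syntheticConfig(nDrugs = 30, nVersions = 2,
#'     ddiDensitySchedule = c(0.05, 0.1), seed = 1))
#' paths <- writeFixtureXML(nets, tempfile("fixtures"))
#' @export
writeFixtureXML <- function(networks, dir, fileNames = NULL,
                            extraDrugs = list(), seed = NULL) {
    if (is(networks, "InteractionNetwork"))
        networks <- list(networks)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    labels <- vapply(networks, function(el) {
        if (is(el, "InteractionNetwork")) el@versionLabel
        else el[[1]]@versionLabel
    }, character(1))
    if (is.null(fileNames))
        fileNames <- paste0(labels, ".xml")
    paths <- file.path(dir, fileNames)
    for (k in seq_along(networks)) {
        el <- networks[[k]]
        if (is(el, "InteractionNetwork")) el <- list(el)
        body <- drugElementLines(el, extraDrugs)
        doc <- c('<?xml version="1.0" encoding="UTF-8"?>',
                 sprintf('<drugbank version="%s">', xmlEscape(labels[k])),
                 body, "</drugbank>")
        xml2::read_xml(paste(doc, collapse = "\n"))  # well-formedness check
        ok <- tryCatch({
            writeLines(doc, paths[k], useBytes = TRUE)
            TRUE
        }, error = function(e) e)
        if (!isTRUE(ok))
            stop("failed to write fixture ", paths[k], ": ",
                 conditionMessage(ok))
    }
    manifest <- list(versions = as.list(labels),
                     files = as.list(fileNames))
    if (!is.null(seed)) manifest$seed <- seed
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    invisible(paths)
}
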