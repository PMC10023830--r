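# Network construction from filtered drug records.

# Internal: wrap an igraph into a validated InteractionNetwork.
newInteractionNetwork <- function(g, bipartite, directed, label) {
    new("InteractionNetwork", graph = g, bipartite = bipartite,
        directed = directed, versionLabel = as.character(label))
}

#' Build the drug-drug interaction network
#'
#' Creates the monopartite, undirected, unweighted DDI network from a set of
#' (filtered) drug records: an edge \{a, b\} exists iff a lists b or b lists
#' a as an interaction partner (symmetric closure -- listings are mirrored
#' in principle but not always in practice) and both drugs are in the record
#' set. Partner identifiers pointing outside the record set are pruned, and
#' drugs left without any surviving interaction are omitted. Nodes are
#' ordered lexicographically by identifier, so the build is deterministic
#' and independent of the input record order.
#'
#' @param records List of [DrugRecord-class] objects (typically the output
#'   of [filterApproved()]).
#' @param versionLabel Label stored on the network.
#' @return An [InteractionNetwork-class] with \code{bipartite = FALSE}.
#' @examples
#' recs <- list(drugRecord("A", interactions = "B", groups = "approved"),
#'              drugRecord("B", groups = "approved"))
#' numEdges(buildDdi(recs))  # 1, via symmetric closure
#' @export
buildDdi <- function(records, versionLabel = "") {
    ids <- vapply(records, function(r) r@drugId, character(1))
    from <- character(0); to <- character(0)
    for (rec in records) {
        partners <- intersect(rec@interactions, ids)
        if (length(partners)) {
            from <- c(from, rep(rec@drugId, length(partners)))
            to <- c(to, partners)
        }
    }
    if (length(from)) {
        lo <- pmin(from, to); hi <- pmax(from, to)
        keep <- !duplicated(paste0(lo, "\r", hi))
        lo <- lo[keep]; hi <- hi[keep]
    } else {
        lo <- hi <- character(0)
    }
    nodes <- sort(unique(c(lo, hi)))
    g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
    igraph::V(g)$name <- nodes
    igraph::V(g)$kind <- "drug"
    if (length(lo))
        g <- igraph::add_edges(g, rbind(match(lo, nodes), match(hi, nodes)))
    newInteractionNetwork(g, FALSE, FALSE, versionLabel)
}

#' Build the drug-target interaction network
#'
#' Creates the bipartite, directed (drug to target), unweighted DTI network:
#' one edge per (drug, target) annotation, with targets deduplicated by
#' identifier across drugs. Drugs without targets and targets referenced by
#' no drug are omitted. Node order is lexicographic within each partition
#' (drugs first).
#'
#' @inheritParams buildDdi
#' @return An [InteractionNetwork-class] with \code{bipartite = TRUE}.
#' @examples
#' tg <- data.frame(target_id = "T1", organism = "Humans",
#'                  known_action = "yes")
#' recs <- list(drugRecord("A", groups = "approved", targets = tg),
#'              drugRecord("B", groups = "approved", targets = tg))
#' numNodes(buildDti(recs))  # 3: two drugs sharing one target
#' @export
buildDti <- function(records, versionLabel = "") {
    from <- character(0); to <- character(0)
    for (rec in records) {
        tg <- unique(rec@targets$target_id)
        if (length(tg)) {
            from <- c(from, rep(rec@drugId, length(tg)))
            to <- c(to, tg)
        }
    }
    drugs <- sort(unique(from))
    targets <- sort(unique(to))
    nodes <- c(drugs, targets)
    g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
    igraph::V(g)$name <- nodes
    igraph::V(g)$kind <- rep(c("drug", "target"),
                             c(length(drugs), length(targets)))
    if (length(from))
        g <- igraph::add_edges(g, rbind(match(from, nodes),
                                        match(to, nodes)))
    newInteractionNetwork(g, TRUE, TRUE, versionLabel)
}

#' Describe the non-edge universe of a network
#'
#' Returns an implicit descriptor of every structurally permitted node pair
#' that carries no edge -- all unordered drug pairs minus existing edges for
#' a DDI network, all drug x target pairs minus existing edges for a DTI
#' network -- on the network's \emph{current} node set. The set size is
#' reported exactly but the set itself is never materialised; use
#' [sampleNonedges()] to draw from it.
#'
#' @param net An [InteractionNetwork-class].
#' @return A [NonedgeUniverse-class].
#' @examples
#' recs <- list(drugRecord("A", interactions = c("B", "C"),
#'                         groups = "approved"),
#'              drugRecord("B", interactions = "C", groups = "approved"),
#'              drugRecord("C", groups = "approved"))
#' universeSize(nonedgeUniverse(buildDdi(recs)))  # C(3,2) - 3 = 0
#' @export
nonedgeUniverse <- function(net) {
    g <- net@graph
    nm <- igraph::V(g)$name
    ep <- igraph::ends(g, igraph::E(g), names = FALSE)
    if (net@bipartite) {
        kind <- igraph::V(g)$kind
        drugs <- nm[kind == "drug"]
        targets <- nm[kind == "target"]
        di <- match(nm[ep[, 1]], drugs)
        ti <- match(nm[ep[, 2]], targets)
        idx <- sort((di - 1) * length(targets) + ti)
        nPairs <- as.numeric(length(drugs)) * length(targets)
        new("NonedgeUniverse", nPairs = nPairs,
            nEdges = as.numeric(nrow(ep)), size = nPairs - nrow(ep),
            bipartite = TRUE, drugNames = drugs, targetNames = targets,
            edgeIndex = idx)
    } else {
        n <- length(nm)
        lo <- pmin(ep[, 1], ep[, 2]); hi <- pmax(ep[, 1], ep[, 2])
        idx <- sort(pairIndexDdi(lo, hi, n))
        nPairs <- n * (n - 1) / 2
        new("NonedgeUniverse", nPairs = nPairs,
            nEdges = as.numeric(nrow(ep)), size = nPairs - nrow(ep),
            bipartite = FALSE, drugNames = nm, targetNames = character(),
            edgeIndex = idx)
    }
}

#' Sample non-edges uniformly without replacement
#'
#' Draws \code{m} distinct pairs from a [NonedgeUniverse-class] by
#' rank-decoding: ranks among the non-edges are sampled uniformly and each
#' rank is mapped to its pair index by a monotone fixed-point search over
#' the sorted existing-edge indices. Memory use is independent of the
#' universe size, and the draw is uniform for sparse and dense networks
#' alike.
#'
#' @param universe A [NonedgeUniverse-class].
#' @param m Number of pairs to draw (at most \code{universeSize(universe)}).
#' @return A character matrix with \code{m} rows and columns
#'   \code{from}, \code{to} (drug, partner/target).
#' @export
sampleNonedges <- function(universe, m) {
    if (m > universe@size)
        stop("cannot draw ", m, " non-edges from a universe of size ",
             universe@size)
    if (m == 0)
        return(matrix(character(0), 0, 2,
                      dimnames = list(NULL, c("from", "to"))))
    ranks <- if (universe@size <= .Machine$integer.max)
        sample.int(universe@size, m)
    else
        sample(universe@size, m)
    edgeIdx <- universe@edgeIndex
    idx <- vapply(as.numeric(ranks), function(r) {
        x <- r
        repeat {
            x2 <- r + findInterval(x, edgeIdx)
            if (x2 == x) return(x)
            x <- x2
        }
    }, numeric(1))
    if (universe@bipartite) {
        nT <- length(universe@targetNames)
        di <- floor((idx - 1) / nT) + 1
        ti <- idx - (di - 1) * nT
        cbind(from = universe@drugNames[di],
              to = universe@targetNames[ti])
    } else {
        n <- length(universe@drugNames)
        ij <- decodePairDdi(idx, n)
        cbind(from = universe@drugNames[ij[, 1]],
              to = universe@drugNames[ij[, 2]])
    }
}

#' Export / import networks
#'
#' \code{writeEdgeList()} writes a two-column TSV (with a header comment
#' recording kind and directedness) that \code{readEdgeList()} parses back
#' into an identical network; \code{writeGraphML()} writes GraphML via
#' \pkg{igraph}.
#'
#' @param net An [InteractionNetwork-class].
#' @param path Output file.
#' @return \code{readEdgeList()} returns an [InteractionNetwork-class]; the
#'   writers return \code{path} invisibly.
#' @export
writeEdgeList <- function(net, path) {
    header <- sprintf("# kind=%s directed=%s version=%s",
                      if (net@bipartite) "dti" else "ddi",
                      tolower(net@directed), net@versionLabel)
    ep <- igraph::ends(net@graph, igraph::E(net@graph))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(header, "from\tto"), con)
    if (nrow(ep))
        utils::write.table(ep, con, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' @rdname writeEdgeList
#' @export
readEdgeList <- function(path) {
    header <- readLines(path, n = 1L)
    bip <- grepl("kind=dti", header)
    label <- sub(".*version=", "", header)
    tab <- utils::read.table(path, sep = "\t", skip = 2L, header = FALSE,
                             col.names = c("from", "to"),
                             colClasses = "character")
    if (bip) {
        recs <- lapply(split(tab$to, tab$from), function(tg)
            data.frame(target_id = tg, organism = "Humans",
                       known_action = "", stringsAsFactors = FALSE))
        records <- mapply(function(id, tg)
            drugRecord(id, groups = "approved", targets = tg),
            names(recs), recs)
        buildDti(records, versionLabel = label)
    } else {
        partners <- split(c(tab$to, tab$from), c(tab$from, tab$to))
        records <- lapply(names(partners), function(id)
            drugRecord(id, groups = "approved",
                       interactions = unique(partners[[id]])))
        buildDdi(records, versionLabel = label)
    }
}

#' @rdname writeEdgeList
#' @export
writeGraphML <- function(net, path) {
    igraph::write_graph(net@graph, path, format = "graphml")
    invisible(path)
}
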