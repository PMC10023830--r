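# Test helpers: small-graph constructors and brute-force oracles that are
# independent of the package's implementation paths.

# Wrap an igraph (undirected, simple, no isolated vertices) as a DDI
# network; vertices are named D01, D02, ...
asDdiNet <- function(g, label = "test") {
    stopifnot(!igraph::is_directed(g))
    g <- igraph::simplify(g)
    deg <- igraph::degree(g)
    g <- igraph::induced_subgraph(g, which(deg > 0))
    igraph::V(g)$name <- sprintf("D%02d", seq_len(igraph::gorder(g)))
    igraph::V(g)$kind <- "drug"
    new("InteractionNetwork", graph = g, bipartite = FALSE,
        directed = FALSE, versionLabel = label)
}

randomDdiNet <- function(n, p, seed) {
    set.seed(seed)
    g <- igraph::sample_gnp(n, p)
    if (igraph::gsize(g) == 0)
        g <- igraph::add_edges(g, c(1, 2))
    asDdiNet(g)
}

ringNet <- function(n) asDdiNet(igraph::make_ring(n))

pathNet <- function(n) asDdiNet(igraph::make_ring(n, circular = FALSE))

starNet <- function(leaves) {
    asDdiNet(igraph::make_star(leaves + 1, mode = "undirected"))
}

# Pure-R BFS distances from every vertex (adjacency-list queue walk).
bfsDistOracle <- function(g) {
    n <- igraph::gorder(g)
    adj <- lapply(seq_len(n), function(v)
        as.integer(igraph::neighbors(g, v)))
    d <- matrix(Inf, n, n)
    for (s in seq_len(n)) {
        d[s, s] <- 0
        queue <- s
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            for (w in adj[[v]]) {
                if (is.infinite(d[s, w])) {
                    d[s, w] <- d[s, v] + 1
                    queue <- c(queue, w)
                }
            }
        }
    }
    d
}

# Exhaustive betweenness via shortest-path counting DP (independent of
# Brandes' accumulation): sigma[j,k] = number of shortest j-k paths;
# sigma through v = sigma[j,v] * sigma[v,k] when d[j,v] + d[v,k] = d[j,k].
betweennessOracle <- function(g) {
    n <- igraph::gorder(g)
    d <- bfsDistOracle(g)
    sigma <- matrix(0, n, n)
    adj <- lapply(seq_len(n), function(v)
        as.integer(igraph::neighbors(g, v)))
    for (s in seq_len(n)) {
        sigma[s, s] <- 1
        ord <- order(d[s, ])
        for (v in ord) {
            if (v == s || is.infinite(d[s, v])) next
            sigma[s, v] <- sum(vapply(adj[[v]], function(u)
                if (d[s, u] == d[s, v] - 1) sigma[s, u] else 0,
                numeric(1)))
        }
    }
    b <- numeric(n)
    for (v in seq_len(n)) {
        acc <- 0
        for (j in seq_len(n - 1)) for (k in (j + 1):n) {
            if (j == v || k == v || is.infinite(d[j, k])) next
            if (d[j, v] + d[v, k] == d[j, k] && sigma[j, k] > 0)
                acc <- acc + sigma[j, v] * sigma[v, k] / sigma[j, k]
        }
        b[v] <- acc
    }
    b * 2 / (n * (n - 1))
}

# O(n^2) Kendall tau by explicit pair counting.
tauOracle <- function(x, y, variant = "b") {
    n <- length(x)
    nc <- nd <- tx <- ty <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        a <- sign(x[i] - x[j]); b <- sign(y[i] - y[j])
        if (a == 0) tx <- tx + 1
        if (b == 0) ty <- ty + 1
        if (a != 0 && b != 0) {
            if (a == b) nc <- nc + 1 else nd <- nd + 1
        }
    }
    n0 <- n * (n - 1) / 2
    if (variant == "a") (nc - nd) / n0
    else (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# String-formatting route to the first significant digit (independent of
# the arithmetic scaling in the package).
firstDigitOracle <- function(x) {
    as.integer(substr(formatC(x, format = "e", digits = 12), 1, 1))
}

# Minimal hand-rolled release XML for parser tests.
releaseXml <- function(drugBodies, version = "t1") {
    paste0('<?xml version="1.0" encoding="UTF-8"?>\n',
           '<drugbank version="', version, '">\n',
           paste(drugBodies, collapse = "\n"), "\n</drugbank>\n")
}

drugXml <- function(id, groups = "approved", partners = character(),
                    targets = NULL, name = id, extra = "") {
    t <- ""
    if (!is.null(targets)) {
        t <- paste0("<targets>", paste(vapply(seq_len(nrow(targets)),
            function(i) paste0("<target><id>", targets$target_id[i],
                "</id><organism>", targets$organism[i],
                "</organism><known-action>unknown</known-action></target>"),
            character(1)), collapse = ""), "</targets>")
    }
    paste0("  <drug>", extra, "<drugbank-id>", id, "</drugbank-id><name>",
           name, "</name><groups>",
           paste0("<group>", groups, "</group>", collapse = ""),
           "</groups><drug-interactions>",
           paste(vapply(partners, function(p)
               paste0("<drug-interaction><drugbank-id>", p,
                      "</drugbank-id></drug-interaction>"), character(1)),
               collapse = ""),
           "</drug-interactions>", t, "</drug>")
}

edgeKey <- function(net) {
    el <- igraph::as_edgelist(asIgraph(net))
    if (!nrow(el)) return(character(0))
    if (net@directed) paste(el[, 1], el[, 2], sep = "->")
    else apply(el, 1, function(r) paste(sort(r), collapse = "|"))
}
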