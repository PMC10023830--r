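# Node centralities. Path-based centralities operate on the undirected
# view of the network (the convention under which the reported bipartite
# path statistics are even defined); tables carry one finite value per node.

newCentralityTable <- function(name, values, params = list()) {
    new("CentralityTable", centralityName = name, values = values,
        params = params)
}

undirectedView <- function(net) {
    if (net@directed)
        igraph::as_undirected(net@graph, mode = "collapse")
    else net@graph
}

#' Degree centrality
#'
#' @param net An [InteractionNetwork-class].
#' @param mode \code{"all"} (total degree, default), \code{"in"} or
#'   \code{"out"} (directed networks only).
#' @return A [CentralityTable-class].
#' @export
degreeCentrality <- function(net, mode = c("all", "in", "out")) {
    mode <- match.arg(mode)
    if (mode != "all" && !net@directed)
        stop("in-/out-degree require a directed network")
    vals <- igraph::degree(net@graph, mode = mode)
    newCentralityTable(switch(mode, all = "degree", `in` = "in_degree",
                              out = "out_degree"),
                       vals, list(mode = mode))
}

#' Betweenness centrality
#'
#' The default \code{"brandes"} variant is standard shortest-path
#' betweenness (fractional pair counts \eqn{\sigma_{jk}(v)/\sigma_{jk}},
#' Brandes' algorithm), normalised by the number of node pairs:
#' \eqn{b(v) = \frac{2}{|V|(|V|-1)} \sum_{j<k} \sigma_{jk}(v)/\sigma_{jk}}.
#' The \code{"pair_indicator"} variant replaces the fraction by a 0/1
#' indicator: a pair (j, k) contributes 1 iff \emph{some} shortest j--k
#' path passes through \eqn{v} as an interior node. Both are computed on
#' the undirected view.
#'
#' @param net An [InteractionNetwork-class].
#' @param variant \code{"brandes"} (default) or \code{"pair_indicator"}.
#' @return A [CentralityTable-class].
#' @examples
#' star <- buildDdi(list(
#'     drugRecord("C", interactions = c("L1", "L2", "L3"),
#'                groups = "approved"),
#'     drugRecord("L1", groups = "approved"),
#'     drugRecord("L2", groups = "approved"),
#'     drugRecord("L3", groups = "approved")))
#' centralityValues(betweennessCentrality(star))["C"]  # 0.5
#' @export
betweennessCentrality <- function(net,
                                  variant = c("brandes",
                                              "pair_indicator")) {
    variant <- match.arg(variant)
    g <- undirectedView(net)
    n <- igraph::gorder(g)
    norm <- if (n > 2) 2 / (n * (n - 1)) else 1
    if (variant == "brandes") {
        vals <- igraph::betweenness(g, directed = FALSE) * norm
    } else {
        d <- igraph::distances(g)
        vals <- numeric(n)
        for (v in seq_len(n)) {
            through <- outer(d[, v], d[v, ], `+`) == d & is.finite(d)
            through[v, ] <- FALSE
            through[, v] <- FALSE
            diag(through) <- FALSE
            vals[v] <- sum(through) / 2 * norm
        }
        names(vals) <- igraph::V(g)$name
    }
    newCentralityTable("betweenness", vals, list(variant = variant))
}

#' Closeness centrality
#'
#' For a node \eqn{v} in component \eqn{C}, the inverse of the sum of
#' shortest-path distances to the other members of its component, scaled by
#' \eqn{(|C|-1)/(|V|-1)} so that values from components of different sizes
#' are comparable. Nodes alone in their component get 0.
#'
#' @param net An [InteractionNetwork-class].
#' @return A [CentralityTable-class].
#' @export
closenessCentrality <- function(net) {
    g <- undirectedView(net)
    n <- igraph::gorder(g)
    comp <- igraph::components(g)
    vals <- numeric(n)
    for (ci in seq_len(comp$no)) {
        members <- which(comp$membership == ci)
        if (length(members) < 2) next
        d <- igraph::distances(g, v = members, to = members)
        vals[members] <- (1 / rowSums(d)) *
            (length(members) - 1) / (n - 1)
    }
    names(vals) <- igraph::V(g)$name
    newCentralityTable("closeness", vals,
                       list(scaling = "component"))
}

#' Eccentricity centrality
#'
#' Maximum shortest-path distance from a node to any node of its component
#' (undirected view).
#'
#' @param net An [InteractionNetwork-class].
#' @return A [CentralityTable-class].
#' @export
eccentricityCentrality <- function(net) {
    g <- undirectedView(net)
    vals <- igraph::eccentricity(g, mode = "all")
    newCentralityTable("eccentricity", vals, list())
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the adjacency matrix \eqn{W} (solving
#' \eqn{W\eta = \lambda\eta}), computed by shifted power iteration on the
#' largest connected component of the undirected view and L2-normalised to
#' non-negative values; nodes outside the largest component get 0. The
#' shift (iterating \eqn{(W + I)x}) leaves the eigenvectors unchanged but
#' guarantees convergence on bipartite components, whose adjacency spectrum
#' is symmetric around zero.
#'
#' @param net An [InteractionNetwork-class].
#' @param tol Convergence tolerance on successive iterates (default 1e-10).
#' @param maxIter Iteration cap (default 1000).
#' @return A [CentralityTable-class]; \code{params} records the dominant
#'   eigenvalue \code{lambda} and the iteration count.
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, maxIter = 1000L) {
    g <- undirectedView(net)
    n <- igraph::gorder(g)
    comp <- igraph::components(g)
    members <- which(comp$membership == which.max(comp$csize))
    vals <- numeric(n)
    names(vals) <- igraph::V(g)$name
    lambda <- NA_real_
    iter <- 0L
    if (length(members) == 1) {
        vals[members] <- 1
        lambda <- 0
    } else {
        lcc <- igraph::induced_subgraph(g, members)
        A <- igraph::as_adjacency_matrix(lcc, sparse = TRUE)
        x <- rep(1 / sqrt(length(members)), length(members))
        repeat {
            iter <- iter + 1L
            y <- as.numeric(A %*% x) + x  # shift by +I
            y <- y / sqrt(sum(y^2))
            delta <- max(abs(y - x))
            x <- y
            if (delta < tol) break
            if (iter >= maxIter)
                stop("eigenvector centrality did not converge within ",
                     iter, " iterations (last delta ",
                     format(delta, digits = 3), ")")
        }
        lambda <- as.numeric(x %*% (A %*% x))
        vals[members] <- x
    }
    newCentralityTable("eigenvector", vals,
                       list(tol = tol, maxIter = maxIter,
                            lambda = lambda, iterations = iter))
}

#' PageRank centrality
#'
#' Standard PageRank on the undirected view (each undirected edge acting as
#' two directed links); the values sum to 1.
#'
#' @param net An [InteractionNetwork-class].
#' @param damping Damping factor (default 0.85).
#' @return A [CentralityTable-class].
#' @export
pageRankCentrality <- function(net, damping = 0.85) {
    g <- undirectedView(net)
    vals <- igraph::page_rank(g, damping = damping)$vector
    newCentralityTable("pagerank", vals, list(damping = damping))
}
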