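# Whole-network summary statistics.

#' Summarize a network
#'
#' Computes the scalar network statistics used throughout the analysis:
#' \itemize{
#'   \item average degree \eqn{\langle d\rangle = \frac{1}{|V|}\sum_i d(v_i)
#'     = 2|E|/|V|}, with in-/out-degree means for directed networks and
#'     per-partition means for bipartite ones;
#'   \item average local clustering coefficient \eqn{\langle c\rangle}
#'     (nodes of degree < 2 contribute 0; bipartite networks are
#'     triangle-free, so \eqn{\langle c\rangle = 0} by construction);
#'   \item density \eqn{r = 2|E| / (|V|(|V|-1))}, using the total node
#'     count for both network kinds;
#'   \item average shortest-path length \eqn{\langle s\rangle} and diameter
#'     \eqn{\phi}, computed by BFS on the undirected view and
#'     averaged/maximised over node pairs of the largest connected
#'     component.
#' }
#' Path statistics are \code{NA} when the largest component has fewer than
#' two nodes. Setting \code{paths} or \code{clustering} to \code{FALSE}
#' skips the corresponding (more expensive) computations and reports
#' \code{NA}.
#'
#' @param net An [InteractionNetwork-class].
#' @param paths Compute path length and diameter (default \code{TRUE}).
#' @param clustering Compute the clustering coefficient (default
#'   \code{TRUE}).
#' @return A [MetricsSummary-class].
#' @examples
#' tri <- buildDdi(list(
#'     drugRecord("A", interactions = c("B", "C"), groups = "approved"),
#'     drugRecord("B", interactions = "C", groups = "approved"),
#'     drugRecord("C", groups = "approved")))
#' networkSummary(tri)  # <d> = 2, <c> = 1, r = 1, <s> = 1, diameter 1
#' @export
networkSummary <- function(net, paths = TRUE, clustering = TRUE) {
    g <- net@graph
    n <- igraph::gorder(g)
    m <- igraph::gsize(g)
    if (n < 1) stop("cannot summarize an empty network")
    und <- if (net@directed) igraph::as_undirected(g, mode = "each") else g

    avgDegree <- 2 * m / n
    avgIn <- avgOut <- NA_real_
    partition <- numeric(0)
    if (net@directed) {
        avgIn <- m / n
        avgOut <- m / n
    }
    if (net@bipartite) {
        kind <- igraph::V(g)$kind
        degAll <- igraph::degree(g, mode = "all")
        partition <- c(drug = mean(degAll[kind == "drug"]),
                       target = mean(degAll[kind == "target"]))
    }

    avgClust <- NA_real_
    if (clustering) {
        avgClust <- if (net@bipartite) 0 else if (n == 1) 0 else
            igraph::transitivity(und, type = "localaverage",
                                 isolates = "zero")
        if (is.nan(avgClust)) avgClust <- 0
    }

    density <- if (n > 1) 2 * m / (n * (n - 1)) else 0

    comp <- igraph::components(und)
    nComp <- comp$no
    lccSize <- max(comp$csize)

    avgPath <- diam <- NA_real_
    if (paths && lccSize >= 2) {
        lcc <- igraph::induced_subgraph(
            und, which(comp$membership == which.max(comp$csize)))
        d <- igraph::distances(lcc)
        up <- d[upper.tri(d)]
        avgPath <- mean(up)
        diam <- max(up)
    }

    new("MetricsSummary", nNodes = n, nEdges = m, avgDegree = avgDegree,
        avgInDegree = avgIn, avgOutDegree = avgOut,
        partitionAvgDegree = partition, avgClustering = avgClust,
        density = density, avgPathLength = avgPath, diameter = diam,
        nComponents = nComp, largestComponentSize = lccSize)
}

#' Turn a summary into a one-row data.frame
#'
#' @param x A [MetricsSummary-class].
#' @return A one-row \code{data.frame}, convenient for assembling evolution
#'   tables across versions.
#' @export
summaryRow <- function(x) {
    data.frame(n_nodes = x@nNodes, n_edges = x@nEdges,
               avg_degree = x@avgDegree, avg_clustering = x@avgClustering,
               density = x@density, avg_path_length = x@avgPathLength,
               diameter = x@diameter, n_components = x@nComponents,
               largest_component = x@largestComponentSize)
}
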