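# Edge-injection robustness simulation: how stable are centrality-based
# node rankings (Kendall tau) and the fitted power-law exponent when a
# fraction q of the unknown-interaction universe is assumed to exist?

#' Inject unknown edges into a network
#'
#' Returns a copy of the network with \eqn{m} additional edges drawn
#' uniformly without replacement from the non-edge universe
#' (bipartite-respecting for DTI networks). Under the default
#' \code{"universe"} mode \eqn{m = \mathrm{round}(q \cdot |E_t
#' \setminus E|)}, a fraction of the set of structurally possible but
#' unreported pairs; mode \code{"edges"} instead scales the existing edge
#' count, \eqn{m = \mathrm{round}(q \cdot |E|)}. The node set is unchanged
#' and the input network untouched.
#'
#' @param net An [InteractionNetwork-class].
#' @param q Injection rate in (0, 1).
#' @param mode \code{"universe"} (default) or \code{"edges"}.
#' @return An [InteractionNetwork-class] with the injected edges; when
#'   rounding gives \eqn{m = 0} the network is returned unchanged (with a
#'   message), and \eqn{m} is capped at the universe size (with a warning).
#' @examples
#' ring <- readEdgeList(system.file("extdata", "ring5.tsv",
#'                                  package = "DrugNetEvo"))
#' numEdges(injectUnknownEdges(ring, 0.2))  # 6 = 5 + round(0.2 * 5)
#' @export
injectUnknownEdges <- function(net, q, mode = c("universe", "edges")) {
    mode <- match.arg(mode)
    if (q <= 0 || q >= 1)
        stop("'q' must lie in (0, 1)")
    uni <- nonedgeUniverse(net)
    m <- if (mode == "universe") round(q * uni@size)
         else round(q * uni@nEdges)
    if (m == 0) {
        message("injection rate q = ", q,
                " rounds to zero edges; returning the network unchanged")
        return(net)
    }
    if (m > uni@size) {
        warning("requested ", m, " injected edges but only ", uni@size,
                " non-edges exist; capping")
        m <- uni@size
    }
    pairs <- sampleNonedges(uni, m)
    g <- net@graph
    nm <- igraph::V(g)$name
    g <- igraph::add_edges(g, rbind(match(pairs[, 1], nm),
                                    match(pairs[, 2], nm)))
    newInteractionNetwork(g, net@bipartite, net@directed, net@versionLabel)
}

#' Kendall rank correlation between two centrality tables
#'
#' Kendall \eqn{\tau} between two centrality value vectors aligned by node.
#' The default tie-corrected \eqn{\tau_b} is appropriate for centralities
#' with pervasive ties (degree in particular); \eqn{\tau_a} divides the
#' concordant-discordant difference by the raw pair count
#' \eqn{n(n-1)/2} without tie correction. Identical tables give 1. When
#' one vector is constant (every pair tied) \eqn{\tau_b} is undefined and
#' \code{NA} is returned -- reported absent, not 0.
#'
#' @param c1,c2 [CentralityTable-class] objects (or named numeric vectors)
#'   over the same node set.
#' @param variant \code{"b"} (tie-corrected, default) or \code{"a"}.
#' @return A number in \eqn{[-1, 1]}, or \code{NA} for a degenerate
#'   \eqn{\tau_b}.
#' @export
rankingTau <- function(c1, c2, variant = c("b", "a")) {
    variant <- match.arg(variant)
    x <- if (is(c1, "CentralityTable")) c1@values else c1
    y <- if (is(c2, "CentralityTable")) c2@values else c2
    if (is.null(names(x)) || is.null(names(y)) ||
        !setequal(names(x), names(y)))
        stop("the two tables must cover the same node set")
    y <- y[names(x)]
    if (identical(unname(x), unname(y)))
        return(1)
    if (variant == "b") {
        if (length(unique(x)) == 1L || length(unique(y)) == 1L)
            return(NA_real_)
        unname(stats::cor(x, y, method = "kendall"))
    } else {
        dx <- sign(outer(x, x, `-`))
        dy <- sign(outer(y, y, `-`))
        s <- dx * dy
        n <- length(x)
        sum(s[upper.tri(s)]) / (n * (n - 1) / 2)
    }
}

centralityFor <- function(net, name) {
    switch(name,
           degree = degreeCentrality(net),
           betweenness = betweennessCentrality(net),
           stop("unsupported centrality: ", name))
}

alphaOf <- function(values, mode, discrete, xmin) {
    v <- values[is.finite(values) & values > 0]
    tryCatch({
        if (mode == "mle")
            fitPowerLaw(v, discrete = discrete, xmin = xmin)@alpha
        else
            -loglogSlope(v)
    }, error = function(e) NA_real_)
}

#' Run the edge-injection robustness simulation
#'
#' For every rate \eqn{q} in the grid, runs \code{R} independent,
#' substream-seeded replicates of: inject
#' \eqn{\mathrm{round}(q\,|E_t\setminus E|)} unknown edges, recompute the
#' chosen centrality on the perturbed network \eqn{G'}, record the Kendall
#' \eqn{\tau} between the node rankings on \eqn{G} and \eqn{G'} and the
#' power-law exponent \eqn{\alpha} of the perturbed centrality
#' distribution. The curve reports per-\eqn{q} means, variances and ranges
#' over the replicates, plus the reference exponent at \eqn{q = 0}.
#' Replicates with a degenerate \eqn{\tau} (constant reference vector under
#' \eqn{\tau_b}) are excluded from the \eqn{\tau} aggregates and counted.
#'
#' Degree-based replicates cost \eqn{O(n^2)}; betweenness replicates are
#' refused above \code{nodeBound} nodes, reflecting the much steeper cost
#' of repeated all-pairs shortest-path computation on dense networks.
#'
#' @param net An [InteractionNetwork-class].
#' @param centrality \code{"degree"} (default) or \code{"betweenness"}.
#' @param qGrid Injection rates, each in (0, 1); default
#'   \code{seq(0.01, 0.1, by = 0.01)} ("from a very small value to 0.1").
#' @param R Replicates per rate (default 100).
#' @param seed Root seed for the replicate substreams.
#' @param alphaMode \code{"mle"} (default) or \code{"loglog"} (binned
#'   log-log slope).
#' @param tauVariant \code{"b"} (default) or \code{"a"}.
#' @param injectionMode Passed to [injectUnknownEdges()].
#' @param xmin Optional fixed power-law cutoff; default re-estimates the
#'   cutoff per perturbed network.
#' @param nodeBound Node-count bound for betweenness runs (default 2000).
#' @return A [RobustnessCurve-class].
#' @examples
#' dti <- generateDti(syntheticConfig(nDrugs = 20, nTargets = 15,
#'                                    dtiMeanDegree = 2, seed = 5))
#' rc <- runRobustness(dti, qGrid = c(0.02, 0.05), R = 10, seed = 1)
#' curveTable(rc)
#' @export
runRobustness <- function(net, centrality = c("degree", "betweenness"),
                          qGrid = seq(0.01, 0.1, by = 0.01), R = 100L,
                          seed = 1L, alphaMode = c("mle", "loglog"),
                          tauVariant = c("b", "a"),
                          injectionMode = c("universe", "edges"),
                          xmin = NULL, nodeBound = 2000L) {
    centrality <- match.arg(centrality)
    alphaMode <- match.arg(alphaMode)
    tauVariant <- match.arg(tauVariant)
    injectionMode <- match.arg(injectionMode)
    if (any(qGrid <= 0 | qGrid >= 1))
        stop("all q values must lie in (0, 1)")
    assertCount(R, "R")
    if (centrality == "betweenness" && numNodes(net) > nodeBound)
        stop("betweenness robustness is limited to networks with at most ",
             nodeBound, " nodes (see 'nodeBound')")

    discrete <- centrality == "degree"
    ref <- centralityFor(net, centrality)
    refAlpha <- alphaOf(ref@values, alphaMode, discrete, xmin)
    uni <- nonedgeUniverse(net)

    rows <- vector("list", length(qGrid) * R)
    ri <- 0L
    for (qi in seq_along(qGrid)) {
        q <- qGrid[qi]
        for (r in seq_len(R)) {
            repSeed <- subSeed(seed, 1000L * qi + r)
            res <- withSeed(repSeed, {
                gp <- suppressMessages(
                    injectUnknownEdges(net, q, mode = injectionMode))
                pert <- centralityFor(gp, centrality)
                tau <- rankingTau(ref, pert, variant = tauVariant)
                alpha <- alphaOf(pert@values, alphaMode, discrete, xmin)
                list(tau = tau, alpha = alpha,
                     m = numEdges(gp) - numEdges(net))
            })
            ri <- ri + 1L
            rows[[ri]] <- data.frame(q = q, replicate = r, tau = res$tau,
                                     alpha = res$alpha,
                                     n_injected = res$m)
        }
    }
    reps <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(reps, reps$q), function(d) {
        tau <- d$tau[!is.na(d$tau)]
        data.frame(
            q = d$q[1],
            tau_mean = if (length(tau)) mean(tau) else NA_real_,
            tau_var = if (length(tau) > 1) stats::var(tau) else NA_real_,
            tau_min = if (length(tau)) min(tau) else NA_real_,
            tau_max = if (length(tau)) max(tau) else NA_real_,
            n_degenerate = sum(is.na(d$tau)),
            alpha_mean = mean(d$alpha, na.rm = TRUE),
            alpha_var = if (sum(!is.na(d$alpha)) > 1)
                stats::var(d$alpha[!is.na(d$alpha)]) else NA_real_,
            n_injected_edges = mean(d$n_injected))
    }))
    rownames(agg) <- NULL
    new("RobustnessCurve", curve = agg, replicates = reps,
        referenceAlpha = refAlpha, centralityName = centrality,
        config = list(qGrid = qGrid, R = R, seed = seed,
                      alphaMode = alphaMode, tauVariant = tauVariant,
                      injectionMode = injectionMode, xmin = xmin,
                      universeSize = uni@size))
}
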