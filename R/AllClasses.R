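#' @import methods
#' @importFrom igraph V E gorder gsize is_igraph is_directed vertex_attr
#'   any_loop any_multiple degree ends
NULL

setOldClass("igraph")

#' Parsed drug record
#'
#' One drug entry from a database release: identifier, display name, group
#' labels (regulatory status), the identifiers of its interaction partners
#' and its target annotations.
#'
#' @slot drugId Unique, non-empty drug identifier.
#' @slot name Display name.
#' @slot groups Character vector of group labels, a subset of
#'   \code{c("approved", "investigational", "experimental", "withdrawn",
#'   "vet_approved", "illicit", "nutraceutical")}.
#' @slot interactions Character vector of partner drug identifiers. Never
#'   contains \code{drugId} itself.
#' @slot targets \code{data.frame} with columns \code{target_id},
#'   \code{organism} and \code{known_action}.
#'
#' @seealso [drugRecord()], [parseRelease()], [filterApproved()]
#' @exportClass DrugRecord
setClass("DrugRecord",
    representation(
        drugId = "character",
        name = "character",
        groups = "character",
        interactions = "character",
        targets = "data.frame"
    )
)

setValidity("DrugRecord", function(object) {
    msg <- character()
    if (length(object@drugId) != 1L || is.na(object@drugId) ||
        !nzchar(object@drugId))
        msg <- c(msg, "'drugId' must be a single non-empty string")
    if (object@drugId %in% object@interactions)
        msg <- c(msg, "a drug must not list itself as an interaction partner")
    if (!all(c("target_id", "organism", "known_action") %in%
             colnames(object@targets)))
        msg <- c(msg,
            "'targets' needs columns target_id, organism, known_action")
    else if (any(!nzchar(object@targets$target_id) |
                 is.na(object@targets$target_id)))
        msg <- c(msg, "all target_id values must be non-empty")
    if (length(msg)) msg else TRUE
})

#' Interaction network
#'
#' An unweighted interaction network wrapping an \pkg{igraph} graph. DDI
#' networks are monopartite and undirected (nodes are drugs, edges are
#' reported drug--drug interactions); DTI networks are bipartite and directed
#' from drug to target. Self-loops and duplicate edges are forbidden and
#' every node carries at least one edge: entities without any known
#' interaction are not part of the network.
#'
#' @slot graph The underlying \pkg{igraph} object. Vertices carry a
#'   \code{kind} attribute (\code{"drug"} or \code{"target"}).
#' @slot bipartite Logical; \code{TRUE} for DTI networks.
#' @slot directed Logical; \code{TRUE} for DTI networks (edges drug to
#'   target).
#' @slot versionLabel Release label the network was built from.
#'
#' @seealso [buildDdi()], [buildDti()], [networkSummary()]
#' @exportClass InteractionNetwork
setClass("InteractionNetwork",
    representation(
        graph = "igraph",
        bipartite = "logical",
        directed = "logical",
        versionLabel = "character"
    )
)

setValidity("InteractionNetwork", function(object) {
    g <- object@graph
    msg <- character()
    if (!is_igraph(g))
        return("'graph' must be an igraph object")
    if (igraph::any_loop(g))
        msg <- c(msg, "self-loops are not allowed")
    if (igraph::any_multiple(g))
        msg <- c(msg, "duplicate edges are not allowed")
    if (is_directed(g) != object@directed)
        msg <- c(msg, "'directed' flag does not match the graph")
    kind <- vertex_attr(g, "kind")
    if (gorder(g) > 0 &&
        (is.null(kind) || !all(kind %in% c("drug", "target"))))
        msg <- c(msg, "every vertex needs a 'kind' of drug or target")
    if (object@bipartite) {
        if (!object@directed)
            msg <- c(msg, "bipartite (DTI) networks must be directed")
        if (gsize(g) > 0) {
            ep <- ends(g, E(g), names = FALSE)
            if (!all(kind[ep[, 1L]] == "drug" & kind[ep[, 2L]] == "target"))
                msg <- c(msg, "every DTI edge must run drug -> target")
        }
    } else {
        if (gorder(g) > 0 && !all(kind == "drug"))
            msg <- c(msg, "all DDI nodes must be drugs")
        if (object@directed)
            msg <- c(msg, "DDI networks must be undirected")
    }
    if (gorder(g) > 0 && any(degree(g, mode = "all") == 0))
        msg <- c(msg, "isolated nodes are not allowed")
    if (length(msg)) msg else TRUE
})

#' Per-node centrality values
#'
#' @slot centralityName Name of the centrality (e.g. \code{"degree"},
#'   \code{"betweenness"}).
#' @slot values Named numeric vector, one finite value per network node.
#' @slot params Computation parameters (damping, tolerance, variant, ...).
#'
#' @seealso [degreeCentrality()], [betweennessCentrality()]
#' @exportClass CentralityTable
setClass("CentralityTable",
    representation(
        centralityName = "character",
        values = "numeric",
        params = "list"
    )
)

setValidity("CentralityTable", function(object) {
    msg <- character()
    if (length(object@values) && is.null(names(object@values)))
        msg <- c(msg, "'values' must be named by node id")
    if (any(!is.finite(object@values)))
        msg <- c(msg, "centrality values must be finite")
    if (length(msg)) msg else TRUE
})

#' Network summary statistics
#'
#' Scalar summaries of an [InteractionNetwork-class]: node and edge counts,
#' average degree (with directed and per-partition variants where they
#' apply), average local clustering coefficient, density, and the average
#' shortest-path length and diameter of the largest connected component of
#' the undirected view. Quantities that are undefined for a given network
#' (e.g. path length of a single-node network) are \code{NA}.
#'
#' @seealso [networkSummary()]
#' @exportClass MetricsSummary
setClass("MetricsSummary",
    representation(
        nNodes = "numeric",
        nEdges = "numeric",
        avgDegree = "numeric",
        avgInDegree = "numeric",
        avgOutDegree = "numeric",
        partitionAvgDegree = "numeric",
        avgClustering = "numeric",
        density = "numeric",
        avgPathLength = "numeric",
        diameter = "numeric",
        nComponents = "numeric",
        largestComponentSize = "numeric"
    )
)

setValidity("MetricsSummary", function(object) {
    msg <- character()
    if (!is.na(object@density) &&
        (object@density < 0 || object@density > 1))
        msg <- c(msg, "density must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Power-law fit
#'
#' Maximum-likelihood fit of \eqn{P(x) \propto x^{-\alpha}} to a positive
#' sample above a lower cutoff \eqn{x_{min}}, with the cutoff chosen by
#' minimising the Kolmogorov--Smirnov distance between data and fit.
#'
#' @slot alpha Fitted exponent (> 1).
#' @slot xmin Lower cutoff of the fitted tail.
#' @slot ksDistance Kolmogorov--Smirnov statistic of the fit on the tail.
#' @slot nTail Number of observations at or above \code{xmin}.
#' @slot discrete Whether the discrete (integer-support) likelihood was used.
#' @slot smallTail \code{TRUE} when fewer than 10 tail points supported the
#'   fit.
#'
#' @seealso [fitPowerLaw()]
#' @exportClass PowerLawFit
setClass("PowerLawFit",
    representation(
        alpha = "numeric",
        xmin = "numeric",
        ksDistance = "numeric",
        nTail = "numeric",
        discrete = "logical",
        smallTail = "logical"
    )
)

setValidity("PowerLawFit", function(object) {
    msg <- character()
    if (object@alpha <= 1)
        msg <- c(msg, "alpha must exceed 1")
    if (!is.na(object@ksDistance) &&
        (object@ksDistance < 0 || object@ksDistance > 1))
        msg <- c(msg, "ksDistance must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Benford first-digit report
#'
#' Observed first-significant-digit distribution of a positive sample
#' against the Benford distribution \eqn{P(f) = \log_{10}(1 + 1/f)}, with
#' three distances: Pearson's chi-squared statistic (used as a distance, no
#' p-value attached), the 1-D Wasserstein distance on the ordered digit
#' support, and the sum of squared deviations between the two proportion
#' vectors.
#'
#' @slot digitCounts Observed counts for digits 1..9.
#' @slot nUsed Number of values that contributed a digit.
#' @slot nExcluded Number of zero or non-finite values that were excluded.
#' @slot pObserved Observed proportions.
#' @slot pBenford Theoretical Benford proportions.
#' @slot chi2 Pearson chi-squared statistic.
#' @slot wasserstein 1-D earth-mover distance on digits.
#' @slot ssd Sum of squared deviations.
#' @slot qqPoints 9 x 2 matrix of (theoretical, observed) cumulative pairs
#'   for Q--Q plots.
#'
#' @seealso [benfordTest()]
#' @exportClass BenfordReport
setClass("BenfordReport",
    representation(
        digitCounts = "numeric",
        nUsed = "numeric",
        nExcluded = "numeric",
        pObserved = "numeric",
        pBenford = "numeric",
        chi2 = "numeric",
        wasserstein = "numeric",
        ssd = "numeric",
        qqPoints = "matrix"
    )
)

setValidity("BenfordReport", function(object) {
    msg <- character()
    if (length(object@digitCounts) != 9L)
        msg <- c(msg, "digitCounts must have 9 entries")
    if (sum(object@digitCounts) != object@nUsed)
        msg <- c(msg, "digitCounts must sum to nUsed")
    if (object@nUsed > 0 &&
        abs(sum(object@pObserved) - 1) > 1e-9)
        msg <- c(msg, "pObserved must sum to 1")
    if (any(c(object@chi2, object@wasserstein, object@ssd) < 0))
        msg <- c(msg, "distances must be non-negative")
    if (length(msg)) msg else TRUE
})

#' Robustness curve
#'
#' Result of the edge-injection robustness simulation: per injection rate
#' \eqn{q}, the mean/variance/range of the Kendall \eqn{\tau} between node
#' rankings before and after injection and the mean/variance of the fitted
#' power-law exponent \eqn{\alpha} of the perturbed centrality distribution,
#' over \code{R} replicates.
#'
#' @slot curve One aggregated row per \eqn{q}.
#' @slot replicates One row per (\eqn{q}, replicate).
#' @slot referenceAlpha Exponent fitted on the unperturbed network
#'   (the \eqn{q = 0} reference).
#' @slot centralityName Which centrality was tracked.
#' @slot config The simulation configuration that produced the curve.
#'
#' @seealso [runRobustness()]
#' @exportClass RobustnessCurve
setClass("RobustnessCurve",
    representation(
        curve = "data.frame",
        replicates = "data.frame",
        referenceAlpha = "numeric",
        centralityName = "character",
        config = "list"
    )
)

setValidity("RobustnessCurve", function(object) {
    tau <- c(object@curve$tau_mean, object@curve$tau_min,
             object@curve$tau_max)
    tau <- tau[!is.na(tau)]
    if (length(tau) && any(tau < -1 - 1e-12 | tau > 1 + 1e-12))
        return("Kendall tau values must lie in [-1, 1]")
    TRUE
})

#' Non-edge universe descriptor
#'
#' Implicit description of all node pairs that the network structure permits
#' but that carry no edge: unordered drug pairs for DDI networks, drug x
#' target pairs for DTI networks. The set is never materialised; pairs are
#' drawn by rank-decoding over the lexicographic pair enumeration, so
#' sampling stays uniform and memory-safe on large networks.
#'
#' @slot nPairs Total number of structurally possible pairs.
#' @slot nEdges Number of existing edges.
#' @slot size Exact number of non-edges, \code{nPairs - nEdges}.
#' @slot bipartite Whether pairs are drug x target.
#' @slot drugNames,targetNames Node names per partition (targetNames is
#'   empty for DDI networks).
#' @slot edgeIndex Sorted encoded indices of the existing edges.
#'
#' @seealso [nonedgeUniverse()], [sampleNonedges()]
#' @exportClass NonedgeUniverse
setClass("NonedgeUniverse",
    representation(
        nPairs = "numeric",
        nEdges = "numeric",
        size = "numeric",
        bipartite = "logical",
        drugNames = "character",
        targetNames = "character",
        edgeIndex = "numeric"
    )
)

setValidity("NonedgeUniverse", function(object) {
    msg <- character()
    if (object@size != object@nPairs - object@nEdges)
        msg <- c(msg, "size must equal nPairs - nEdges")
    if (is.unsorted(object@edgeIndex, strictly = TRUE) &&
        length(object@edgeIndex) > 1)
        msg <- c(msg, "edgeIndex must be strictly sorted")
    if (length(msg)) msg else TRUE
})

#' Synthetic release configuration
#'
#' Parameters of the synthetic versioned DDI/DTI generator. The defaults
#' emulate the regime observed across database releases: DDI density growing
#' from about 0.019 to about 0.128 over the versions, a sparse bipartite DTI
#' layer with mean degree near 3.6, and initially power-law degrees.
#'
#' @slot nDrugs,nTargets,nVersions Positive sizes.
#' @slot ddiDensitySchedule Non-decreasing target densities in (0, 1), one
#'   per version.
#' @slot dtiMeanDegree Target mean degree (over all nodes) of the DTI
#'   network.
#' @slot degreeExponent Exponent of the seed power-law degree sequence,
#'   in (1, 4].
#' @slot seed Root seed; all generator substreams derive from it.
#' @slot removalFraction Fraction of edges removed between consecutive DDI
#'   versions before densification (default 0, i.e. pure accretion).
#' @slot groupLabelProbabilities Named probabilities that a generated drug
#'   carries each group label.
#'
#' @seealso [syntheticConfig()], [generateDdiSeries()], [generateDti()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
    representation(
        nDrugs = "numeric",
        nTargets = "numeric",
        nVersions = "numeric",
        ddiDensitySchedule = "numeric",
        dtiMeanDegree = "numeric",
        degreeExponent = "numeric",
        seed = "numeric",
        removalFraction = "numeric",
        groupLabelProbabilities = "numeric"
    )
)

setValidity("SyntheticConfig", function(object) {
    msg <- character()
    if (object@nDrugs < 1 || object@nTargets < 1 || object@nVersions < 1)
        msg <- c(msg, "sizes must be positive integers")
    if (length(object@ddiDensitySchedule) != object@nVersions)
        msg <- c(msg, "ddiDensitySchedule must have one entry per version")
    if (any(object@ddiDensitySchedule <= 0 |
            object@ddiDensitySchedule >= 1))
        msg <- c(msg, "densities must lie strictly inside (0, 1)")
    if (is.unsorted(object@ddiDensitySchedule))
        msg <- c(msg, "ddiDensitySchedule must be non-decreasing")
    if (object@dtiMeanDegree <= 0)
        msg <- c(msg, "dtiMeanDegree must be positive")
    if (object@dtiMeanDegree >= min(object@nDrugs, object@nTargets))
        msg <- c(msg, "dtiMeanDegree must be below min(nDrugs, nTargets)")
    if (object@degreeExponent <= 1 || object@degreeExponent > 4)
        msg <- c(msg, "degreeExponent must lie in (1, 4]")
    if (object@removalFraction < 0 || object@removalFraction >= 1)
        msg <- c(msg, "removalFraction must lie in [0, 1)")
    p <- object@groupLabelProbabilities
    if (is.null(names(p)) || any(p < 0 | p > 1))
        msg <- c(msg, "group label probabilities must be named and in [0,1]")
    if (length(msg)) msg else TRUE
})

#' Per-version analysis report
#'
#' Everything the pipeline computes for one release: DDI and DTI summary
#' statistics, power-law fits and Benford reports per centrality, and the
#' optional robustness curves.
#'
#' @slot versionLabel Release label.
#' @slot ddiSummary,dtiSummary [MetricsSummary-class] objects (or NULL when
#'   a stage failed).
#' @slot powerLawFits,benfordReports,robustness Named lists of stage
#'   results.
#' @slot errors Named character vector of per-stage failure messages.
#'
#' @seealso [runPipeline()]
#' @exportClass VersionReport
setClass("VersionReport",
    representation(
        versionLabel = "character",
        ddiSummary = "ANY",
        dtiSummary = "ANY",
        powerLawFits = "list",
        benfordReports = "list",
        robustness = "list",
        errors = "character"
    )
)
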