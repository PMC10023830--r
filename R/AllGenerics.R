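# Generics, accessors and show methods for the core classes.

#' @rdname InteractionNetwork-class
#' @param x,object An object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("nodeKind", function(x) standardGeneric("nodeKind"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("isBipartite", function(x) standardGeneric("isBipartite"))

#' @rdname InteractionNetwork-class
#' @export
setGeneric("versionLabel", function(x) standardGeneric("versionLabel"))

#' @rdname CentralityTable-class
#' @param x An object.
#' @export
setGeneric("centralityName", function(x) standardGeneric("centralityName"))

#' @rdname CentralityTable-class
#' @export
setGeneric("centralityValues",
    function(x) standardGeneric("centralityValues"))

#' @rdname PowerLawFit-class
#' @param x An object.
#' @export
setGeneric("plAlpha", function(x) standardGeneric("plAlpha"))

#' @rdname PowerLawFit-class
#' @export
setGeneric("plXmin", function(x) standardGeneric("plXmin"))

#' @rdname PowerLawFit-class
#' @export
setGeneric("ksDistance", function(x) standardGeneric("ksDistance"))

#' @rdname PowerLawFit-class
#' @export
setGeneric("tailSize", function(x) standardGeneric("tailSize"))

#' @rdname RobustnessCurve-class
#' @param x An object.
#' @export
setGeneric("curveTable", function(x) standardGeneric("curveTable"))

#' @rdname RobustnessCurve-class
#' @export
setGeneric("replicateTable", function(x) standardGeneric("replicateTable"))

#' @rdname RobustnessCurve-class
#' @export
setGeneric("referenceAlpha", function(x) standardGeneric("referenceAlpha"))

#' @rdname NonedgeUniverse-class
#' @param x An object.
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' @rdname DrugRecord-class
#' @param x An object.
#' @export
setGeneric("drugId", function(x) standardGeneric("drugId"))

#' @rdname DrugRecord-class
#' @export
setGeneric("drugGroups", function(x) standardGeneric("drugGroups"))

#' @rdname DrugRecord-class
#' @export
setGeneric("drugInteractions",
    function(x) standardGeneric("drugInteractions"))

#' @rdname DrugRecord-class
#' @export
setGeneric("drugTargets", function(x) standardGeneric("drugTargets"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("asIgraph", "InteractionNetwork", function(x) x@graph)

#' @rdname InteractionNetwork-class
#' @export
setMethod("numNodes", "InteractionNetwork",
    function(x) igraph::gorder(x@graph))

#' @rdname InteractionNetwork-class
#' @export
setMethod("numEdges", "InteractionNetwork",
    function(x) igraph::gsize(x@graph))

#' @rdname InteractionNetwork-class
#' @export
setMethod("nodeNames", "InteractionNetwork",
    function(x) igraph::vertex_attr(x@graph, "name"))

#' @rdname InteractionNetwork-class
#' @export
setMethod("nodeKind", "InteractionNetwork", function(x) {
    k <- igraph::vertex_attr(x@graph, "kind")
    names(k) <- nodeNames(x)
    k
})

#' @rdname InteractionNetwork-class
#' @export
setMethod("isBipartite", "InteractionNetwork", function(x) x@bipartite)

#' @rdname InteractionNetwork-class
#' @export
setMethod("versionLabel", "InteractionNetwork", function(x) x@versionLabel)

setMethod("show", "InteractionNetwork", function(object) {
    kind <- if (object@bipartite) "DTI (bipartite, directed)"
            else "DDI (monopartite, undirected)"
    cat("InteractionNetwork:", kind, "\n")
    if (nzchar(object@versionLabel))
        cat("  version:", object@versionLabel, "\n")
    if (object@bipartite) {
        k <- igraph::vertex_attr(object@graph, "kind")
        cat(sprintf("  %d nodes (%d drugs, %d targets), %d edges\n",
            numNodes(object), sum(k == "drug"), sum(k == "target"),
            numEdges(object)))
    } else {
        cat(sprintf("  %d nodes, %d edges\n", numNodes(object),
            numEdges(object)))
    }
})

#' @rdname CentralityTable-class
#' @export
setMethod("centralityName", "CentralityTable",
    function(x) x@centralityName)

#' @rdname CentralityTable-class
#' @export
setMethod("centralityValues", "CentralityTable", function(x) x@values)

setMethod("show", "CentralityTable", function(object) {
    cat(sprintf("CentralityTable '%s': %d nodes\n",
        object@centralityName, length(object@values)))
    if (length(object@values)) {
        q <- stats::quantile(object@values, c(0, .5, 1))
        cat(sprintf("  min %.4g / median %.4g / max %.4g\n",
            q[[1]], q[[2]], q[[3]]))
    }
})

#' @rdname PowerLawFit-class
#' @export
setMethod("plAlpha", "PowerLawFit", function(x) x@alpha)

#' @rdname PowerLawFit-class
#' @export
setMethod("plXmin", "PowerLawFit", function(x) x@xmin)

#' @rdname PowerLawFit-class
#' @export
setMethod("ksDistance", "PowerLawFit", function(x) x@ksDistance)

#' @rdname PowerLawFit-class
#' @export
setMethod("tailSize", "PowerLawFit", function(x) x@nTail)

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf(
        "PowerLawFit (%s): alpha = %.4f, xmin = %g, KS = %.4f, n_tail = %d%s\n",
        if (object@discrete) "discrete" else "continuous",
        object@alpha, object@xmin, object@ksDistance, object@nTail,
        if (object@smallTail) " [small tail]" else ""))
})

setMethod("show", "BenfordReport", function(object) {
    cat(sprintf("BenfordReport: n = %d used, %d excluded\n",
        object@nUsed, object@nExcluded))
    cat(sprintf("  chi2 = %.4g, wasserstein = %.4g, ssd = %.4g\n",
        object@chi2, object@wasserstein, object@ssd))
})

#' @rdname RobustnessCurve-class
#' @export
setMethod("curveTable", "RobustnessCurve", function(x) x@curve)

#' @rdname RobustnessCurve-class
#' @export
setMethod("replicateTable", "RobustnessCurve", function(x) x@replicates)

#' @rdname RobustnessCurve-class
#' @export
setMethod("referenceAlpha", "RobustnessCurve", function(x) x@referenceAlpha)

setMethod("show", "RobustnessCurve", function(object) {
    cat(sprintf("RobustnessCurve (%s centrality), reference alpha %.4f\n",
        object@centralityName, object@referenceAlpha))
    print(object@curve, row.names = FALSE)
})

#' @rdname NonedgeUniverse-class
#' @export
setMethod("universeSize", "NonedgeUniverse", function(x) x@size)

setMethod("show", "NonedgeUniverse", function(object) {
    cat(sprintf(
        "NonedgeUniverse (%s): %g possible pairs, %g edges, %g non-edges\n",
        if (object@bipartite) "drug x target" else "unordered drug pairs",
        object@nPairs, object@nEdges, object@size))
})

#' @rdname DrugRecord-class
#' @export
setMethod("drugId", "DrugRecord", function(x) x@drugId)

#' @rdname DrugRecord-class
#' @export
setMethod("drugGroups", "DrugRecord", function(x) x@groups)

#' @rdname DrugRecord-class
#' @export
setMethod("drugInteractions", "DrugRecord", function(x) x@interactions)

#' @rdname DrugRecord-class
#' @export
setMethod("drugTargets", "DrugRecord", function(x) x@targets)

setMethod("show", "DrugRecord", function(object) {
    cat(sprintf("DrugRecord %s ('%s'): groups {%s}, %d interactions, %d targets\n",
        object@drugId, object@name, paste(object@groups, collapse = ", "),
        length(object@interactions), nrow(object@targets)))
})

setMethod("show", "MetricsSummary", function(object) {
    cat("MetricsSummary\n")
    cat(sprintf("  |V| = %g, |E| = %g, density = %.6g\n",
        object@nNodes, object@nEdges, object@density))
    cat(sprintf("  <d> = %.4f, <c> = %s\n", object@avgDegree,
        formatC(object@avgClustering, digits = 4, format = "fg")))
    cat(sprintf("  <s> = %s, diameter = %s (largest of %g components, %g nodes)\n",
        formatC(object@avgPathLength, digits = 4, format = "fg"),
        formatC(object@diameter, format = "fg"),
        object@nComponents, object@largestComponentSize))
})

setMethod("show", "SyntheticConfig", function(object) {
    cat(sprintf(
        "SyntheticConfig: %d drugs, %d targets, %d versions, seed %d\n",
        object@nDrugs, object@nTargets, object@nVersions, object@seed))
    cat("  DDI density schedule:",
        paste(signif(object@ddiDensitySchedule, 4), collapse = " -> "), "\n")
    cat(sprintf("  DTI mean degree %.3g, degree exponent %.3g\n",
        object@dtiMeanDegree, object@degreeExponent))
})

setMethod("show", "VersionReport", function(object) {
    cat("VersionReport:", object@versionLabel, "\n")
    if (!is.null(object@ddiSummary))
        cat(sprintf("  DDI: |V| = %g, |E| = %g\n",
            object@ddiSummary@nNodes, object@ddiSummary@nEdges))
    if (!is.null(object@dtiSummary))
        cat(sprintf("  DTI: |V| = %g, |E| = %g\n",
            object@dtiSummary@nNodes, object@dtiSummary@nEdges))
    if (length(object@errors))
        cat("  stage errors:", paste(names(object@errors), collapse = ", "),
            "\n")
})
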