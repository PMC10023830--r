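# Per-version orchestration: parse -> filter -> build -> summarize ->
# power-law -> Benford -> (optional) robustness, with per-version failure
# isolation and cross-version evolution tables.

# Session cache of parsed releases keyed by file digest, so re-running a
# pipeline over partially overlapping inputs never re-parses a file.
.parseCache <- new.env(parent = emptyenv())

parseReleaseCached <- function(xmlPath) {
    key <- unname(tools::md5sum(xmlPath))
    hit <- .parseCache[[key]]
    if (!is.null(hit))
        return(hit)
    records <- parseRelease(xmlPath)
    .parseCache[[key]] <- records
    records
}

#' Run the versioned network analysis pipeline
#'
#' For each release (a \code{version label -> XML path} pair) the pipeline
#' parses the file, applies the approved-human-drug filter, builds the DDI
#' and DTI networks, summarizes them, fits power laws to the degree
#' distributions (plus target in-degree and drug out-degree for the DTI),
#' runs the Benford first-digit test on degree and betweenness, and
#' optionally runs the edge-injection robustness simulation on the DTI
#' degree ranking. A failure in one version is caught, recorded in that
#' version's report, and does not stop the remaining versions.
#'
#' Parsed releases are cached for the session, keyed by file digest.
#'
#' @param inputs Named character vector of XML paths; names are the version
#'   labels (unnamed inputs are labelled by file name).
#' @param filterPolicy Passed to [filterApproved()].
#' @param robustness Run the robustness stage (default \code{FALSE};
#'   mirrors running the analysis with or without the simulation stage).
#' @param qGrid,R,seed Robustness parameters, see [runRobustness()].
#' @param betweennessNodeBound Betweenness stages (Benford and robustness)
#'   are skipped for networks above this many nodes.
#' @param pathMetrics Compute path-based summary statistics (default
#'   \code{TRUE}).
#' @param outDir Optional directory; when given, per-version summary JSON,
#'   centrality CSVs and the evolution table CSV are written there with
#'   6-significant-digit formatting.
#' @return A list of [VersionReport-class] objects with the evolution
#'   \code{data.frame} attached as attribute \code{"evolution"} (also
#'   returned by [evolutionTable()]).
#' @examples
#' cfg <- syntheticConfig(nDrugs = 40, nTargets = 30, nVersions = 2,
#'                        ddiDensitySchedule = c(0.05, 0.1), seed = 2)
#' dir <- tempfile("rel")
#' paths <- writeFixtureXML(c(generateDdiSeries(cfg), list(generateDti(cfg))),
#'                          dir)
#' reports <- runPipeline(stats::setNames(paths[1:2], c("v1", "v2")))
#' evolutionTable(reports)
#' @export
runPipeline <- function(inputs, filterPolicy = "permissive",
                        robustness = FALSE,
                        qGrid = seq(0.01, 0.1, by = 0.01), R = 100L,
                        seed = 1L, betweennessNodeBound = 2000L,
                        pathMetrics = TRUE, outDir = NULL) {
    labs <- names(inputs)
    if (is.null(labs)) labs <- rep("", length(inputs))
    empty <- !nzchar(labs)
    labs[empty] <- sub("[.]xml$", "", basename(inputs[empty]))
    names(inputs) <- labs
    if (!is.null(outDir))
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    reports <- vector("list", length(inputs))
    names(reports) <- names(inputs)
    for (k in seq_along(inputs)) {
        label <- names(inputs)[k]
        reports[[k]] <- analyzeVersion(label, inputs[[k]], filterPolicy,
                                       robustness, qGrid, R, seed,
                                       betweennessNodeBound, pathMetrics,
                                       outDir)
    }
    evo <- buildEvolutionTable(reports)
    if (!is.null(outDir))
        utils::write.csv(signifNumeric(evo),
                         file.path(outDir, "evolution.csv"),
                         row.names = FALSE)
    attr(reports, "evolution") <- evo
    reports
}

`%||%` <- function(a, b) if (is.null(a)) b else a

signifNumeric <- function(d, digits = 6L) {
    for (j in seq_along(d))
        if (is.numeric(d[[j]])) d[[j]] <- signif(d[[j]], digits)
    d
}

analyzeVersion <- function(label, xmlPath, filterPolicy, robustness,
                           qGrid, R, seed, bound, pathMetrics, outDir) {
    errors <- character()
    step <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            errors[[name]] <<- conditionMessage(e)
            NULL
        })
    }
    records <- step("parse", parseReleaseCached(xmlPath))
    filtered <- if (is.null(records)) NULL else
        step("filter", filterApproved(records, policy = filterPolicy))
    ddi <- dti <- NULL
    ddiSummary <- dtiSummary <- NULL
    fits <- list()
    benford <- list()
    robust <- list()
    if (!is.null(filtered)) {
        ddi <- step("build_ddi", buildDdi(filtered, versionLabel = label))
        dti <- step("build_dti", buildDti(filtered, versionLabel = label))
        if (!is.null(ddi) && numNodes(ddi) > 0) {
            ddiSummary <- step("ddi_summary",
                               networkSummary(ddi, paths = pathMetrics))
            deg <- degreeCentrality(ddi)
            fits$ddi_degree <- step("ddi_degree_fit",
                                    fitPowerLaw(deg@values))
            benford$ddi_degree <- step("ddi_degree_benford",
                                       benfordTest(deg))
            if (numNodes(ddi) <= bound) {
                btw <- step("ddi_betweenness", betweennessCentrality(ddi))
                if (!is.null(btw))
                    benford$ddi_betweenness <-
                        step("ddi_betweenness_benford", benfordTest(btw))
            }
            if (!is.null(outDir))
                writeCentralityCsv(deg, label, "ddi", outDir)
        }
        if (!is.null(dti) && numNodes(dti) > 0) {
            dtiSummary <- step("dti_summary",
                               networkSummary(dti, paths = pathMetrics))
            deg <- degreeCentrality(dti)
            kind <- nodeKind(dti)
            fits$dti_degree <- step("dti_degree_fit",
                                    fitPowerLaw(deg@values))
            fits$dti_target_in_degree <- step("dti_in_fit",
                fitPowerLaw(centralityValues(
                    degreeCentrality(dti, "in"))[kind == "target"]))
            fits$dti_drug_out_degree <- step("dti_out_fit",
                fitPowerLaw(centralityValues(
                    degreeCentrality(dti, "out"))[kind == "drug"]))
            benford$dti_degree <- step("dti_degree_benford",
                                       benfordTest(deg))
            if (numNodes(dti) <= bound) {
                btw <- step("dti_betweenness", betweennessCentrality(dti))
                if (!is.null(btw))
                    benford$dti_betweenness <-
                        step("dti_betweenness_benford", benfordTest(btw))
            }
            if (robustness)
                robust$dti_degree <- step("dti_robustness",
                    runRobustness(dti, "degree", qGrid = qGrid, R = R,
                                  seed = seed))
            if (!is.null(outDir))
                writeCentralityCsv(deg, label, "dti", outDir)
        }
    }
    report <- new("VersionReport", versionLabel = label,
                  ddiSummary = ddiSummary, dtiSummary = dtiSummary,
                  powerLawFits = fits, benfordReports = benford,
                  robustness = robust, errors = unlist(errors) %||%
                      character())
    if (!is.null(outDir))
        writeVersionJson(report, outDir)
    report
}

writeCentralityCsv <- function(tab, label, kind, outDir) {
    d <- data.frame(node = names(tab@values),
                    value = signif(unname(tab@values), 6L))
    utils::write.csv(d, file.path(outDir,
        sprintf("%s_%s_%s.csv", label, kind, tab@centralityName)),
        row.names = FALSE)
}

summaryAsList <- function(s) {
    if (is.null(s)) return(NULL)
    list(n_nodes = s@nNodes, n_edges = s@nEdges,
         avg_degree = signif(s@avgDegree, 6L),
         avg_clustering = signif(s@avgClustering, 6L),
         density = signif(s@density, 6L),
         avg_path_length = signif(s@avgPathLength, 6L),
         diameter = s@diameter, n_components = s@nComponents,
         largest_component = s@largestComponentSize)
}

writeVersionJson <- function(report, outDir) {
    out <- list(
        version = report@versionLabel,
        ddi = summaryAsList(report@ddiSummary),
        dti = summaryAsList(report@dtiSummary),
        power_law = lapply(report@powerLawFits, function(f)
            if (is.null(f)) NULL else list(
                alpha = signif(f@alpha, 6L), xmin = f@xmin,
                ks = signif(f@ksDistance, 6L), n_tail = f@nTail)),
        benford = lapply(report@benfordReports, function(b)
            if (is.null(b)) NULL else list(
                chi2 = signif(b@chi2, 6L),
                wasserstein = signif(b@wasserstein, 6L),
                ssd = signif(b@ssd, 6L), n = b@nUsed,
                n_excluded = b@nExcluded)),
        errors = as.list(report@errors))
    jsonlite::write_json(out,
        file.path(outDir, paste0(report@versionLabel, "_report.json")),
        auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

buildEvolutionTable <- function(reports) {
    rows <- lapply(reports, function(rep) {
        out <- list()
        for (kind in c("ddi", "dti")) {
            s <- if (kind == "ddi") rep@ddiSummary else rep@dtiSummary
            if (is.null(s)) next
            row <- summaryRow(s)
            row$version <- rep@versionLabel
            row$network <- kind
            fit <- rep@powerLawFits[[paste0(kind, "_degree")]]
            row$alpha_degree <- if (is.null(fit)) NA_real_ else fit@alpha
            out[[kind]] <- row
        }
        do.call(rbind, out)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) return(data.frame())
    rownames(tab) <- NULL
    tab[, c("version", "network", setdiff(names(tab),
                                          c("version", "network")))]
}

#' Cross-version evolution table
#'
#' @param reports The list returned by [runPipeline()].
#' @return A \code{data.frame} with one row per (version, network kind):
#'   node/edge counts, density, average degree, clustering, path length,
#'   diameter and the fitted degree power-law exponent.
#' @export
evolutionTable <- function(reports) {
    evo <- attr(reports, "evolution")
    if (!is.null(evo)) evo else buildEvolutionTable(reports)
}
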