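#' Construct a drug record
#'
#' @param drugId Unique non-empty drug identifier.
#' @param name Display name (defaults to the identifier).
#' @param groups Character vector of group labels.
#' @param interactions Character vector of partner drug identifiers;
#'   self-references are dropped, duplicates collapsed.
#' @param targets \code{data.frame} with columns \code{target_id},
#'   \code{organism}, \code{known_action}, or \code{NULL} for none.
#'
#' @return A [DrugRecord-class] object.
#' @examples
#' drugRecord("DB001", "aspirin", groups = "approved",
#'            interactions = c("DB002", "DB003"))
#' @export
drugRecord <- function(drugId, name = drugId, groups = character(),
                       interactions = character(), targets = NULL) {
    if (is.null(targets))
        targets <- emptyTargets()
    interactions <- sort(unique(setdiff(as.character(interactions), drugId)))
    new("DrugRecord", drugId = as.character(drugId),
        name = as.character(name), groups = as.character(groups),
        interactions = interactions, targets = targets)
}

# Extract one <drug> element (already parsed by xml2) into a DrugRecord,
# or NULL when the element has no usable identifier.
drugFromXml <- function(node) {
    id <- xml2::xml_text(xml2::xml_find_first(node, "./*[local-name()='drugbank-id']"))
    if (is.na(id) || !nzchar(id))
        return(NULL)
    name <- xml2::xml_text(xml2::xml_find_first(node, "./*[local-name()='name']"))
    if (is.na(name)) name <- id
    groups <- xml2::xml_text(xml2::xml_find_all(node,
        "./*[local-name()='groups']/*[local-name()='group']"))
    groups <- gsub("-", "_", trimws(groups))
    partners <- xml2::xml_text(xml2::xml_find_all(node,
        paste0("./*[local-name()='drug-interactions']",
               "/*[local-name()='drug-interaction']",
               "/*[local-name()='drugbank-id']")))
    tnodes <- xml2::xml_find_all(node,
        "./*[local-name()='targets']/*[local-name()='target']")
    if (length(tnodes)) {
        tid <- vapply(tnodes, function(t)
            xml2::xml_text(xml2::xml_find_first(t, "./*[local-name()='id']")),
            character(1))
        org <- vapply(tnodes, function(t)
            xml2::xml_text(xml2::xml_find_first(t,
                "./*[local-name()='organism']")), character(1))
        ka <- vapply(tnodes, function(t)
            xml2::xml_text(xml2::xml_find_first(t,
                "./*[local-name()='known-action']")), character(1))
        keep <- !is.na(tid) & nzchar(tid)
        targets <- data.frame(target_id = tid[keep],
                              organism = ifelse(is.na(org[keep]), "",
                                                org[keep]),
                              known_action = ifelse(is.na(ka[keep]), "",
                                                    ka[keep]),
                              stringsAsFactors = FALSE)
    } else {
        targets <- emptyTargets()
    }
    drugRecord(id, name, groups, partners[!is.na(partners)], targets)
}

#' Parse a DrugBank-dialect XML release
#'
#' Reads a versioned drug-database release and returns one [DrugRecord-class]
#' per \code{<drug>} element. Only the dialect paths are read
#' (\code{drugbank-id}, \code{name}, \code{groups/group},
#' \code{drug-interactions/drug-interaction/drugbank-id},
#' \code{targets/target/\{id, organism, known-action\}}); unknown elements are
#' ignored, so real releases -- a superset of the dialect -- parse as well.
#'
#' The file is consumed in a streaming fashion: lines are scanned for
#' top-level \code{<drug>} elements and each element is parsed on its own,
#' so memory use is bounded by the largest single drug entry rather than the
#' release size.
#'
#' Records without a drug identifier are skipped and counted; a second
#' occurrence of an identifier is rejected and counted. Both counts are
#' reported in a summary warning and attached as attributes
#' \code{nSkipped} and \code{nDuplicates} of the returned list.
#'
#' @param xmlPath Path to the XML file.
#' @param chunkLines Number of lines read per I/O call.
#'
#' @return A list of [DrugRecord-class] objects with attributes
#'   \code{nSkipped}, \code{nDuplicates} and \code{versionLabel} (the
#'   \code{version} attribute of the root element, when present).
#' @seealso [filterApproved()], [writeFixtureXML()]
#' @export
parseRelease <- function(xmlPath, chunkLines = 10000L) {
    if (!file.exists(xmlPath))
        stop("file not found: ", xmlPath)
    con <- file(xmlPath, open = "r", encoding = "UTF-8")
    on.exit(close(con))

    records <- list()
    seen <- new.env(parent = emptyenv())
    nSkipped <- 0L
    nDuplicates <- 0L
    versionLabel <- NA_character_
    inDrug <- FALSE
    buf <- character()
    lineNo <- 0L
    drugStartLine <- 0L

    startRe <- "<drug(>|\\s)"
    endRe <- "</drug>"

    finishDrug <- function(chunk, startLine) {
        node <- tryCatch(
            xml2::read_xml(paste(chunk, collapse = "\n")),
            error = function(e) {
                stop("malformed XML in ", xmlPath, " near line ", startLine,
                     ": ", conditionMessage(e), call. = FALSE)
            })
        rec <- drugFromXml(node)
        if (is.null(rec)) {
            nSkipped <<- nSkipped + 1L
        } else if (!is.null(seen[[rec@drugId]])) {
            nDuplicates <<- nDuplicates + 1L
        } else {
            seen[[rec@drugId]] <- TRUE
            records[[length(records) + 1L]] <<- rec
        }
    }

    repeat {
        lines <- readLines(con, n = chunkLines, warn = FALSE)
        if (!length(lines)) break
        for (ln in lines) {
            lineNo <- lineNo + 1L
            if (!inDrug) {
                if (is.na(versionLabel) && grepl("<drugbank", ln)) {
                    m <- regmatches(ln,
                        regexpr('version="[^"]*"', ln))
                    if (length(m))
                        versionLabel <- sub('version="([^"]*)"', "\\1", m)
                }
                if (grepl(startRe, ln)) {
                    inDrug <- TRUE
                    drugStartLine <- lineNo
                    buf <- ln
                    if (grepl(endRe, ln)) {
                        inDrug <- FALSE
                        finishDrug(buf, drugStartLine)
                        buf <- character()
                    }
                }
            } else {
                buf[length(buf) + 1L] <- ln
                if (grepl(endRe, ln)) {
                    inDrug <- FALSE
                    finishDrug(buf, drugStartLine)
                    buf <- character()
                }
            }
        }
    }
    if (inDrug)
        stop("malformed XML in ", xmlPath, ": <drug> element starting at line ",
             drugStartLine, " is never closed")

    if (nSkipped + nDuplicates > 0L)
        warning(sprintf("%s: skipped %d record(s) without an id, rejected %d duplicate id(s)",
                        basename(xmlPath), nSkipped, nDuplicates))
    attr(records, "nSkipped") <- nSkipped
    attr(records, "nDuplicates") <- nDuplicates
    attr(records, "versionLabel") <- versionLabel
    records
}

#' Restrict a release to approved human drugs
#'
#' Keeps a record iff it is labelled \code{approved} and not
#' \code{withdrawn} or \code{vet_approved}. Under the default
#' \code{"permissive"} policy a drug that is approved \emph{and}
#' investigational/experimental is kept (the additional label merely records
#' an ongoing trial); under \code{"strict"} any investigational or
#' experimental label disqualifies. Target annotations are restricted to the
#' requested organism (case-insensitive, trimmed). Interaction partner
#' identifiers are left untouched here: pruning references to drugs outside
#' the kept set happens at network-build time.
#'
#' The filter is idempotent: applying it twice gives the same records.
#'
#' @param records List of [DrugRecord-class] objects.
#' @param policy \code{"permissive"} (default) or \code{"strict"}.
#' @param organism Organism targets must match (default \code{"Humans"}).
#'
#' @return The filtered list of records.
#' @export
filterApproved <- function(records, policy = c("permissive", "strict"),
                           organism = "Humans") {
    policy <- match.arg(policy)
    wantOrg <- tolower(trimws(organism))
    out <- list()
    for (rec in records) {
        g <- rec@groups
        keep <- ("approved" %in% g) && !("withdrawn" %in% g) &&
            !("vet_approved" %in% g)
        if (policy == "strict")
            keep <- keep && !("investigational" %in% g) &&
                !("experimental" %in% g)
        if (!keep) next
        tg <- rec@targets
        tg <- tg[tolower(trimws(tg$organism)) == wantOrg, , drop = FALSE]
        rownames(tg) <- NULL
        rec@targets <- tg
        out[[length(out) + 1L]] <- rec
    }
    out
}
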