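# XML parsing and the approved-human-drug filter.

writeTmpXml <- function(text) {
    f <- withr::local_tempfile(fileext = ".xml",
                               .local_envir = parent.frame())
    writeLines(text, f)
    f
}

test_that("a small release parses verbatim", {
    xml <- releaseXml(c(
        drugXml("DB01", partners = "DB02"),
        drugXml("DB02", partners = c("DB01", "DB03")),
        drugXml("DB03")))
    recs <- parseRelease(writeTmpXml(xml))
    expect_length(recs, 3)
    expect_identical(vapply(recs, drugId, character(1)),
                     c("DB01", "DB02", "DB03"))
    expect_identical(drugInteractions(recs[[2]]), c("DB01", "DB03"))
    expect_identical(attr(recs, "versionLabel"), "t1")
})

test_that("unknown elements and attributes are ignored", {
    xml <- releaseXml(drugXml("DB01",
        extra = paste0("<created>2001</created>",
                       "<description>an &amp; example</description>"),
        targets = data.frame(target_id = "P100", organism = "Humans")))
    xml <- sub("<drug>", '<drug type="small molecule">', xml)
    recs <- parseRelease(writeTmpXml(xml))
    expect_length(recs, 1)
    expect_identical(drugTargets(recs[[1]])$target_id, "P100")
})

test_that("records without an id are skipped and duplicates rejected", {
    xml <- releaseXml(c(
        drugXml("DB01"),
        "  <drug><name>anonymous</name></drug>",
        drugXml("DB01", name = "impostor"),
        drugXml("DB02")))
    expect_warning(recs <- parseRelease(writeTmpXml(xml)),
                   "skipped 1 .* 1 duplicate")
    expect_length(recs, 2)
    expect_identical(attr(recs, "nSkipped"), 1L)
    expect_identical(attr(recs, "nDuplicates"), 1L)
    # the first occurrence wins
    expect_identical(recs[[1]]@name, "DB01")
})

test_that("malformed XML reports the offending location", {
    xml <- c('<?xml version="1.0"?>', "<drugbank>",
             "  <drug><drugbank-id>DB01</drugbank-id>",
             "  <groups><group>approved</grp></groups>",
             "  </drug>", "</drugbank>")
    f <- writeTmpXml(paste(xml, collapse = "\n"))
    expect_error(parseRelease(f), "malformed XML.*line 3")
    f2 <- writeTmpXml(c('<drugbank>', '<drug><drugbank-id>X</drugbank-id>'))
    expect_error(parseRelease(f2), "never closed")
})

test_that("parsing is order-independent", {
    bodies <- c(drugXml("DB01", partners = "DB02"),
                drugXml("DB02"), drugXml("DB03", partners = "DB01"))
    r1 <- parseRelease(writeTmpXml(releaseXml(bodies)))
    r2 <- parseRelease(writeTmpXml(releaseXml(rev(bodies))))
    byId <- function(r) r[order(vapply(r, drugId, character(1)))]
    expect_equal(byId(r1), byId(r2))
})

test_that("self-interactions are dropped on construction", {
    recs <- parseRelease(writeTmpXml(releaseXml(
        drugXml("DB01", partners = c("DB01", "DB02")))))
    expect_identical(drugInteractions(recs[[1]]), "DB02")
    expect_error(new("DrugRecord", drugId = "A", name = "A",
                     groups = "approved", interactions = "A",
                     targets = drugTargets(recs[[1]])),
                 "itself")
})

test_that("the approved filter implements both policies", {
    recs <- list(
        drugRecord("A", groups = "approved"),
        drugRecord("B", groups = c("approved", "withdrawn")),
        drugRecord("C", groups = c("approved", "investigational")),
        drugRecord("D", groups = c("approved", "vet_approved")),
        drugRecord("E", groups = "experimental"),
        drugRecord("F", groups = c("approved", "experimental")))
    ids <- function(r) vapply(r, drugId, character(1))
    expect_identical(ids(filterApproved(recs)), c("A", "C", "F"))
    expect_identical(ids(filterApproved(recs, policy = "strict")), "A")
})

test_that("the filter restricts targets to the requested organism", {
    tg <- data.frame(target_id = c("P1", "P2", "P3"),
                     organism = c("Humans", " humans ", "Mouse"),
                     known_action = "unknown")
    rec <- drugRecord("A", groups = "approved", targets = tg)
    out <- filterApproved(list(rec))
    expect_identical(drugTargets(out[[1]])$target_id, c("P1", "P2"))
})

test_that("the filter is idempotent", {
    recs <- list(
        drugRecord("A", groups = c("approved", "investigational"),
                   targets = data.frame(target_id = "P1",
                                        organism = "Humans",
                                        known_action = "")),
        drugRecord("B", groups = "approved"))
    once <- filterApproved(recs)
    expect_equal(filterApproved(once), once)
})
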