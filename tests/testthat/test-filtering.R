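test_that("classifyId applies checks in fixed precedence", {
    rec <- function(org = "rat", reviewed = TRUE, obsolete = FALSE)
        list(organism = org, reviewed = reviewed, obsolete = obsolete)
    allModes <- c("organism_based", "reviewed_based", "decoy_based")
    expect_identical(
        classifyId("B4DQ80", rec("human"), "organism_based", "rat"),
        "wrong_organism")
    expect_identical(
        classifyId("CON__P00761", NULL, "decoy_based"), "contaminant")
    expect_identical(
        classifyId("REV__Q63610", rec(), allModes, "rat"), "decoy")
    expect_identical(
        classifyId("Q63610", rec(), allModes, "rat"), "keep")
    ## decoy/contaminant outranks organism; obsolete outranks organism;
    ## organism outranks reviewed
    expect_identical(
        classifyId("CON__X", rec("human"), allModes, "rat"),
        "contaminant")
    expect_identical(
        classifyId("X1", rec("human", obsolete = TRUE), allModes, "rat"),
        "obsolete")
    expect_identical(
        classifyId("X1", rec("human", reviewed = FALSE), allModes, "rat"),
        "wrong_organism")
    ## unknown accession is treated like obsolete for record-based modes
    expect_identical(classifyId("X1", NULL, "reviewed_based"), "obsolete")
    ## decoy-only mode never consults the record
    expect_identical(classifyId("X1", NULL, "decoy_based"), "keep")
})

test_that("wrong-organism members are removed from a rat protein group", {
    fx <- ucFixture()
    tb <- studyTable(list(c("B4DQ80", "Q63610", "B7Z722")),
                     organism = "rat")
    res <- filterProteinIds(tb, fx$provider, modes = "organism_based",
                            targetOrganism = "rat")
    expect_identical(unname(idGroups(res$table)), list("Q63610"))
    ov <- res$overview
    expect_identical(ov$kept_ids, "Q63610")
    expect_identical(ov$removed_ids, "B4DQ80;B7Z722")
    expect_identical(res$detail$reason,
                     rep("wrong_organism", 2))
    expect_match(res$detail$metadata, "organism=human", all = TRUE)
})

test_that("no-op filtering leaves an all-reviewed table unchanged", {
    fx <- ucFixture()
    tb <- fx$proteinStudies$study1_human
    res <- filterProteinIds(tb, fx$provider, modes = "reviewed_based")
    expect_identical(idGroups(res$table), idGroups(tb))
    expect_identical(sum(res$overview$n_removed), 0L)
})

test_that("random-table totals match a direct annotation-table scan", {
    w <- randomWorld()
    tb <- sampleStudyTable(w$provider, "rat", nRows = 50, rngSeed = 21,
                           fractionForeign = 0.15)
    res <- filterProteinIds(tb, w$provider,
        modes = c("organism_based", "reviewed_based", "decoy_based"),
        targetOrganism = "rat")
    expectLogInvariants(res)
    ## brute-force rescan of the raw proteins table, independent of
    ## classifyId
    p <- w$proteins
    expectedVerdict <- function(a) {
        if (startsWith(a, "REV__")) return("decoy")
        if (startsWith(a, "CON__")) return("contaminant")
        i <- which(p$accession == a)
        if (!length(i) || p$obsolete[i]) return("obsolete")
        if (p$organism[i] != "rat") return("wrong_organism")
        if (!p$reviewed[i]) return("unreviewed")
        "keep"
    }
    for (i in seq_len(nrow(tb))) {
        grp <- idGroups(tb)[[i]]
        verd <- vapply(grp, expectedVerdict, character(1))
        expect_identical(res$overview$n_kept[i], sum(verd == "keep"))
        expect_identical(res$overview$n_removed[i], sum(verd != "keep"))
    }
    ## reason totals agree with the scan
    allIds <- unlist(idGroups(tb))
    scan <- table(vapply(allIds[!duplicated(allIds)], expectedVerdict,
                         character(1)))
    logged <- table(res$detail$reason)
    for (rs in setdiff(names(scan), "keep"))
        expect_gte(as.integer(logged[rs]), 1L)
})

test_that("filtering is idempotent and monotone in modes", {
    w <- randomWorld()
    tb <- sampleStudyTable(w$provider, "mouse", nRows = 40, rngSeed = 8,
                           fractionForeign = 0.2)
    allModes <- c("organism_based", "reviewed_based", "decoy_based")
    once <- filterProteinIds(tb, w$provider, modes = allModes,
                             targetOrganism = "mouse")
    twice <- filterProteinIds(once$table, w$provider, modes = allModes,
                              targetOrganism = "mouse")
    expect_identical(idGroups(twice$table), idGroups(once$table))
    expect_identical(sum(twice$overview$n_removed), 0L)
    ## adding a mode never increases the kept set
    keptUnder <- function(modes) {
        r <- filterProteinIds(tb, w$provider, modes = modes,
                              targetOrganism = "mouse", keepEmpty = TRUE)
        unlist(idGroups(r$table))
    }
    k1 <- keptUnder("organism_based")
    k2 <- keptUnder(c("organism_based", "reviewed_based"))
    k3 <- keptUnder(allModes)
    expect_true(all(k2 %in% k1))
    expect_true(all(k3 %in% k2))
})

test_that("single-ID rows drop with their row; keepEmpty retains them", {
    fx <- ucFixture()
    tb <- fx$proteinStudies$study3_rat
    res <- filterProteinIds(tb, fx$provider, modes = "organism_based",
                            targetOrganism = "rat")
    expect_identical(nrow(res$table), nrow(tb) - 2L)
    expect_false(any(c("B4DQ80", "B7Z722") %in%
                     unlist(idGroups(res$table))))
    kept <- filterProteinIds(tb, fx$provider, modes = "organism_based",
                             targetOrganism = "rat", keepEmpty = TRUE)
    expect_identical(nrow(kept$table), nrow(tb))
})

test_that("gene-only studies are rejected for protein filtering", {
    fx <- ucFixture()
    expect_error(
        filterProteinIds(fx$publishedGeneStudies$study4_mouse,
                         fx$provider, modes = "organism_based",
                         targetOrganism = "mouse"),
        "gene IDs")
})
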