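test_that("ID cells split on the group separator", {
    tb <- studyTable(c("P1;P2;P3", "P1"), organism = "human")
    expect_identical(unname(idGroups(tb)),
                     list(c("P1", "P2", "P3"), "P1"))
    ## empty cells parse to empty groups, not errors
    tb2 <- studyTable(c("P1", ""), organism = "human")
    expect_identical(unname(idGroups(tb2))[[2]], character())
})

test_that("TSV/CSV round-trip preserves structure and quoted extras", {
    dir <- withr::local_tempdir()
    path <- file.path(dir, "study.tsv")
    extra <- data.frame(note = c("a, quoted", "plain", "x;y"),
                        stringsAsFactors = FALSE)
    tb <- studyTable(c("P1;P2", "P3", "P4;P5;P6"), organism = "rat",
                     extra = extra)
    writeStudyTable(tb, path)
    tb2 <- readStudyTable(path, "Protein IDs", "rat")
    expect_identical(unname(idGroups(tb2)), unname(idGroups(tb)))
    expect_identical(extraColumns(tb2)$note, extra$note)
    ## write-read-write gives byte-identical files
    path2 <- file.path(dir, "study2.tsv")
    writeStudyTable(tb2, path2)
    expect_identical(readLines(path), readLines(path2))
    ## CSV dialect sniffed from extension
    pcsv <- file.path(dir, "study.csv")
    writeStudyTable(tb, pcsv)
    tb3 <- readStudyTable(pcsv, "Protein IDs", "rat")
    expect_identical(unname(idGroups(tb3)), unname(idGroups(tb)))
    expect_identical(extraColumns(tb3)$note, extra$note)
})

test_that("missing column and empty file give hard errors", {
    dir <- withr::local_tempdir()
    path <- file.path(dir, "s.tsv")
    writeLines(c("A\tB", "1\t2"), path)
    expect_error(readStudyTable(path, "Protein IDs", "rat"),
                 "available columns.*A, B")
    writeLines("A\tB", path)
    expect_error(readStudyTable(path, "A", "rat"), "empty")
})

test_that("output modes: add_column appends, replace keeps layout", {
    dir <- withr::local_tempdir()
    tb <- studyTable(c("P1;P2", "P3"), organism = "human",
                     extra = data.frame(v = c("1", "2"),
                                        stringsAsFactors = FALSE))
    ## drop P2 as a harmonization step would
    tb2 <- initialize(tb, ids = list("P1", "P3"))
    pr <- file.path(dir, "replace.tsv")
    pa <- file.path(dir, "add.tsv")
    writeStudyTable(tb2, pr, mode = "replace")
    writeStudyTable(tb2, pa, mode = "add_column")
    r <- utils::read.delim(pr, check.names = FALSE,
                           colClasses = "character")
    a <- utils::read.delim(pa, check.names = FALSE,
                           colClasses = "character")
    expect_identical(ncol(r), 2L)
    expect_identical(r[["Protein IDs"]], c("P1", "P3"))
    expect_identical(ncol(a), 3L)
    expect_identical(a[["Protein IDs"]], c("P1;P2", "P3"))  # untouched
    expect_identical(a[["Protein IDs_harmonized"]], c("P1", "P3"))
    expect_identical(a[["v"]], c("1", "2"))
})

test_that("mergeLogs concatenates with step labels and recountable sums", {
    empty <- mergeLogs(list())
    expect_s4_class(empty, "HarmonizationLog")
    expect_identical(nrow(overviewLog(empty)), 0L)

    fx <- ucFixture()
    f <- filterProteinIds(fx$proteinStudies$study3_rat, fx$provider,
                          modes = "organism_based",
                          targetOrganism = "rat")
    r <- remapGeneNames(f$table, fx$provider, mode = "uniprot_primary")
    log <- mergeLogs(list(filter = f, remap = r))
    ov <- overviewLog(log)
    expect_setequal(unique(ov$step), c("filter", "remap"))
    s <- logSummary(log)
    for (st in s$step)
        expect_identical(s$n_removed[s$step == st],
                         sum(ov$n_removed[ov$step == st]))
    ## serialization produces the two TSVs plus the JSON summary
    prefix <- file.path(withr::local_tempdir(), "run")
    paths <- writeLogs(log, prefix)
    expect_true(all(file.exists(paths)))
    js <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
    expect_identical(js$n_removed, s$n_removed)
})

test_that("row ids are stable and extras byte-identical through steps", {
    fx <- ucFixture()
    tb <- fx$proteinStudies$study1_human
    f <- filterProteinIds(tb, fx$provider,
                          modes = c("organism_based", "reviewed_based"),
                          targetOrganism = "human")
    expect_identical(rowIds(f$table), rowIds(tb))
    expect_identical(extraColumns(f$table), extraColumns(tb))
    r <- remapGeneNames(f$table, fx$provider, mode = "uniprot_primary")
    expect_true(all(rowIds(r$table) %in% rowIds(tb)))
    expect_identical(extraColumns(r$table),
                     extraColumns(tb)[match(rowIds(r$table), rowIds(tb)), ,
                                      drop = FALSE])
})
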