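test_that("UniProt FASTA headers parse accession and GN token", {
    h <- parseFastaHeader(
        ">sp|P12345|X_HUMAN some desc OS=Homo sapiens GN=ABC1 PE=1")
    expect_identical(h$accession, "P12345")
    expect_identical(h$gene, "ABC1")
    h2 <- parseFastaHeader(">tr|Q99999|Y_RAT desc OS=Rattus norvegicus")
    expect_identical(h2$accession, "Q99999")
    expect_true(is.na(h2$gene))
    ## GN= as last token, trailing newline: no whitespace leaks in
    h3 <- parseFastaHeader(">sp|P1|Z_HUMAN d GN=XYZ\n")
    expect_identical(h3$gene, "XYZ")
    ## non-UniProt grammar: accession absent
    h4 <- parseFastaHeader(">contig_17 length=3000")
    expect_true(is.na(h4$accession))
})

test_that("uniprot_one picks the most frequent primary name", {
    pv <- miniProvider(rbind(
        protRow("A1", primary = "A"), protRow("A2", primary = "A"),
        protRow("A3", primary = "B"), protRow("B1", primary = "B"),
        protRow("C1", primary = "C")))
    tb <- studyTable(list(c("A1", "A2", "A3")), organism = "human")
    res <- remapGeneNames(tb, pv, mode = "uniprot_one")
    expect_identical(unname(geneGroups(res$table)), list("A"))
    ## tie at 1-1: group order wins (B1 precedes C1)
    tb2 <- studyTable(list(c("B1", "C1")), organism = "human")
    expect_identical(
        unname(geneGroups(remapGeneNames(tb2, pv,
                                         mode = "uniprot_one")$table)),
        list("B"))
    ## singleton with a primary name maps to it under any UniProt mode
    tb3 <- studyTable(list("C1"), organism = "human")
    for (m in c("uniprot_primary", "uniprot_one"))
        expect_identical(
            unname(geneGroups(remapGeneNames(tb3, pv, mode = m)$table)),
            list("C"))
})

test_that("accessions without gene names drop their rows and are logged", {
    ## ten single-ID rows lacking any annotated gene name
    accs <- sprintf("N%03d", 1:10)
    pv <- miniProvider(rbind(
        do.call(rbind, lapply(accs, function(a) protRow(a, "rat"))),
        protRow("G1", "rat", primary = "Postn")),
        genes = geneRow("Postn", "rat", "ENSRNOG1", "Postn"))
    tb <- studyTable(as.list(c(accs, "G1")), organism = "rat")
    res <- remapGeneNames(tb, pv, mode = "uniprot_primary")
    expect_identical(nrow(res$table), 1L)
    dropped <- res$detail[res$detail$reason == "no_gene_name", ]
    expect_identical(sort(dropped$identifier), sort(accs))
    expect_identical(nrow(dropped), 10L)
    ## keepEmpty retains the rows with empty gene cells
    kept <- remapGeneNames(tb, pv, mode = "uniprot_primary",
                           keepEmpty = TRUE)
    expect_identical(nrow(kept$table), 11L)
    expect_identical(sum(lengths(geneGroups(kept$table)) == 0), 10L)
})

test_that("fasta mode reads GN tokens; all mode fills gaps from UniProt", {
    dir <- withr::local_tempdir()
    fasta <- file.path(dir, "ref.fasta")
    writeLines(c(
        ">sp|F1|A_HUMAN desc OS=Homo sapiens GN=FROMFASTA PE=1",
        "MAAAKKK",
        ">sp|F2|B_HUMAN desc OS=Homo sapiens",
        "MCCCDDD"), fasta)
    pv <- miniProvider(rbind(protRow("F1", primary = "FROMDB"),
                             protRow("F2", primary = "DBONLY")))
    tb <- studyTable(list("F1", "F2"), organism = "human")
    resF <- remapGeneNames(tb, pv, mode = "fasta", fastaPath = fasta,
                           keepEmpty = TRUE)
    expect_identical(unname(geneGroups(resF$table)),
                     list("FROMFASTA", character()))
    resA <- remapGeneNames(tb, pv, mode = "all", fastaPath = fasta)
    expect_identical(unname(geneGroups(resA$table)),
                     list("FROMFASTA", "DBONLY"))
    ## per row, mode=all is a superset of mode=fasta
    gf <- geneGroups(resF$table)
    ga <- geneGroups(resA$table)
    for (rid in names(gf))
        expect_true(all(gf[[rid]] %in% ga[[rid]]))
    expect_error(remapGeneNames(tb, pv, mode = "fasta"), "FASTA")
})

test_that("uniprot mode keeps only HGNC-listed names", {
    pv <- miniProvider(
        protRow("U1", primary = "MAIN", synonyms = "ALT1|ALT2"),
        genes = rbind(geneRow("MAIN", hgnc = TRUE),
                      geneRow("ALT1", hgnc = TRUE),
                      geneRow("ALT2", hgnc = FALSE)))
    tb <- studyTable(list("U1"), organism = "human")
    res <- remapGeneNames(tb, pv, mode = "uniprot")
    expect_identical(unname(geneGroups(res$table)),
                     list(c("MAIN", "ALT1")))
})

test_that("remapping is deterministic and overwrite is logged", {
    fx <- ucFixture()
    f <- filterProteinIds(fx$proteinStudies$study3_rat, fx$provider,
                          modes = "organism_based",
                          targetOrganism = "rat")
    r1 <- remapGeneNames(f$table, fx$provider, mode = "uniprot_primary")
    r2 <- remapGeneNames(f$table, fx$provider, mode = "uniprot_primary")
    expect_identical(r1, r2)
    expectLogInvariants(r1)
    ## n_added counts the newly filled gene cells
    expect_identical(sum(r1$overview$n_added > 0),
                     sum(lengths(geneGroups(r1$table)) > 0))
    ## skipFilled leaves already-populated cells untouched
    pre <- initialize(f$table,
        genes = replicate(nrow(f$table), "Existing", simplify = FALSE),
        geneColumn = "Gene names")
    rs <- remapGeneNames(pre, fx$provider, mode = "uniprot_primary",
                         skipFilled = TRUE)
    expect_true(all(vapply(geneGroups(rs$table),
                           identical, logical(1), "Existing")))
    ## default overwrites and logs the superseded names
    ro <- remapGeneNames(pre, fx$provider, mode = "uniprot_primary")
    expect_false(any(vapply(geneGroups(ro$table),
                            identical, logical(1), "Existing")))
    expect_true(all(ro$detail$reason %in%
                    c("no_gene_name", "not_in_namespace")))
    expectLogInvariants(ro)
})
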