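test_that("provider generation is deterministic and spec-faithful", {
    d1 <- file.path(withr::local_tempdir(), "p1")
    d2 <- file.path(withr::local_tempdir(), "p2")
    spec <- fixtureSpec(seed = 42)
    generateProviderTables(spec, d1)
    generateProviderTables(spec, d2)
    for (f in c("proteins.tsv", "genes.tsv", "orthologs.tsv",
                "manifest.json"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    ## zero obsolete fraction plants zero obsolete rows
    d3 <- file.path(withr::local_tempdir(), "p3")
    w0 <- generateProviderTables(fixtureSpec(seed = 1,
                                             fractionObsolete = 0), d3)
    expect_identical(sum(w0$proteins$obsolete), 0L)
    expect_length(w0$manifest$obsolete_accessions, 0L)
})

test_that("manifest counts equal direct file scans", {
    w <- randomWorld()
    dir <- file.path(tempdir(), "provider_seed11")
    p <- utils::read.delim(file.path(dir, "proteins.tsv"),
                           colClasses = "character")
    expect_identical(sort(w$manifest$obsolete_accessions),
                     sort(p$accession[p$obsolete == "1"]))
    expect_identical(sort(w$manifest$unreviewed_accessions),
                     sort(p$accession[p$obsolete == "0" &
                                      p$reviewed == "0"]))
    g <- utils::read.delim(file.path(dir, "genes.tsv"),
                           colClasses = "character")
    expect_identical(sort(w$manifest$genes_without_ensembl),
                     sort(g$symbol[g$ensembl_id == ""]))
    ## referential integrity: every non-empty primary gene name exists
    named <- p$primary_gene_name[p$primary_gene_name != ""]
    expect_true(all(paste(named, p$organism[p$primary_gene_name != ""])
                    %in% paste(g$symbol, g$organism)))
})

test_that("use-case fixture reproduces its construction oracle", {
    fx <- ucFixture()
    expect_s4_class(fx$provider, "AnnotationProvider")
    res <- harmonizeUseCase(fx)
    expect_identical(sort(intersectionGenes(res$before)$gene),
                     fx$expected$before)
    expect_identical(sort(intersectionGenes(res$after)$gene),
                     fx$expected$after)
    ## written form round-trips through the file-based readers
    dir <- withr::local_tempdir()
    generateUseCaseFixture(dir)
    pv <- loadProvider(file.path(dir, "provider"))
    expect_identical(pv@proteins$accession,
                     fx$provider@proteins$accession)
    s3 <- readStudyTable(file.path(dir, "study3_rat_proteins.tsv"),
                         "Protein IDs", "rat", studyId = "study3_rat")
    expect_identical(unname(idGroups(s3)),
                     unname(idGroups(fx$proteinStudies$study3_rat)))
})

test_that("network fixture plants a mandatory bridge with attached drugs", {
    nf <- netFixture(seed = 5)
    g <- ppiGraph(nf$network)
    ## removing the bridge disconnects the two seed cliques
    cut <- igraph::delete_vertices(g, nf$connector)
    memb <- igraph::components(cut)$membership
    expect_false(memb[["SEEDA01"]] == memb[["SEEDB01"]])
    ## drug multiplicity as specified
    dt <- drugTargets(nf$network)
    expect_identical(nrow(dt), length(nf$seeds) * 2L)
    ## zero drugs produce an empty ranking
    nf0 <- generateNetworkFixture(fixtureSpec(seed = 5,
                                              drugsPerGene = 0L))
    expect_identical(nrow(rankDrugs(nf0$network, nf0$seeds)), 0L)
    ## determinism
    nfa <- generateNetworkFixture(fixtureSpec(seed = 9))
    nfb <- generateNetworkFixture(fixtureSpec(seed = 9))
    expect_identical(igraph::as_edgelist(ppiGraph(nfa$network)),
                     igraph::as_edgelist(ppiGraph(nfb$network)))
    expect_identical(nfa$drugTargets, nfb$drugTargets)
})

test_that("invalid fixture fractions are rejected", {
    expect_error(fixtureSpec(fractionObsolete = 1.2), "\\[0, 1\\]")
})
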