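## Curated four-study micro-fixture: two human protein-group studies, one
## rat single-ID study (Proteome-Discoverer style) and one mouse gene-only
## study, with an annotation snapshot in which the well-known identifier
## behaviors of the bone-healing meta-analysis scenario hold exactly
## (B4DQ80/B7Z722 wrong-organism removal, Q63610/Tpm3 kept,
## Ppia -> Ppial4d and Serpina3n -> RGD1565462 Ensembl renames,
## Serpinc1 -> SERPINC1 ortholog, POSTN found in all four studies only
## after harmonization).

.ucGeneRow <- function(symbol, organism, eid, esym = symbol,
                       in_hgnc = organism == "human", in_mygene = TRUE,
                       has_annotation = TRUE) {
    if (!nzchar(eid)) esym <- ""
    data.frame(symbol = symbol, organism = organism, ensembl_id = eid,
               ensembl_symbol = esym, in_hgnc = in_hgnc,
               in_mygene = in_mygene, has_annotation = has_annotation,
               stringsAsFactors = FALSE)
}

.useCaseProvider <- function() {
    humanGenes <- c("POSTN", "COL1A1", "FN1", "ANXA1", "MMP2", "SPARC",
                    "VIM", "TPM3", "LUM", "BGN", "DCN", "THBS1",
                    "SERPINC1", "GAPDH", "HSPG2", "PGAM4")
    gh <- do.call(rbind, lapply(seq_along(humanGenes), function(i)
        .ucGeneRow(humanGenes[i], "human", sprintf("ENSG%011d", i))))
    ratSelf <- c("Tpm3", "Fn1", "Lum", "Serpinc1", "Gapdh", "Hspg2",
                 "Pgam1", "Postn")
    gr <- do.call(rbind, lapply(seq_along(ratSelf), function(i)
        .ucGeneRow(ratSelf[i], "rat", sprintf("ENSRNOG%011d", i))))
    gr <- rbind(gr,
        .ucGeneRow("Ppia", "rat", "ENSRNOG00000000101", "Ppial4d",
                   has_annotation = TRUE),
        .ucGeneRow("Ppial4d", "rat", "ENSRNOG00000000101",
                   has_annotation = FALSE),
        .ucGeneRow("Serpina3n", "rat", "ENSRNOG00000000102",
                   "RGD1565462", has_annotation = FALSE),
        .ucGeneRow("RGD1565462", "rat", "ENSRNOG00000000102",
                   has_annotation = TRUE))
    mouseSyms <- c("Postn", "Serpinc1", "Gapdh", "Col1a1", "Vim", "Dcn",
                   "Thbs1", "Ube2l6")
    gm <- do.call(rbind, lapply(seq_along(mouseSyms), function(i)
        .ucGeneRow(mouseSyms[i], "mouse", sprintf("ENSMUSG%011d", i))))
    gm <- rbind(gm, .ucGeneRow("Xkr4", "mouse", ""))  # no Ensembl entry
    genes <- rbind(gh, gr, gm)
    rownames(genes) <- NULL

    humanAcc <- sprintf("H%05d", 1:15)
    humanPrim <- c("POSTN", "POSTN", "COL1A1", "FN1", "FN1", "ANXA1",
                   "MMP2", "SPARC", "VIM", "TPM3", "COL1A1", "LUM",
                   "BGN", "DCN", "THBS1")
    ph <- data.frame(accession = humanAcc, organism = "human",
                     reviewed = TRUE, obsolete = FALSE,
                     primary_gene_name = humanPrim, synonyms = "",
                     stringsAsFactors = FALSE)
    ratAcc <- c("Q63610", sprintf("R%05d", 10001:10011))
    ratPrim <- c("Tpm3", "Fn1", "Lum", "Serpinc1", "Ppia", "Serpina3n",
                 "Gapdh", "Hspg2", "Pgam1", "Postn", "", "")
    pr <- data.frame(accession = ratAcc, organism = "rat",
                     reviewed = TRUE, obsolete = FALSE,
                     primary_gene_name = ratPrim, synonyms = "",
                     stringsAsFactors = FALSE)
    ## the two human accessions published in the rat study (unreviewed
    ## TrEMBL entries of tropomyosin 3)
    pt <- data.frame(accession = c("B4DQ80", "B7Z722"),
                     organism = "human", reviewed = FALSE,
                     obsolete = FALSE, primary_gene_name = "TPM3",
                     synonyms = "", stringsAsFactors = FALSE)
    proteins <- rbind(ph, pr, pt)

    orth <- function(srcEid, tgtSym) {
        i <- match(tgtSym, humanGenes)
        data.frame(source_ensembl_id = srcEid, source_organism = NA,
                   target_organism = "human",
                   target_ensembl_id = sprintf("ENSG%011d", i),
                   target_symbol = tgtSym, stringsAsFactors = FALSE)
    }
    ratPairs <- do.call(rbind, Map(orth,
        sprintf("ENSRNOG%011d", seq_along(ratSelf)),
        c("TPM3", "FN1", "LUM", "SERPINC1", "GAPDH", "HSPG2", "PGAM4",
          "POSTN")))
    ratPairs$source_organism <- "rat"
    mousePairs <- do.call(rbind, Map(orth,
        sprintf("ENSMUSG%011d", 1:7),
        c("POSTN", "SERPINC1", "GAPDH", "COL1A1", "VIM", "DCN",
          "THBS1")))
    mousePairs$source_organism <- "mouse"
    orthologs <- rbind(ratPairs, mousePairs)
    rownames(proteins) <- rownames(orthologs) <- NULL
    new("AnnotationProvider", proteins = proteins, genes = genes,
        orthologs = orthologs)
}

#' Generate the curated four-study use-case fixture
#'
#' A hand-built micro-fixture (8--14 rows per study) mirroring a
#' four-study bone-healing meta-analysis: two human studies with
#' MaxQuant-style protein groups, one rat study with single protein IDs
#' per row, and one mouse study providing gene symbols only.  The
#' annotation snapshot is curated so that the scenario's hallmark
#' identifier behaviors hold exactly; in particular, organism-based
#' filtering of the rat study removes exactly the two human accessions
#' \code{B4DQ80} and \code{B7Z722} while keeping \code{Q63610}, and the
#' bone-matrix gene \code{POSTN} intersects all four studies only after
#' full harmonization (filter, remap, Ensembl reduction, ortholog mapping
#' to human).
#'
#' @param dir optional directory; when given, the provider snapshot
#'   (subdirectory \code{provider/}) and the study tables (TSV) are
#'   written there.
#' @return list with components:
#'   \describe{
#'     \item{provider}{the curated \linkS4class{AnnotationProvider}.}
#'     \item{proteinStudies}{named list of the three protein-level
#'       \linkS4class{StudyTable}s (\code{schmidt2016}-, \code{schmidt2018}-
#'       and \code{calciolari2017}-like shapes).}
#'     \item{publishedGeneStudies}{named list of four gene-only
#'       \linkS4class{StudyTable}s as published (mixed organisms).}
#'     \item{expected}{list with the fixture-construction oracle: sorted
#'       gene sets \code{before} and \code{after} of the min-2-studies
#'       intersection, and the POSTN occurrence counts
#'       \code{postnBefore}/\code{postnAfter}.}
#'   }
#' @export
generateUseCaseFixture <- function(dir = NULL) {
    provider <- .useCaseProvider()
    s1 <- studyTable(
        list(c("H00001", "H00002"), "H00003", c("H00004", "H00005"),
             "H00006", "H00007", "H00008", "H00009", "H00010"),
        organism = "human", studyId = "study1_human",
        extra = data.frame(log2fc = sprintf("%.2f",
            seq(0.5, by = 0.25, length.out = 8)),
            stringsAsFactors = FALSE))
    s2 <- studyTable(
        list("H00001", c("H00003", "H00011"), "H00007", "H00008",
             "H00012", "H00013", "H00014", c("H00015", "CON__P00761")),
        organism = "human", studyId = "study2_human")
    s3 <- studyTable(
        as.list(c("Q63610", sprintf("R%05d", 10001:10011), "B4DQ80",
                  "B7Z722")),
        organism = "rat", studyId = "study3_rat")
    pubGenes <- list(
        study1_human = c("POSTN", "COL1A1", "FN1", "ANXA1", "MMP2",
                         "SPARC", "VIM", "TPM3"),
        study2_human = c("POSTN", "COL1A1", "MMP2", "SPARC", "LUM",
                         "BGN", "DCN", "THBS1"),
        study3_rat = c("TPM3", "FN1", "LUM", "Serpinc1", "Ppia",
                       "Serpina3n", "Gapdh", "Hspg2", "Pgam1", "Postn"),
        study4_mouse = c("Postn", "Serpinc1", "Gapdh", "Col1a1", "Vim",
                         "Dcn", "Thbs1", "Ube2l6", "Xkr4"))
    pubOrg <- c(study1_human = "human", study2_human = "human",
                study3_rat = "rat", study4_mouse = "mouse")
    published <- lapply(names(pubGenes), function(nm)
        studyTable(replicate(length(pubGenes[[nm]]), character(),
                             simplify = FALSE),
                   organism = pubOrg[[nm]], studyId = nm,
                   genes = as.list(pubGenes[[nm]]), idColumn = "",
                   geneColumn = "Gene names"))
    ## published gene-only tables: drop the empty protein column marker
    published <- lapply(published, function(tb)
        initialize(tb, idColumn = "", colOrder = "Gene names",
                   originalCells = data.frame(
                       `Gene names` = vapply(tb@genes, paste,
                           character(1), collapse = ";"),
                       check.names = FALSE, stringsAsFactors = FALSE)))
    names(published) <- names(pubGenes)
    expected <- list(
        before = sort(c("POSTN", "COL1A1", "MMP2", "SPARC", "FN1",
                        "TPM3", "LUM", "Serpinc1", "Gapdh", "Postn")),
        after = sort(c("POSTN", "COL1A1", "MMP2", "SPARC", "FN1", "TPM3",
                       "LUM", "VIM", "DCN", "THBS1", "SERPINC1",
                       "GAPDH")),
        postnBefore = 2L, postnAfter = 4L)
    out <- list(provider = provider,
                proteinStudies = list(study1_human = s1,
                                      study2_human = s2,
                                      study3_rat = s3),
                publishedGeneStudies = published,
                expected = expected)
    if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        .writeProviderDir(provider@proteins, provider@genes,
                          provider@orthologs, file.path(dir, "provider"))
        for (tb in out$proteinStudies)
            writeStudyTable(tb, file.path(dir,
                paste0(tb@studyId, "_proteins.tsv")))
        for (tb in out$publishedGeneStudies)
            writeStudyTable(tb, file.path(dir,
                paste0(tb@studyId, "_published_genes.tsv")))
    }
    out
}

#' Run the full harmonization over the use-case fixture
#'
#' Convenience wrapper used by the examples, tests and the acceptance
#' script: filters, remaps (primary names), reduces (Ensembl ground) and
#' ortholog-maps the three protein studies to human, maps the published
#' mouse gene list to human orthologs, and returns both intersections.
#'
#' @param fixture result of [generateUseCaseFixture()] (regenerated when
#'   missing).
#' @param minStudies intersection threshold (default 2).
#' @return list with \code{before} and \code{after}
#'   (\linkS4class{IntersectionResult}s), \code{harmonized} (named list of
#'   harmonized \linkS4class{StudyTable}s) and \code{log} (merged
#'   \linkS4class{HarmonizationLog} of the rat study's pipeline).
#' @export
harmonizeUseCase <- function(fixture = generateUseCaseFixture(),
                             minStudies = 2L) {
    pv <- fixture$provider
    harmonizeProtein <- function(tb) {
        f <- filterProteinIds(tb, pv,
            modes = c("organism_based", "reviewed_based", "decoy_based"))
        r <- remapGeneNames(f$table, pv, mode = "uniprot_primary")
        d <- reduceGeneNames(r$table, pv, ground = "ensembl")
        o <- mapOrthologs(d$table, pv, targetOrganism = "human")
        list(table = o$table,
             log = mergeLogs(list(filter = f, remap = r, reduce = d,
                                  orthologs = o)))
    }
    hp <- lapply(fixture$proteinStudies, harmonizeProtein)
    s4 <- mapOrthologs(fixture$publishedGeneStudies$study4_mouse, pv,
                       targetOrganism = "human")
    harmonized <- c(lapply(hp, `[[`, "table"), list(s4$table))
    names(harmonized) <- c(names(fixture$proteinStudies), "study4_mouse")
    beforeTables <- lapply(fixture$publishedGeneStudies, function(tb)
        initialize(tb, organism = "human"))  # compare published symbols as-is
    list(before = intersectStudies(unname(beforeTables), minStudies),
         after = intersectStudies(unname(harmonized), minStudies),
         harmonized = harmonized,
         log = hp$study3_rat$log)
}
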