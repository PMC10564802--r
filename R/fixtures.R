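## synthetic_fixtures: deterministic generators for provider snapshots,
## study tables and networks with known ground truth, so every pipeline
## stage is testable offline.  The curated use-case family reproduces the
## four-study bone-healing meta-analysis scenario at desk scale.

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old))
        assign(".Random.seed", old, envir = globalenv()))
    expr
}

#' Fixture specification
#'
#' Collects all knobs of the random generators.  Defaults emulate the
#' shapes of the four-study meta-analysis scenario (two human protein-group
#' studies, one rat single-ID study, one mouse gene-only study) and
#' annotation snapshots large enough to exercise every removal reason.
#'
#' @param seed RNG seed; same spec + seed gives byte-identical outputs.
#' @param organisms organisms covered by the snapshot.
#' @param nGenesPerOrganism gene records per organism.
#' @param nProteinsPerOrganism protein records per organism.
#' @param fractionObsolete fraction of protein records flagged obsolete.
#' @param fractionUnreviewed fraction of non-obsolete records without
#'   reviewed status.
#' @param fractionMissingGene fraction of records lacking a primary gene
#'   name.
#' @param fractionNoEnsembl fraction of gene records without an Ensembl
#'   id.
#' @param fractionRenamed fraction of Ensembl-covered genes whose
#'   Ensembl-listed symbol differs from the common symbol.
#' @param orthologCoverage fraction of non-human Ensembl-covered genes
#'   with a human ortholog pair.
#' @param fractionOneToMany fraction of ortholog sources with two human
#'   partners.
#' @param fractionForeign fraction of study-group members drawn from the
#'   wrong organism.
#' @param fractionContaminant,fractionDecoy fractions of study-group
#'   members decorated with \code{CON__} / \code{REV__} flags.
#' @param nRows default study size (rows).
#' @param maxGroupSize protein-group sizes are drawn uniformly from
#'   1..maxGroupSize (MaxQuant-like).
#' @param networkSize background protein count of the network fixture.
#' @param moduleSizes sizes of the two planted seed cliques.
#' @param drugsPerGene drugs attached per module gene.
#' @return a list of class \code{"fixtureSpec"}.
#' @export
fixtureSpec <- function(seed = 1L,
                        organisms = c("human", "rat", "mouse", "rabbit"),
                        nGenesPerOrganism = 120L,
                        nProteinsPerOrganism = 200L,
                        fractionObsolete = 0.05,
                        fractionUnreviewed = 0.05,
                        fractionMissingGene = 0.06,
                        fractionNoEnsembl = 0.08,
                        fractionRenamed = 0.10,
                        orthologCoverage = 0.93,
                        fractionOneToMany = 0.10,
                        fractionForeign = 0.05,
                        fractionContaminant = 0.02,
                        fractionDecoy = 0.02,
                        nRows = 50L,
                        maxGroupSize = 4L,
                        networkSize = 150L,
                        moduleSizes = c(5L, 5L),
                        drugsPerGene = 2L) {
    spec <- as.list(environment())
    fr <- unlist(spec[grep("^fraction|Coverage$", names(spec))])
    if (any(fr < 0 | fr > 1))
        stop("all fractions must lie in [0, 1]", call. = FALSE)
    spec$organisms <- vapply(spec$organisms, normalizeOrganism,
                             character(1), USE.NAMES = FALSE)
    class(spec) <- "fixtureSpec"
    spec
}

.symbolCase <- function(sym, org) {
    if (org == "human") toupper(sym)
    else paste0(toupper(substr(sym, 1, 1)), tolower(substr(sym, 2,
                                                           nchar(sym))))
}

#' Generate a synthetic annotation-provider snapshot
#'
#' Writes \code{proteins.tsv}, \code{genes.tsv} and \code{orthologs.tsv}
#' (plus a \code{manifest.json} with the planted ground truth) into a
#' directory.  The tables are internally consistent: every protein's gene
#' names exist in the gene table, every Ensembl-listed symbol is its own
#' fixed point (so reduction on the Ensembl ground is idempotent), and
#' ortholog pairs respect organisms.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the three data.frames, the manifest and
#'   the loaded \linkS4class{AnnotationProvider}.
#' @export
generateProviderTables <- function(spec = fixtureSpec(), dir) {
    stopifnot(inherits(spec, "fixtureSpec"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    .withSeed(spec$seed, {
        genes <- list()
        orth <- list()
        for (org in spec$organisms) {
            ng <- spec$nGenesPerOrganism
            base <- sprintf("gfx%03d", seq_len(ng))
            sym <- vapply(base, .symbolCase, character(1), org = org)
            hasEns <- stats::runif(ng) >= spec$fractionNoEnsembl
            pre <- c(human = "ENSG", rat = "ENSRNOG", mouse = "ENSMUSG",
                     rabbit = "ENSOCUG")[[org]]
            eid <- ifelse(hasEns, sprintf("%s%011d", pre, seq_len(ng)), "")
            renamed <- hasEns & stats::runif(ng) < spec$fractionRenamed
            esym <- ifelse(hasEns, ifelse(renamed,
                .symbolCase(paste0(base, "alt"), org), sym), "")
            g <- data.frame(symbol = sym, organism = org, ensembl_id = eid,
                            ensembl_symbol = esym,
                            in_hgnc = stats::runif(ng) < 0.9,
                            in_mygene = stats::runif(ng) < 0.9,
                            has_annotation = stats::runif(ng) < 0.85,
                            stringsAsFactors = FALSE)
            ## Ensembl-listed alternates are genes too, their own fixed
            ## points under the same Ensembl id.
            alt <- g[renamed, , drop = FALSE]
            if (nrow(alt)) {
                alt$symbol <- alt$ensembl_symbol
                alt$in_hgnc <- TRUE
                alt$in_mygene <- TRUE
                alt$has_annotation <- TRUE
                g <- rbind(g, alt)
            }
            genes[[org]] <- g
            if (org != "human") {
                src <- g[nzchar(g$ensembl_id), , drop = FALSE]
                src <- src[!duplicated(src$ensembl_id), , drop = FALSE]
                covered <- stats::runif(nrow(src)) < spec$orthologCoverage
                hsIdx <- sample.int(ng, nrow(src), replace = TRUE)
                many <- stats::runif(nrow(src)) < spec$fractionOneToMany
                hs <- sprintf("gfx%03d", hsIdx)
                for (k in which(covered)) {
                    tsym <- toupper(hs[k])
                    orth[[length(orth) + 1L]] <- data.frame(
                        source_ensembl_id = src$ensembl_id[k],
                        source_organism = org,
                        target_organism = "human",
                        target_ensembl_id = sprintf("ENSG%011d", hsIdx[k]),
                        target_symbol = tsym, stringsAsFactors = FALSE)
                    if (many[k]) {
                        j <- hsIdx[k] %% ng + 1L
                        orth[[length(orth) + 1L]] <- data.frame(
                            source_ensembl_id = src$ensembl_id[k],
                            source_organism = org,
                            target_organism = "human",
                            target_ensembl_id = sprintf("ENSG%011d", j),
                            target_symbol = toupper(sprintf("gfx%03d", j)),
                            stringsAsFactors = FALSE)
                    }
                }
            }
        }
        genesDf <- do.call(rbind, genes)
        genesDf <- genesDf[!duplicated(paste(genesDf$symbol,
                                             genesDf$organism)), ,
                           drop = FALSE]
        orthDf <- if (length(orth)) unique(do.call(rbind, orth))
            else data.frame(source_ensembl_id = character(),
                            source_organism = character(),
                            target_organism = character(),
                            target_ensembl_id = character(),
                            target_symbol = character(),
                            stringsAsFactors = FALSE)
        prot <- list()
        for (org in spec$organisms) {
            np <- spec$nProteinsPerOrganism
            pre <- c(human = "HU", rat = "RT", mouse = "MS",
                     rabbit = "RB")[[org]]
            acc <- sprintf("X%s%05d", pre, seq_len(np))
            obsolete <- stats::runif(np) < spec$fractionObsolete
            reviewed <- !obsolete & stats::runif(np) >= spec$fractionUnreviewed
            orgSyms <- genes[[org]]$symbol
            primary <- sample(orgSyms, np, replace = TRUE)
            primary[obsolete] <- ""
            primary[!obsolete & stats::runif(np) < spec$fractionMissingGene] <- ""
            nsyn <- ifelse(obsolete, 0L, stats::rbinom(np, 2L, 0.2))
            syn <- vapply(seq_len(np), function(i) {
                if (nsyn[i] == 0L) return("")
                paste(sample(orgSyms, nsyn[i]), collapse = "|")
            }, character(1))
            prot[[org]] <- data.frame(accession = acc, organism = org,
                                      reviewed = reviewed,
                                      obsolete = obsolete,
                                      primary_gene_name = primary,
                                      synonyms = syn,
                                      stringsAsFactors = FALSE)
        }
        protDf <- do.call(rbind, prot)
        rownames(protDf) <- rownames(genesDf) <- rownames(orthDf) <- NULL
        .writeProviderDir(protDf, genesDf, orthDf, dir)
        manifest <- list(
            seed = spec$seed,
            n_proteins = nrow(protDf),
            n_genes = nrow(genesDf),
            n_ortholog_pairs = nrow(orthDf),
            obsolete_accessions = protDf$accession[protDf$obsolete],
            unreviewed_accessions =
                protDf$accession[!protDf$obsolete & !protDf$reviewed],
            accessions_without_gene =
                protDf$accession[!protDf$obsolete &
                                 !nzchar(protDf$primary_gene_name)],
            genes_without_ensembl =
                genesDf$symbol[!nzchar(genesDf$ensembl_id)],
            renamed_genes = genesDf$symbol[
                nzchar(genesDf$ensembl_id) &
                genesDf$symbol != genesDf$ensembl_symbol])
        jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        invisible(list(proteins = protDf, genes = genesDf,
                       orthologs = orthDf, manifest = manifest,
                       provider = loadProvider(dir)))
    })
}

.fmtFlag <- function(x) ifelse(x, "1", "0")

.writeProviderDir <- function(proteins, genes, orthologs, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- proteins
    p$reviewed <- .fmtFlag(p$reviewed)
    p$obsolete <- .fmtFlag(p$obsolete)
    utils::write.table(p, file.path(dir, "proteins.tsv"), sep = "\t",
                       quote = TRUE, row.names = FALSE)
    g <- genes
    for (cl in c("in_hgnc", "in_mygene", "has_annotation"))
        g[[cl]] <- .fmtFlag(g[[cl]])
    utils::write.table(g, file.path(dir, "genes.tsv"), sep = "\t",
                       quote = TRUE, row.names = FALSE)
    utils::write.table(orthologs, file.path(dir, "orthologs.tsv"),
                       sep = "\t", quote = TRUE, row.names = FALSE)
    invisible(dir)
}

#' Sample a random protein study table against a provider snapshot
#'
#' Draws MaxQuant-like protein groups from a snapshot: most members from
#' the study organism, a fraction from foreign organisms, and a fraction
#' decorated with contaminant/decoy flags.  Used by the property tests;
#' the provider's manifest gives the matching ground truth.
#'
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param organism study organism.
#' @param nRows number of rows.
#' @param maxGroupSize group sizes drawn uniformly from 1..maxGroupSize.
#' @param fractionForeign,fractionContaminant,fractionDecoy see
#'   [fixtureSpec()].
#' @param rngSeed RNG seed.
#' @param studyId study label.
#' @return a \linkS4class{StudyTable} with one extra column
#'   (\code{intensity}).
#' @export
sampleStudyTable <- function(provider, organism, nRows = 50L,
                             maxGroupSize = 4L, fractionForeign = 0.05,
                             fractionContaminant = 0.02,
                             fractionDecoy = 0.02, rngSeed = 1L,
                             studyId = "random_study") {
    stopifnot(is(provider, "AnnotationProvider"))
    org <- normalizeOrganism(organism)
    .withSeed(rngSeed, {
        p <- provider@proteins
        own <- p$accession[p$organism == org]
        foreign <- p$accession[p$organism != org]
        ids <- lapply(seq_len(nRows), function(i) {
            k <- sample.int(maxGroupSize, 1L)
            grp <- vapply(seq_len(k), function(j) {
                a <- if (length(foreign) &&
                         stats::runif(1) < fractionForeign)
                    sample(foreign, 1L) else sample(own, 1L)
                u <- stats::runif(1)
                if (u < fractionDecoy) paste0("REV__", a)
                else if (u < fractionDecoy + fractionContaminant)
                    paste0("CON__", a)
                else a
            }, character(1))
            grp
        })
        extra <- data.frame(
            intensity = sprintf("%.1f", stats::runif(nRows, 1e5, 1e8)),
            stringsAsFactors = FALSE)
        studyTable(ids, organism = org, studyId = studyId, extra = extra)
    })
}

#' Generate the planted-module network fixture
#'
#' Builds a PPI network with two seed cliques that are connected to each
#' other only through one planted bridge protein, plus background proteins
#' attached strictly within their side of the bridge; any tree spanning
#' seeds of both cliques must therefore pass through the bridge, giving a
#' known ground-truth connector.  Drugs are attached to module genes with
#' known target multiplicity.
#'
#' @param spec a [fixtureSpec()] (fields networkSize, moduleSizes,
#'   drugsPerGene, seed).
#' @param dir optional output directory; when given, \code{ppi.tsv},
#'   \code{drug_targets.tsv}, \code{seeds.txt} and
#'   \code{ground_truth.json} are written.
#' @return list with \code{network} (a \linkS4class{MechanismNetwork}),
#'   \code{seeds}, \code{connector} (the planted bridge) and
#'   \code{drugTargets}.
#' @export
generateNetworkFixture <- function(spec = fixtureSpec(), dir = NULL) {
    stopifnot(inherits(spec, "fixtureSpec"))
    .withSeed(spec$seed + 7L, {
        sizes <- spec$moduleSizes
        cliqueA <- sprintf("SEEDA%02d", seq_len(sizes[1]))
        cliqueB <- sprintf("SEEDB%02d", seq_len(sizes[2]))
        bridge <- "BRIDGE01"
        edges <- list()
        addE <- function(a, b) edges[[length(edges) + 1L]] <<- c(a, b)
        for (cl in list(cliqueA, cliqueB))
            for (i in seq_along(cl)) for (j in seq_len(i - 1L))
                addE(cl[i], cl[j])
        addE(bridge, cliqueA[1])
        addE(bridge, cliqueB[1])
        nbg <- spec$networkSize
        half <- nbg %/% 2L
        bgA <- sprintf("PROTA%03d", seq_len(half))
        bgB <- sprintf("PROTB%03d", seq_len(nbg - half))
        attach_side <- function(bg, clique) {
            for (i in seq_along(bg)) {
                anchors <- c(clique, bg[seq_len(i - 1L)])
                k <- min(length(anchors), sample.int(3L, 1L))
                for (a in sample(anchors, k)) addE(bg[i], a)
            }
        }
        attach_side(bgA, cliqueA)
        attach_side(bgB, cliqueB)
        em <- do.call(rbind, edges)
        ppi <- data.frame(node_a = em[, 1], node_b = em[, 2],
                          weight = "1", stringsAsFactors = FALSE)
        seeds <- c(cliqueA, cliqueB)
        emptyDt <- data.frame(drug = character(), protein = character(),
                              approved = character(),
                              stringsAsFactors = FALSE)
        dt <- if (spec$drugsPerGene < 1L) emptyDt
        else do.call(rbind, lapply(seeds, function(s) {
            data.frame(drug = sprintf("DRUG_%s_%d", s,
                                      seq_len(spec$drugsPerGene)),
                       protein = s,
                       approved = .fmtFlag(stats::runif(
                           spec$drugsPerGene) < 0.8),
                       stringsAsFactors = FALSE)
        }))
        if (!is.null(dir)) {
            dir.create(dir, showWarnings = FALSE, recursive = TRUE)
            utils::write.table(ppi, file.path(dir, "ppi.tsv"), sep = "\t",
                               quote = TRUE, row.names = FALSE)
            utils::write.table(dt, file.path(dir, "drug_targets.tsv"),
                               sep = "\t", quote = TRUE, row.names = FALSE)
            writeLines(seeds, file.path(dir, "seeds.txt"))
            jsonlite::write_json(
                list(connector = bridge, seeds = seeds,
                     clique_a = cliqueA, clique_b = cliqueB),
                file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
        }
        list(network = mechanismNetwork(ppi, dt, seeds), seeds = seeds,
             connector = bridge, drugTargets = dt)
    })
}
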