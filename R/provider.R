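## annotation_provider: offline snapshot lookups (proteins, genes, orthologs).
## All knowledge the pipeline needs about identifiers flows through this
## contract; no stage contacts a web service.

.providerFiles <- c("proteins.tsv", "genes.tsv", "orthologs.tsv")

.readProviderTable <- function(path, required, logical_cols) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "\"",
                            colClasses = "character", check.names = FALSE,
                            comment.char = "", na.strings = NULL,
                            stringsAsFactors = FALSE)
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop("provider table '", basename(path), "' lacks column(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
    for (cl in logical_cols) {
        bad <- !df[[cl]] %in% c("0", "1")
        if (any(bad))
            stop("provider table '", basename(path), "', line ",
                 which(bad)[1] + 1L, ": column '", cl,
                 "' must be 0 or 1", call. = FALSE)
        df[[cl]] <- df[[cl]] == "1"
    }
    df
}

#' Load a local annotation provider
#'
#' Reads the three snapshot tables \code{proteins.tsv}, \code{genes.tsv}
#' and \code{orthologs.tsv} from a directory and validates them against the
#' provider invariants (unique accessions, Ensembl symbol present iff
#' Ensembl id present, ortholog pairs crossing organisms).  The snapshot
#' freezes one release of the underlying databases so that every pipeline
#' run is reproducible offline.
#'
#' File formats (tab-separated, header row):
#' \itemize{
#'   \item proteins.tsv: accession, organism, reviewed (0/1), obsolete
#'     (0/1), primary_gene_name (may be empty), synonyms ("|"-joined).
#'   \item genes.tsv: symbol, organism, ensembl_id, ensembl_symbol,
#'     in_hgnc (0/1), in_mygene (0/1), has_annotation (0/1).
#'   \item orthologs.tsv: source_ensembl_id, source_organism,
#'     target_organism, target_ensembl_id, target_symbol.
#' }
#'
#' @param directory path containing the three TSV files.
#' @return an \linkS4class{AnnotationProvider}.
#' @export
loadProvider <- function(directory) {
    for (f in .providerFiles)
        if (!file.exists(file.path(directory, f)))
            stop("provider directory '", directory, "' is missing '", f,
                 "'", call. = FALSE)
    proteins <- .readProviderTable(file.path(directory, "proteins.tsv"),
        c("accession", "organism", "reviewed", "obsolete",
          "primary_gene_name", "synonyms"), c("reviewed", "obsolete"))
    genes <- .readProviderTable(file.path(directory, "genes.tsv"),
        c("symbol", "organism", "ensembl_id", "ensembl_symbol", "in_hgnc",
          "in_mygene", "has_annotation"),
        c("in_hgnc", "in_mygene", "has_annotation"))
    orth <- .readProviderTable(file.path(directory, "orthologs.tsv"),
        c("source_ensembl_id", "source_organism", "target_organism",
          "target_ensembl_id", "target_symbol"), character())
    if (anyDuplicated(proteins$accession)) {
        d <- proteins$accession[duplicated(proteins$accession)][1]
        stop("proteins.tsv: duplicate accession '", d, "'", call. = FALSE)
    }
    new("AnnotationProvider", proteins = proteins, genes = genes,
        orthologs = orth)
}

setMethod("show", "AnnotationProvider", function(object) {
    cat("AnnotationProvider:", nrow(object@proteins), "protein records,",
        nrow(object@genes), "gene records,", nrow(object@orthologs),
        "ortholog pairs\n")
})

#' Look up protein records
#'
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param accessions character vector of UniProt-style accessions.
#' @return named list mapping each known accession to a record list with
#'   fields \code{accession}, \code{organism}, \code{reviewed},
#'   \code{obsolete}, \code{primary_gene_name} (\code{NA} if absent) and
#'   \code{gene_name_synonyms} (character vector).  Accessions unknown to
#'   the snapshot are absent from the result; absence is data, not an
#'   error.
#' @export
lookupProteins <- function(provider, accessions) {
    stopifnot(is(provider, "AnnotationProvider"))
    accessions <- unique(accessions)
    hit <- match(accessions, provider@proteins$accession)
    found <- which(!is.na(hit))
    out <- vector("list", length(found))
    names(out) <- accessions[found]
    for (k in seq_along(found)) {
        r <- provider@proteins[hit[found[k]], ]
        out[[k]] <- list(
            accession = r$accession,
            organism = r$organism,
            reviewed = r$reviewed,
            obsolete = r$obsolete,
            primary_gene_name = if (nzchar(r$primary_gene_name))
                r$primary_gene_name else NA_character_,
            gene_name_synonyms = if (nzchar(r$synonyms))
                strsplit(r$synonyms, "|", fixed = TRUE)[[1L]]
                else character())
    }
    out
}

#' Look up gene records
#'
#' Symbol matching is exact-string and case-sensitive; \code{"postn"} and
#' \code{"POSTN"} are different symbols (organism-specific capitalization
#' conventions are meaningful).
#'
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param symbols character vector of gene symbols.
#' @param organism organism code the symbols belong to.
#' @return named list mapping each known symbol to a record list with
#'   fields \code{symbol}, \code{organism}, \code{ensembl_id},
#'   \code{ensembl_symbol} (both \code{NA} when the gene has no Ensembl
#'   entry), \code{in_hgnc}, \code{in_mygene},
#'   \code{has_functional_annotation}.  Unknown symbols are absent.
#' @export
lookupGenes <- function(provider, symbols, organism) {
    stopifnot(is(provider, "AnnotationProvider"))
    org <- normalizeOrganism(organism)
    symbols <- unique(symbols)
    g <- provider@genes
    key <- paste(g$symbol, g$organism)
    hit <- match(paste(symbols, org), key)
    found <- which(!is.na(hit))
    out <- vector("list", length(found))
    names(out) <- symbols[found]
    for (k in seq_along(found)) {
        r <- g[hit[found[k]], ]
        out[[k]] <- list(
            symbol = r$symbol, organism = r$organism,
            ensembl_id = if (nzchar(r$ensembl_id)) r$ensembl_id
                         else NA_character_,
            ensembl_symbol = if (nzchar(r$ensembl_symbol)) r$ensembl_symbol
                             else NA_character_,
            in_hgnc = r$in_hgnc, in_mygene = r$in_mygene,
            has_functional_annotation = r$has_annotation)
    }
    out
}

#' Look up orthologs for gene symbols
#'
#' Two-step mapping: each source symbol is first converted to its Ensembl
#' gene identifier, then ortholog pairs from the snapshot are followed to
#' the target organism.  A symbol without an Ensembl id, or whose Ensembl
#' id has no pair into the target organism, maps to an empty vector.
#'
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param symbols character vector of gene symbols.
#' @param sourceOrganism,targetOrganism organism codes (both must be
#'   supported).
#' @return named list mapping every input symbol to a character vector of
#'   target-organism symbols (possibly empty, possibly several).
#' @export
lookupOrthologs <- function(provider, symbols, sourceOrganism,
                            targetOrganism) {
    stopifnot(is(provider, "AnnotationProvider"))
    src <- normalizeOrganism(sourceOrganism)
    tgt <- normalizeOrganism(targetOrganism)
    symbols <- unique(symbols)
    out <- replicate(length(symbols), character(), simplify = FALSE)
    names(out) <- symbols
    recs <- lookupGenes(provider, symbols, src)
    o <- provider@orthologs
    o <- o[o$source_organism == src & o$target_organism == tgt, ,
           drop = FALSE]
    for (s in names(recs)) {
        eid <- recs[[s]]$ensembl_id
        if (is.na(eid)) next
        out[[s]] <- unique(o$target_symbol[o$source_ensembl_id == eid])
    }
    out
}
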