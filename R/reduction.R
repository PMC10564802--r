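## reduction: collapse synonym-laden gene cells to a single canonical
## namespace, preventing undetected overlaps between studies.

.REDUCE_GROUNDS <- c("ensembl", "hgnc", "mygeneinfo", "enrichment")

#' Reduce gene names to a canonical namespace
#'
#' Per gene cell, keeps only the names that exist in the chosen namespace
#' and, for the Ensembl ground, rewrites each survivor to the symbol the
#' Ensembl database lists for it:
#' \describe{
#'   \item{ensembl}{keep names with an Ensembl gene id; replace each by its
#'     Ensembl-listed symbol.  Idempotent: Ensembl symbols are their own
#'     fixed points.}
#'   \item{hgnc}{keep names with an HGNC entry (human only).}
#'   \item{mygeneinfo}{keep names with a MyGene.info entry.}
#'   \item{enrichment}{keep names carrying a functional annotation.}
#' }
#' Names that fall out of the namespace (or are rewritten) are logged with
#' reason \code{not_in_namespace}; for rewrites, the metadata names the
#' replacement symbol.  Two synonyms collapsing onto one canonical symbol
#' yield a single name.  Cells that empty out drop their row unless
#' \code{keepEmpty}.
#'
#' @param table a \linkS4class{StudyTable} with a populated gene column.
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param ground one of \code{"ensembl"}, \code{"hgnc"},
#'   \code{"mygeneinfo"}, \code{"enrichment"}.
#' @param keepEmpty keep rows whose gene cell empties out.
#' @return list(table, overview, detail) as in [filterProteinIds()].
#' @export
reduceGeneNames <- function(table, provider,
                            ground = c("ensembl", "hgnc", "mygeneinfo",
                                       "enrichment"),
                            keepEmpty = FALSE) {
    stopifnot(is(table, "StudyTable"), is(provider, "AnnotationProvider"))
    ground <- match.arg(ground)
    if (!length(table@genes))
        stop("gene-name reduction requires a populated gene column ",
             "(run remapGeneNames first)", call. = FALSE)
    if (ground == "hgnc" && table@organism != "human")
        stop("the HGNC ground is only available for human studies; study '",
             table@studyId, "' is ", table@organism, call. = FALSE)
    allSym <- unique(unlist(table@genes, use.names = FALSE))
    recs <- lookupGenes(provider, allSym, table@organism)
    canonical <- function(sym) {
        r <- recs[[sym]]
        if (is.null(r)) return(NA_character_)
        switch(ground,
            ensembl = if (is.na(r$ensembl_id)) NA_character_
                      else r$ensembl_symbol,
            hgnc = if (isTRUE(r$in_hgnc)) sym else NA_character_,
            mygeneinfo = if (isTRUE(r$in_mygene)) sym else NA_character_,
            enrichment = if (isTRUE(r$has_functional_annotation)) sym
                         else NA_character_)
    }
    sep <- table@sep
    n <- length(table@rowIds)
    newGenes <- table@genes
    ov <- vector("list", n)
    dt <- vector("list", n)
    for (i in seq_len(n)) {
        cell <- table@genes[[i]]
        repl <- vapply(cell, canonical, character(1), USE.NAMES = FALSE)
        surv <- !is.na(repl)
        newCell <- unique(repl[surv])
        newGenes[[i]] <- newCell
        ## a name "remains" only if it survives under its own symbol
        kept <- cell[surv & repl == cell]
        removed <- cell[!(surv & repl == cell)]
        added <- setdiff(newCell, cell)
        ov[[i]] <- .overviewRow(table@rowIds[i], cell, kept, removed, added,
                                sep)
        if (length(removed)) {
            ur <- !duplicated(removed)
            meta <- vapply(removed[ur], function(s) {
                r <- repl[match(s, cell)]
                if (is.na(r)) paste0("no entry in ground=", ground)
                else paste0("replaced_by=", r)
            }, character(1), USE.NAMES = FALSE)
            dt[[i]] <- .detailRows(table@rowIds[i], removed[ur],
                                   "not_in_namespace", meta)
        }
    }
    overview <- do.call(rbind, ov)
    detail <- do.call(rbind, c(dt, list(.emptyDetail())))
    rownames(overview) <- rownames(detail) <- NULL
    out <- initialize(table, genes = newGenes)
    if (!keepEmpty)
        out <- .subsetRows(out, lengths(newGenes) > 0L)
    list(table = out, overview = overview, detail = detail)
}
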