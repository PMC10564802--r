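## orthologs: translate gene symbols between organisms through Ensembl
## gene identifiers (two-step mapping: symbol -> Ensembl id -> pairs).

#' Map gene names to orthologs of a target organism
#'
#' Replaces every gene symbol by the symbol(s) of its orthologous gene(s)
#' in the target organism.  The mapping runs in two steps: symbols are
#' first converted to Ensembl gene identifiers, then ortholog pairs are
#' followed to the target organism.  One-to-many orthology expands a symbol
#' to all its partners; many-to-one collisions are deduplicated within a
#' cell.  A row survives if at least one member has an ortholog partner;
#' members without one are removed and logged with reason
#' \code{no_ortholog}.  The result table carries the target organism.
#'
#' When source and target organism coincide the table is returned
#' unchanged with empty logs (identity pass-through).
#'
#' @param table a \linkS4class{StudyTable} with a populated gene column;
#'   its organism is the source organism.
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param targetOrganism supported organism code to map into.
#' @param keepEmpty keep rows in which no member has an ortholog.
#' @return list(table, overview, detail) as in [filterProteinIds()].
#' @export
mapOrthologs <- function(table, provider, targetOrganism,
                         keepEmpty = FALSE) {
    stopifnot(is(table, "StudyTable"), is(provider, "AnnotationProvider"))
    tgt <- normalizeOrganism(targetOrganism)
    src <- table@organism
    if (!length(table@genes))
        stop("ortholog mapping requires a populated gene column ",
             "(run remapGeneNames first)", call. = FALSE)
    if (src == tgt)
        return(list(table = table, overview = .emptyOverview(),
                    detail = .emptyDetail()))
    allSym <- unique(unlist(table@genes, use.names = FALSE))
    omap <- lookupOrthologs(provider, allSym, src, tgt)
    sep <- table@sep
    n <- length(table@rowIds)
    newGenes <- table@genes
    ov <- vector("list", n)
    dt <- vector("list", n)
    for (i in seq_len(n)) {
        cell <- table@genes[[i]]
        partners <- lapply(cell, function(s) omap[[s]])
        hasPartner <- lengths(partners) > 0L
        newCell <- unique(unlist(partners, use.names = FALSE))
        if (is.null(newCell)) newCell <- character()
        newGenes[[i]] <- newCell
        kept <- cell[hasPartner]
        removed <- cell[!hasPartner]
        added <- setdiff(newCell, cell)
        ov[[i]] <- .overviewRow(table@rowIds[i], cell, kept, removed, added,
                                sep)
        if (length(removed)) {
            ur <- unique(removed)
            dt[[i]] <- .detailRows(table@rowIds[i], ur, "no_ortholog",
                paste0("no ", tgt, " ortholog in snapshot"))
        }
    }
    overview <- do.call(rbind, ov)
    detail <- do.call(rbind, c(dt, list(.emptyDetail())))
    rownames(overview) <- rownames(detail) <- NULL
    out <- initialize(table, genes = newGenes, organism = tgt)
    if (!keepEmpty)
        out <- .subsetRows(out, lengths(newGenes) > 0L)
    list(table = out, overview = overview, detail = detail)
}
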