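## remapping: attach gene names to protein groups (five modes, FASTA
## header support).

.REMAP_MODES <- c("uniprot", "uniprot_primary", "uniprot_one", "fasta",
                  "all")

#' Parse a UniProt-dialect FASTA header line
#'
#' Understands the standard UniProt grammar
#' \code{>db|ACCESSION|ENTRY description OS=... GN=SYMBOL PE=...}; the
#' \code{GN=} token is optional.
#'
#' @param headerLine one header line (with or without the leading
#'   \code{">"}).
#' @return list with \code{accession} (\code{NA} when the header does not
#'   follow the three-field UniProt grammar) and \code{gene} (\code{NA}
#'   when no \code{GN=} token is present).
#' @examples
#' parseFastaHeader(">sp|P12345|X_HUMAN desc OS=Homo sapiens GN=ABC1 PE=1")
#' @export
parseFastaHeader <- function(headerLine) {
    h <- sub("^>", "", headerLine)
    h <- sub("[\r\n]+$", "", h)
    first <- strsplit(h, "[[:space:]]+")[[1L]][1L]
    acc <- NA_character_
    if (!is.na(first) && grepl("^[^|]+\\|[^|]+\\|[^|]+$", first))
        acc <- strsplit(first, "|", fixed = TRUE)[[1L]][2L]
    gene <- NA_character_
    m <- regmatches(h, regexpr("(?:^|[[:space:]])GN=[^[:space:]]+", h))
    if (length(m))
        gene <- sub("^[[:space:]]*GN=", "", m)
    list(accession = acc, gene = gene)
}

## accession -> gene-name map from a FASTA file; unparseable headers are
## returned in attr "unparsed" so callers can log them.
.readFastaGeneMap <- function(fastaPath) {
    if (is.null(fastaPath) || !file.exists(fastaPath))
        stop("FASTA file required but not found: ",
             if (is.null(fastaPath)) "(none given)" else fastaPath,
             call. = FALSE)
    headers <- names(Biostrings::readAAStringSet(fastaPath))
    parsed <- lapply(headers, parseFastaHeader)
    acc <- vapply(parsed, `[[`, character(1), "accession")
    gene <- vapply(parsed, `[[`, character(1), "gene")
    ok <- !is.na(acc) & !is.na(gene)
    map <- gene[ok]
    names(map) <- acc[ok]
    map <- map[!duplicated(names(map))]
    attr(map, "unparsed") <- headers[is.na(acc)]
    map
}

## Most frequent primary name across a group; ties broken by first
## occurrence in group order, then lexicographically.
.mostFrequentName <- function(namesInGroupOrder) {
    if (!length(namesInGroupOrder))
        return(character())
    lv <- unique(namesInGroupOrder)
    cnt <- vapply(lv, function(x) sum(namesInGroupOrder == x), integer(1))
    best <- lv[cnt == max(cnt)]
    first <- vapply(best, function(x) match(x, namesInGroupOrder),
                    integer(1))
    best <- best[order(first, best)]
    best[1L]
}

#' Re-map protein groups to gene names
#'
#' Fills (or rewrites) the gene-name column of a study table from its
#' protein IDs.  Modes:
#' \describe{
#'   \item{uniprot}{all annotated names (primary plus synonyms) of each
#'     accession that are listed in HGNC (snapshot flag \code{in_hgnc}).}
#'   \item{uniprot_primary}{primary gene names only.}
#'   \item{uniprot_one}{the single most frequent primary name across the
#'     group (ties broken by group order, then lexicographically).}
#'   \item{fasta}{names extracted from \code{GN=} tokens of the supplied
#'     FASTA headers.}
#'   \item{all}{FASTA names first, gaps filled with UniProt primary
#'     names.}
#' }
#' By default existing gene cells are overwritten so that every name stems
#' from the same snapshot; \code{skipFilled = TRUE} leaves nonempty cells
#' untouched.  Rows that end up with no gene name are dropped unless
#' \code{keepEmpty}; the affected accessions are logged with reason
#' \code{no_gene_name}.
#'
#' @param table a \linkS4class{StudyTable} with protein accessions.
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param mode one of \code{"uniprot"}, \code{"uniprot_primary"},
#'   \code{"uniprot_one"}, \code{"fasta"}, \code{"all"}.
#' @param fastaPath FASTA file path; required for modes \code{fasta} and
#'   \code{all}.
#' @param keepEmpty keep rows without any resulting gene name.
#' @param skipFilled leave rows whose gene cell is already populated
#'   untouched.
#' @return list(table, overview, detail) as in [filterProteinIds()].
#' @export
remapGeneNames <- function(table, provider,
                           mode = c("uniprot_primary", "uniprot",
                                    "uniprot_one", "fasta", "all"),
                           fastaPath = NULL, keepEmpty = FALSE,
                           skipFilled = FALSE) {
    stopifnot(is(table, "StudyTable"), is(provider, "AnnotationProvider"))
    mode <- match.arg(mode)
    if (!nzchar(table@idColumn) || !length(table@ids))
        stop("gene-name remapping requires a protein-ID column; study '",
             table@studyId, "' provides gene IDs only", call. = FALSE)
    fastaMap <- if (mode %in% c("fasta", "all"))
        .readFastaGeneMap(fastaPath) else NULL
    allAcc <- unique(unlist(table@ids, use.names = FALSE))
    records <- lookupProteins(provider, allAcc)
    ## candidate names per accession under the chosen mode
    namesFor <- function(acc) {
        rec <- records[[acc]]
        primary <- if (!is.null(rec) && !is.na(rec$primary_gene_name))
            rec$primary_gene_name else character()
        switch(mode,
            uniprot_primary = primary,
            uniprot_one = primary,
            uniprot = {
                cand <- unique(c(primary,
                                 if (!is.null(rec)) rec$gene_name_synonyms))
                if (!length(cand)) return(character())
                recs <- lookupGenes(provider, cand, table@organism)
                cand[vapply(cand, function(s)
                    !is.null(recs[[s]]) && isTRUE(recs[[s]]$in_hgnc),
                    logical(1))]
            },
            fasta = {
                g <- fastaMap[acc]
                if (is.na(g)) character() else unname(g)
            },
            all = {
                g <- fastaMap[acc]
                if (!is.na(g)) unname(g) else primary
            })
    }
    sep <- table@sep
    n <- length(table@rowIds)
    oldGenes <- if (length(table@genes)) table@genes
                else replicate(n, character(), simplify = FALSE)
    newGenes <- oldGenes
    ov <- vector("list", n)
    dt <- vector("list", n)
    for (i in seq_len(n)) {
        old <- oldGenes[[i]]
        if (skipFilled && length(old)) {
            ov[[i]] <- .overviewRow(table@rowIds[i], old, old, character(),
                                    character(), sep)
            next
        }
        grp <- table@ids[[i]]
        perAcc <- lapply(grp, namesFor)
        cell <- if (mode == "uniprot_one")
            .mostFrequentName(unlist(perAcc, use.names = FALSE))
        else unique(unlist(perAcc, use.names = FALSE))
        newGenes[[i]] <- cell
        inNew <- old %in% cell
        kept <- old[inNew]
        removedOld <- old[!inNew]
        added <- setdiff(cell, old)
        ov[[i]] <- .overviewRow(table@rowIds[i], old, kept, removedOld,
                                added, sep)
        rows <- list()
        ## distinct accessions yielding no candidate name
        distinct <- which(!duplicated(grp))
        noName <- grp[distinct[vapply(distinct, function(k)
            length(perAcc[[k]]) == 0L, logical(1))]]
        if (length(noName))
            rows <- c(rows, list(.detailRows(table@rowIds[i], noName,
                "no_gene_name", "no gene name under mode=" %+% mode)))
        if (length(removedOld))
            rows <- c(rows, list(.detailRows(table@rowIds[i],
                unique(removedOld), "not_in_namespace",
                "superseded by remapping (mode=" %+% mode %+% ")")))
        dt[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
    }
    overview <- do.call(rbind, ov)
    detail <- do.call(rbind, c(dt, list(.emptyDetail())))
    rownames(overview) <- rownames(detail) <- NULL
    out <- initialize(table, genes = newGenes,
                      geneColumn = if (nzchar(table@geneColumn))
                          table@geneColumn else "Gene names")
    if (!keepEmpty)
        out <- .subsetRows(out, lengths(newGenes) > 0L)
    list(table = out, overview = overview, detail = detail)
}

`%+%` <- function(a, b) paste0(a, b)
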