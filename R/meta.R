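## meta_analysis: gene-level intersection analysis across harmonized
## studies (UpSet-style membership matrix and occurrence ranking).

#' Flatten a study table to its gene set
#'
#' Union over all rows of all gene-cell members; matching downstream is
#' exact-string and case-sensitive, so a gene present in several rows of
#' one study counts once.
#'
#' @param table a \linkS4class{StudyTable} with a populated gene column.
#' @return character vector of distinct gene symbols (input order of first
#'   occurrence).
#' @export
studyGeneSet <- function(table) {
    stopifnot(is(table, "StudyTable"))
    if (!length(table@genes))
        stop("study '", table@studyId, "' has no gene column", call. = FALSE)
    u <- unlist(table@genes, use.names = FALSE)
    if (is.null(u)) character() else unique(u)
}

#' Intersection analysis across studies
#'
#' Rates genes by the number of studies they occur in and reports those
#' found in at least \code{minStudies} studies.  Matching is exact-string
#' and case-sensitive: symbols of different organisms (e.g. rat
#' \code{Postn} vs human \code{POSTN}) deliberately fail to intersect, so
#' studies must be harmonized to one organism namespace first; mixing
#' organisms is rejected.
#'
#' @param tables list of \linkS4class{StudyTable}s (at least two, all in
#'   one organism namespace, distinct study ids).
#' @param minStudies minimum number of studies a gene must appear in
#'   (default 2).
#' @return an \linkS4class{IntersectionResult}; genes ordered by occurrence
#'   count descending, then alphabetically.
#' @export
intersectStudies <- function(tables, minStudies = 2L) {
    stopifnot(is.list(tables), length(tables) >= 2L)
    minStudies <- as.integer(minStudies)
    orgs <- vapply(tables, organism, character(1))
    if (length(unique(orgs)) > 1L)
        stop("studies span several organisms (",
             paste(unique(orgs), collapse = ", "),
             "); harmonize them to one organism first", call. = FALSE)
    sids <- vapply(tables, studyId, character(1))
    if (anyDuplicated(sids))
        stop("study ids must be distinct", call. = FALSE)
    sets <- lapply(tables, studyGeneSet)
    names(sets) <- sids
    allGenes <- sort(unique(unlist(sets, use.names = FALSE)))
    membership <- lapply(allGenes, function(g)
        sids[vapply(sets, function(s) g %in% s, logical(1))])
    count <- lengths(membership)
    keep <- count >= minStudies
    df <- data.frame(gene = allGenes[keep], count = count[keep],
                     studies = vapply(membership[keep], paste,
                                      character(1), collapse = ";"),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$count, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    new("IntersectionResult", genes = df, minStudies = minStudies,
        studyIds = sids)
}

#' @rdname IntersectionResult-class
#' @param x an \linkS4class{IntersectionResult}.
#' @return \code{intersectionGenes} returns the ranked gene data.frame
#'   (gene, count, studies).
#' @export
intersectionGenes <- function(x) {
    stopifnot(is(x, "IntersectionResult"))
    x@genes
}

setMethod("show", "IntersectionResult", function(object) {
    cat("IntersectionResult:", nrow(object@genes), "gene(s) in >=",
        object@minStudies, "of", length(object@studyIds), "studies\n")
    if (nrow(object@genes))
        print(utils::head(object@genes, 10L))
})

#' Binary gene-by-study membership matrix and combination counts
#'
#' Expands an intersection result into the binary matrix underlying an
#' UpSet-style plot: one row per reported gene, one column per study, and
#' the per-combination counts (how many genes share each exact study
#' combination).
#'
#' @param result an \linkS4class{IntersectionResult}.
#' @return list with \code{matrix} (0/1 integer matrix, genes x studies;
#'   row sums equal the occurrence counts) and \code{combinations}
#'   (data.frame combination, count; counts sum to the number of reported
#'   genes).
#' @export
intersectionMatrix <- function(result) {
    stopifnot(is(result, "IntersectionResult"))
    df <- result@genes
    sids <- result@studyIds
    m <- matrix(0L, nrow = nrow(df), ncol = length(sids),
                dimnames = list(df$gene, sids))
    for (i in seq_len(nrow(df))) {
        inStudies <- strsplit(df$studies[i], ";", fixed = TRUE)[[1L]]
        m[i, inStudies] <- 1L
    }
    combos <- if (nrow(df)) {
        tab <- table(df$studies)
        data.frame(combination = names(tab),
                   count = as.integer(tab),
                   stringsAsFactors = FALSE)
    } else data.frame(combination = character(), count = integer(),
                      stringsAsFactors = FALSE)
    list(matrix = m, combinations = combos)
}

#' Write intersection outputs to TSV
#'
#' Writes the ranked gene list (gene, count, studies) and the binary
#' membership matrix.
#'
#' @param result an \linkS4class{IntersectionResult}.
#' @param prefix output path prefix; \code{<prefix>_genes.tsv} and
#'   \code{<prefix>_matrix.tsv} are written.
#' @return the two paths, invisibly.
#' @export
writeIntersections <- function(result, prefix) {
    paths <- paste0(prefix, c("_genes.tsv", "_matrix.tsv"))
    utils::write.table(intersectionGenes(result), paths[1], sep = "\t",
                       quote = TRUE, row.names = FALSE)
    m <- intersectionMatrix(result)$matrix
    utils::write.table(data.frame(gene = rownames(m), m,
                                  check.names = FALSE,
                                  stringsAsFactors = FALSE),
                       paths[2], sep = "\t", quote = TRUE,
                       row.names = FALSE)
    invisible(paths)
}
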