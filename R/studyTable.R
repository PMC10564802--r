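## data_model: StudyTable construction, accessors and TSV/CSV round-trip.

.splitGroup <- function(cell, sep) {
    if (is.na(cell) || !nzchar(cell))
        return(character())
    parts <- trimws(strsplit(cell, sep, fixed = TRUE)[[1L]])
    parts[nzchar(parts)]
}

.joinGroup <- function(group, sep) paste(group, collapse = sep)

#' Construct a StudyTable from in-memory groups
#'
#' Programmatic constructor used by the fixture generators and tests;
#' [readStudyTable()] is the file-based entry point.
#'
#' @param ids list of character vectors (protein-ID groups) or a character
#'   vector of separator-joined cells.
#' @param organism organism code (name or taxon id alias).
#' @param studyId character(1) study label.
#' @param genes optional list of character vectors (gene-name groups) or
#'   separator-joined character vector.
#' @param extra optional data.frame of additional columns, preserved
#'   verbatim by all harmonization steps.
#' @param idColumn,geneColumn column names used when writing.
#' @param sep group separator, default \code{";"}.
#' @return a \linkS4class{StudyTable}.
#' @examples
#' studyTable(list(c("P1", "P2"), "P3"), organism = "rat")
#' @export
studyTable <- function(ids, organism, studyId = "study", genes = NULL,
                       extra = NULL, idColumn = "Protein IDs",
                       geneColumn = if (is.null(genes)) "" else "Gene names",
                       sep = ";") {
    if (is.character(ids))
        ids <- lapply(ids, .splitGroup, sep = sep)
    if (is.character(genes))
        genes <- lapply(genes, .splitGroup, sep = sep)
    n <- length(ids)
    if (is.null(extra))
        extra <- data.frame(matrix(nrow = n, ncol = 0L))
    orig <- data.frame(id = vapply(ids, .joinGroup, character(1), sep = sep),
                       stringsAsFactors = FALSE)
    names(orig) <- idColumn
    colOrder <- c(idColumn, names(extra))
    if (!is.null(genes) && nzchar(geneColumn)) {
        orig[[geneColumn]] <- vapply(genes, .joinGroup, character(1),
                                     sep = sep)
        colOrder <- c(idColumn, geneColumn, names(extra))
    }
    new("StudyTable", studyId = studyId,
        organism = normalizeOrganism(organism),
        rowIds = seq_len(n), ids = ids,
        genes = if (is.null(genes)) list() else genes,
        extra = extra, idColumn = idColumn,
        geneColumn = if (is.null(genes)) geneColumn else geneColumn,
        sep = sep, colOrder = colOrder, originalCells = orig)
}

#' Read a study table from a TSV/CSV file
#'
#' Reads one tabular study file with a header row, splits the designated
#' identifier column on the group separator (MaxQuant-style protein groups),
#' and preserves every other column byte-identically.  The file dialect is
#' sniffed from the extension (\code{.csv} means comma-separated, anything
#' else tab-separated) unless \code{format} overrides it.  Empty ID cells
#' parse to empty groups; downstream \code{keepEmpty} options decide their
#' fate.
#'
#' @param path file path.
#' @param idColumnName name of the protein-ID (or gene-ID) column.
#' @param organism organism the study was performed in.
#' @param studyId study label; defaults to the file name without extension.
#' @param geneColumnName optional name of an existing gene-name column.
#' @param sep group separator inside a cell, default \code{";"}.
#' @param format \code{"auto"}, \code{"tsv"} or \code{"csv"}.
#' @param idType \code{"protein"} (the ID column holds protein accessions)
#'   or \code{"gene"} (it holds gene symbols; they are loaded as the gene
#'   column and the protein column is left absent).
#' @return a \linkS4class{StudyTable}.
#' @export
readStudyTable <- function(path, idColumnName, organism,
                           studyId = sub("\\.[^.]*$", "", basename(path)),
                           geneColumnName = NULL, sep = ";",
                           format = c("auto", "tsv", "csv"),
                           idType = c("protein", "gene")) {
    format <- match.arg(format)
    idType <- match.arg(idType)
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    if (format == "auto")
        format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
                  else "tsv"
    df <- utils::read.table(path, header = TRUE,
                            sep = if (format == "csv") "," else "\t",
                            quote = "\"", colClasses = "character",
                            check.names = FALSE, comment.char = "",
                            na.strings = NULL, stringsAsFactors = FALSE)
    if (nrow(df) == 0L)
        stop("empty study file: ", path, call. = FALSE)
    if (!idColumnName %in% names(df))
        stop("column '", idColumnName, "' not found; available columns: ",
             paste(names(df), collapse = ", "), call. = FALSE)
    if (!is.null(geneColumnName) && !geneColumnName %in% names(df))
        stop("gene column '", geneColumnName, "' not found; available ",
             "columns: ", paste(names(df), collapse = ", "), call. = FALSE)
    groups <- lapply(df[[idColumnName]], .splitGroup, sep = sep)
    special <- c(idColumnName, geneColumnName)
    extra <- df[, setdiff(names(df), special), drop = FALSE]
    orig <- df[, intersect(names(df), special), drop = FALSE]
    n <- nrow(df)
    if (idType == "gene") {
        tab <- new("StudyTable", studyId = studyId,
                   organism = normalizeOrganism(organism),
                   rowIds = seq_len(n), ids = replicate(n, character()),
                   genes = groups, extra = extra, idColumn = "",
                   geneColumn = idColumnName, sep = sep,
                   colOrder = names(df), originalCells = orig)
        return(tab)
    }
    genes <- if (is.null(geneColumnName)) list()
             else lapply(df[[geneColumnName]], .splitGroup, sep = sep)
    new("StudyTable", studyId = studyId,
        organism = normalizeOrganism(organism),
        rowIds = seq_len(n), ids = groups, genes = genes, extra = extra,
        idColumn = idColumnName,
        geneColumn = if (is.null(geneColumnName)) "" else geneColumnName,
        sep = sep, colOrder = names(df), originalCells = orig)
}

#' Write a study table back to TSV/CSV
#'
#' In \code{replace} mode the identifier column(s) are overwritten with the
#' current (harmonized) groups, keeping the source column layout; in
#' \code{add_column} mode the original columns are written untouched and the
#' harmonized groups are appended as new columns suffixed
#' \code{"_harmonized"}.  Only surviving rows are written.
#'
#' @param table a \linkS4class{StudyTable}.
#' @param path output path; extension decides TSV vs CSV as in
#'   [readStudyTable()].
#' @param mode \code{"replace"} or \code{"add_column"}.
#' @return the output path, invisibly.
#' @export
writeStudyTable <- function(table, path, mode = c("replace", "add_column")) {
    mode <- match.arg(mode)
    stopifnot(is(table, "StudyTable"))
    sep <- table@sep
    n <- length(table@rowIds)
    idCells <- vapply(table@ids, .joinGroup, character(1), sep = sep)
    geneCells <- if (length(table@genes))
        vapply(table@genes, .joinGroup, character(1), sep = sep) else NULL
    out <- list()
    for (cn in table@colOrder) {
        if (cn %in% names(table@originalCells)) {
            orig <- table@originalCells[[cn]]
            if (mode == "replace") {
                if (cn == table@idColumn && nzchar(table@idColumn))
                    out[[cn]] <- idCells
                else if (cn == table@geneColumn && !is.null(geneCells))
                    out[[cn]] <- geneCells
                else out[[cn]] <- orig
            } else out[[cn]] <- orig
        } else out[[cn]] <- table@extra[[cn]]
    }
    if (mode == "add_column") {
        if (nzchar(table@idColumn))
            out[[paste0(table@idColumn, "_harmonized")]] <- idCells
        if (!is.null(geneCells)) {
            gc <- if (nzchar(table@geneColumn)) table@geneColumn
                  else "Gene names"
            out[[paste0(gc, "_harmonized")]] <- geneCells
        }
    } else if (!is.null(geneCells) && !nzchar(table@geneColumn)) {
        ## gene groups created by harmonization, no source gene column
        out[["Gene names"]] <- geneCells
    }
    df <- as.data.frame(out, check.names = FALSE, optional = TRUE,
                        stringsAsFactors = FALSE)
    if (n == 0L)
        df <- df[integer(), , drop = FALSE]
    csv <- grepl("\\.csv$", path, ignore.case = TRUE)
    ok <- tryCatch({
        utils::write.table(df, path, sep = if (csv) "," else "\t",
                           quote = TRUE, row.names = FALSE, na = "")
        TRUE
    }, error = function(e) {
        stop("cannot write study table to '", path, "': ",
             conditionMessage(e), call. = FALSE)
    })
    invisible(path)
}

## Keep only the rows at positions `idx` (logical or integer), preserving
## stable rowIds and the original cells.
.subsetRows <- function(table, idx) {
    initialize(table,
        rowIds = table@rowIds[idx],
        ids = table@ids[idx],
        genes = if (length(table@genes)) table@genes[idx] else list(),
        extra = table@extra[idx, , drop = FALSE],
        originalCells = table@originalCells[idx, , drop = FALSE])
}

#' @rdname StudyTable-class
#' @export
setMethod("studyId", "StudyTable", function(x) x@studyId)

#' @rdname StudyTable-class
#' @export
setMethod("organism", "StudyTable", function(x) x@organism)

#' @rdname StudyTable-class
#' @export
setMethod("idGroups", "StudyTable", function(x) {
    names(x@ids) <- as.character(x@rowIds)
    x@ids
})

#' @rdname StudyTable-class
#' @export
setMethod("geneGroups", "StudyTable", function(x) {
    g <- x@genes
    if (length(g)) names(g) <- as.character(x@rowIds)
    g
})

#' @rdname StudyTable-class
#' @export
setMethod("rowIds", "StudyTable", function(x) x@rowIds)

#' @rdname StudyTable-class
#' @export
setMethod("extraColumns", "StudyTable", function(x) x@extra)

#' @rdname StudyTable-class
#' @export
setMethod("nrow", "StudyTable", function(x) length(x@rowIds))

setMethod("show", "StudyTable", function(object) {
    cat("StudyTable '", object@studyId, "' (", object@organism, ")\n",
        sep = "")
    cat("  rows: ", length(object@rowIds),
        "  protein groups: ", sum(lengths(object@ids) > 0L),
        "  gene groups: ",
        if (length(object@genes)) sum(lengths(object@genes) > 0L) else 0L,
        "\n", sep = "")
    cat("  extra columns: ",
        if (ncol(object@extra)) paste(names(object@extra), collapse = ", ")
        else "(none)", "\n", sep = "")
})
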