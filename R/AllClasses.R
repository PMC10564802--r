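#' @import methods
NULL

## Supported organisms and their NCBI taxon aliases.
.ORGANISMS <- c(human = "9606", rat = "10116", mouse = "10090", rabbit = "9986")

#' Normalize an organism code
#'
#' Accepts the lowercase organism names \code{human}, \code{rat}, \code{mouse},
#' \code{rabbit} (case-insensitively) or their NCBI taxon identifiers
#' (9606, 10116, 10090, 9986) and returns the canonical lowercase name.
#'
#' @param organism character(1) organism name or taxon id.
#' @return character(1), one of \code{"human"}, \code{"rat"}, \code{"mouse"},
#'   \code{"rabbit"}.
#' @examples
#' normalizeOrganism("Human")
#' normalizeOrganism("10116")
#' @export
normalizeOrganism <- function(organism) {
    if (length(organism) != 1L || is.na(organism))
        stop("'organism' must be a single non-NA string", call. = FALSE)
    org <- tolower(as.character(organism))
    if (org %in% names(.ORGANISMS))
        return(org)
    hit <- names(.ORGANISMS)[.ORGANISMS == org]
    if (length(hit) == 1L)
        return(hit)
    stop("unsupported organism '", organism, "'; supported: ",
         paste(names(.ORGANISMS), collapse = ", "),
         " (or taxon ids ", paste(.ORGANISMS, collapse = ", "), ")",
         call. = FALSE)
}

.validIdGroupList <- function(x, what) {
    if (!is.list(x))
        return(paste0(what, " must be a list of character vectors"))
    bad <- !vapply(x, is.character, logical(1))
    if (any(bad))
        return(paste0(what, " contains non-character members"))
    if (any(vapply(x, function(g) any(is.na(g) | g == ""), logical(1))))
        return(paste0(what, " contains empty or NA identifiers"))
    NULL
}

#' StudyTable: one study's identifier table
#'
#' Holds one study's rows of protein-ID groups (and, optionally, gene-name
#' groups) together with all other columns of the source file, preserved
#' verbatim.  Row identifiers are stable: harmonization steps may drop rows
#' but never renumber the survivors.
#'
#' @slot studyId character(1) study label.
#' @slot organism character(1) canonical organism code.
#' @slot rowIds integer vector of stable, unique row identifiers.
#' @slot ids list of character vectors; each element is one row's protein-ID
#'   group (possibly empty).
#' @slot genes list of character vectors (gene-name groups) of the same
#'   length as \code{ids}, or an empty list when no gene column exists.
#' @slot extra data.frame of all remaining input columns, preserved verbatim;
#'   zero columns allowed, row count must match.
#' @slot idColumn character(1) name of the source ID column.
#' @slot geneColumn character(1) name of the gene column ("" if absent).
#' @slot sep character(1) group separator (default ";").
#' @slot colOrder character vector: source file column names in order, used
#'   to reconstruct the file layout on write.
#' @slot originalCells data.frame of the raw (unsplit) id/gene cells as
#'   read, one row per rowId; backs the add-column output mode.
#'
#' @seealso [readStudyTable()], [writeStudyTable()]
#' @exportClass StudyTable
setClass("StudyTable",
    representation(studyId = "character", organism = "character",
                   rowIds = "integer", ids = "list", genes = "list",
                   extra = "data.frame", idColumn = "character",
                   geneColumn = "character", sep = "character",
                   colOrder = "character", originalCells = "data.frame"),
    prototype(studyId = "study", organism = "human", rowIds = integer(),
              ids = list(), genes = list(), extra = data.frame(),
              idColumn = "ids", geneColumn = "", sep = ";",
              colOrder = character(), originalCells = data.frame()))

setValidity("StudyTable", function(object) {
    msgs <- character()
    if (length(object@studyId) != 1L)
        msgs <- c(msgs, "studyId must be a single string")
    if (!object@organism %in% names(.ORGANISMS))
        msgs <- c(msgs, paste0("organism '", object@organism,
                               "' not in supported list"))
    n <- length(object@rowIds)
    if (anyDuplicated(object@rowIds))
        msgs <- c(msgs, "rowIds must be unique")
    if (length(object@ids) != n)
        msgs <- c(msgs, "length(ids) must equal length(rowIds)")
    if (length(object@genes) && length(object@genes) != n)
        msgs <- c(msgs, "genes must be empty or match length(rowIds)")
    if (nrow(object@extra) != n && ncol(object@extra) > 0L)
        msgs <- c(msgs, "extra must have one row per rowId")
    m <- .validIdGroupList(object@ids, "ids")
    if (!is.null(m)) msgs <- c(msgs, m)
    if (length(object@genes)) {
        m <- .validIdGroupList(object@genes, "genes")
        if (!is.null(m)) msgs <- c(msgs, m)
    }
    if (length(msgs)) msgs else TRUE
})

#' AnnotationProvider: local annotation snapshot
#'
#' A pure, offline lookup service backing all harmonization stages.  Three
#' flat tables are held: protein records (organism, review status, obsolete
#' flag, gene names), gene records (Ensembl id/symbol and namespace
#' membership flags), and ortholog pairs keyed by Ensembl gene ids.  Lookups
#' never mutate the provider and unknown identifiers are reported as absent,
#' not as errors.
#'
#' @slot proteins data.frame with columns accession, organism, reviewed,
#'   obsolete, primary_gene_name, synonyms.
#' @slot genes data.frame with columns symbol, organism, ensembl_id,
#'   ensembl_symbol, in_hgnc, in_mygene, has_annotation.
#' @slot orthologs data.frame with columns source_ensembl_id,
#'   source_organism, target_organism, target_ensembl_id, target_symbol.
#'
#' @seealso [loadProvider()]
#' @exportClass AnnotationProvider
setClass("AnnotationProvider",
    representation(proteins = "data.frame", genes = "data.frame",
                   orthologs = "data.frame"))

setValidity("AnnotationProvider", function(object) {
    msgs <- character()
    pc <- c("accession", "organism", "reviewed", "obsolete",
            "primary_gene_name", "synonyms")
    gc <- c("symbol", "organism", "ensembl_id", "ensembl_symbol",
            "in_hgnc", "in_mygene", "has_annotation")
    oc <- c("source_ensembl_id", "source_organism", "target_organism",
            "target_ensembl_id", "target_symbol")
    if (!all(pc %in% names(object@proteins)))
        msgs <- c(msgs, "proteins table missing required columns")
    if (!all(gc %in% names(object@genes)))
        msgs <- c(msgs, "genes table missing required columns")
    if (!all(oc %in% names(object@orthologs)))
        msgs <- c(msgs, "orthologs table missing required columns")
    if (!length(msgs)) {
        if (anyDuplicated(object@proteins$accession))
            msgs <- c(msgs, "duplicate accession rows in proteins table")
        if (anyDuplicated(paste(object@genes$symbol, object@genes$organism)))
            msgs <- c(msgs, "duplicate (symbol, organism) rows in genes table")
        ## ensembl_symbol present iff ensembl_id present
        hasId <- !is.na(object@genes$ensembl_id) & object@genes$ensembl_id != ""
        hasSym <- !is.na(object@genes$ensembl_symbol) &
            object@genes$ensembl_symbol != ""
        if (any(hasId != hasSym))
            msgs <- c(msgs,
                "genes table: ensembl_symbol must be present iff ensembl_id is")
        if (any(object@orthologs$source_organism ==
                object@orthologs$target_organism))
            msgs <- c(msgs, "ortholog pairs must cross organisms")
    }
    if (length(msgs)) msgs else TRUE
})

#' HarmonizationLog: merged per-step loss/gain records
#'
#' Pairs an overview log (one record per surviving or dropped input row:
#' previous, kept, removed and added identifiers plus their counts) with a
#' detailed log (one record per affected identifier, carrying the single
#' removal reason and any annotation metadata).  Conservation holds in every
#' overview record: \code{n_previous == n_kept + n_removed}.
#'
#' @slot overview data.frame with columns step, row_id, previous_ids,
#'   kept_ids, removed_ids, added_ids (separator-joined), n_previous,
#'   n_kept, n_removed, n_added.
#' @slot detail data.frame with columns step, row_id, identifier, reason,
#'   metadata.
#'
#' @seealso [mergeLogs()], [writeLogs()], [logSummary()]
#' @exportClass HarmonizationLog
setClass("HarmonizationLog",
    representation(overview = "data.frame", detail = "data.frame"))

#' IntersectionResult: gene-level multi-study membership
#'
#' @slot genes data.frame with columns gene, count, studies
#'   (";"-joined study ids), ordered by count descending then gene name.
#' @slot minStudies integer(1) threshold applied.
#' @slot studyIds character vector of all studies compared.
#'
#' @seealso [intersectStudies()], [intersectionMatrix()]
#' @exportClass IntersectionResult
setClass("IntersectionResult",
    representation(genes = "data.frame", minStudies = "integer",
                   studyIds = "character"))

setValidity("IntersectionResult", function(object) {
    msgs <- character()
    if (!all(c("gene", "count", "studies") %in% names(object@genes)))
        msgs <- c(msgs, "genes table missing required columns")
    else if (nrow(object@genes) && any(object@genes$count < object@minStudies))
        msgs <- c(msgs, "reported genes must meet the minStudies threshold")
    if (length(msgs)) msgs else TRUE
})

#' MechanismNetwork: protein interaction graph with attached drugs and seeds
#'
#' An undirected protein--protein interaction graph (edge weights default
#' to 1), a bipartite drug--target edge table, and a set of seed proteins
#' (typically multi-study biomarker candidates).  Drug nodes never take part
#' in protein--protein edges.
#'
#' @slot ppi igraph, undirected, vertices are protein ids, edge attribute
#'   \code{weight} >= 0.
#' @slot drugTargets data.frame with columns drug, protein, approved
#'   (logical).
#' @slot seeds character vector of mapped seed proteins (subset of the PPI
#'   vertex set).
#' @slot unmappedSeeds character vector of requested seeds absent from the
#'   network (reported, never silently dropped).
#'
#' @seealso [mechanismNetwork()], [mapSeeds()], [mustConnect()],
#'   [trustrank()], [rankDrugs()]
#' @exportClass MechanismNetwork
setClass("MechanismNetwork",
    representation(ppi = "ANY", drugTargets = "data.frame",
                   seeds = "character", unmappedSeeds = "character"))

setValidity("MechanismNetwork", function(object) {
    msgs <- character()
    g <- object@ppi
    if (!igraph::is_igraph(g))
        return("ppi slot must be an igraph object")
    if (igraph::is_directed(g))
        msgs <- c(msgs, "ppi graph must be undirected")
    if (any(igraph::which_loop(g)))
        msgs <- c(msgs, "ppi graph must not contain self-loops")
    if (!all(c("drug", "protein", "approved") %in% names(object@drugTargets)))
        msgs <- c(msgs, "drugTargets must have drug, protein, approved columns")
    if (!all(object@seeds %in% igraph::V(g)$name))
        msgs <- c(msgs, "seeds must be vertices of the PPI graph")
    if (any(object@drugTargets$drug %in% igraph::V(g)$name))
        msgs <- c(msgs, "drug ids must not collide with protein vertex names")
    if (length(msgs)) msgs else TRUE
})

#' SteinerSolution: result of the multi-tree connector search
#'
#' @slot trees list of two-column character edge matrices, one per
#'   iteration; each tree spans all seeds of its component.
#' @slot nodes character vector: union of all tree vertices.
#' @slot connectors data.frame with columns node, participation, degree,
#'   sorted by participation descending then degree descending then name;
#'   connectors never include seeds.
#' @slot seeds character vector of the seeds that were connected.
#'
#' @seealso [mustConnect()]
#' @exportClass SteinerSolution
setClass("SteinerSolution",
    representation(trees = "list", nodes = "character",
                   connectors = "data.frame", seeds = "character"))

setValidity("SteinerSolution", function(object) {
    if (length(intersect(object@connectors$node, object@seeds)))
        return("connectors must not include seeds")
    TRUE
})
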