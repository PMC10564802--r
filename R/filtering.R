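## filtering: remove wrong-organism, unreviewed, obsolete, contaminant and
## decoy members from protein groups, with full loss logging.

.FILTER_MODES <- c("organism_based", "reviewed_based", "decoy_based")

.stripFlag <- function(accession) sub("^(REV__|CON__)", "", accession)

#' Classify a single protein accession for filtering
#'
#' Checks are applied in fixed precedence: decoy, contaminant, obsolete (or
#' unknown to the snapshot), wrong organism, unreviewed; the first failing
#' check gives the (single) removal reason.  MaxQuant flag prefixes
#' (\code{REV__} decoys, \code{CON__} contaminants) are recognised when the
#' decoy-based mode is active and stripped before the record is consulted.
#' The obsolete/unknown check is part of the record-based modes (organism or
#' reviewed filtering): an accession that the snapshot cannot verify cannot
#' pass them.
#'
#' @param accession the accession as it appears in the study (possibly
#'   flag-prefixed).
#' @param record the provider record for the flag-stripped accession, or
#'   \code{NULL} when unknown (see [lookupProteins()]).
#' @param modes character subset of \code{c("organism_based",
#'   "reviewed_based", "decoy_based")}; must be nonempty.
#' @param targetOrganism organism code; required when
#'   \code{"organism_based"} is active.
#' @return character(1): \code{"keep"} or one of the removal reasons
#'   \code{"decoy"}, \code{"contaminant"}, \code{"obsolete"},
#'   \code{"wrong_organism"}, \code{"unreviewed"}.
#' @export
classifyId <- function(accession, record = NULL, modes,
                       targetOrganism = NULL) {
    modes <- match.arg(modes, .FILTER_MODES, several.ok = TRUE)
    if ("decoy_based" %in% modes) {
        if (startsWith(accession, "REV__")) return("decoy")
        if (startsWith(accession, "CON__")) return("contaminant")
    }
    recordBased <- any(c("organism_based", "reviewed_based") %in% modes)
    if (recordBased && (is.null(record) || isTRUE(record$obsolete)))
        return("obsolete")
    if ("organism_based" %in% modes) {
        if (is.null(targetOrganism))
            stop("organism_based filtering requires 'targetOrganism'",
                 call. = FALSE)
        if (record$organism != normalizeOrganism(targetOrganism))
            return("wrong_organism")
    }
    if ("reviewed_based" %in% modes && !isTRUE(record$reviewed))
        return("unreviewed")
    "keep"
}

#' Filter protein IDs of a study table
#'
#' Reviews every member of every protein group and removes those of bad
#' quality: assigned to the wrong organism, lacking reviewed status,
#' obsolete (retired from, or unknown to, the annotation snapshot),
#' contaminants (\code{CON__}) and decoys (\code{REV__}).  Rows whose whole
#' group is removed are dropped unless \code{keepEmpty}; surviving rows keep
#' their stable row ids and their extra columns byte-identical.
#'
#' @param table a \linkS4class{StudyTable} whose ID column holds protein
#'   accessions (gene-only tables are rejected).
#' @param provider an \linkS4class{AnnotationProvider}.
#' @param modes one or more of \code{"organism_based"},
#'   \code{"reviewed_based"}, \code{"decoy_based"}.
#' @param targetOrganism organism the study should contain; defaults to the
#'   table's organism when organism-based filtering is requested.
#' @param keepEmpty keep rows whose group became empty (default drop).
#' @return list with components \code{table} (filtered
#'   \linkS4class{StudyTable}), \code{overview} and \code{detail}
#'   (data.frames; see \linkS4class{HarmonizationLog}).
#' @examples
#' ## see the curated use-case fixture: generateUseCaseFixture()
#' @export
filterProteinIds <- function(table, provider, modes,
                             targetOrganism = organism(table),
                             keepEmpty = FALSE) {
    stopifnot(is(table, "StudyTable"), is(provider, "AnnotationProvider"))
    modes <- match.arg(modes, .FILTER_MODES, several.ok = TRUE)
    if (!length(modes))
        stop("at least one filtering mode must be selected", call. = FALSE)
    if (!nzchar(table@idColumn) || !length(table@ids))
        stop("protein-ID filtering cannot be performed: study '",
             table@studyId, "' provides no protein-ID column (gene IDs ",
             "only)", call. = FALSE)
    allAcc <- .stripFlag(unique(unlist(table@ids, use.names = FALSE)))
    records <- lookupProteins(provider, allAcc)
    sep <- table@sep
    ov <- vector("list", length(table@rowIds))
    dt <- vector("list", length(table@rowIds))
    newIds <- table@ids
    for (i in seq_along(table@rowIds)) {
        grp <- table@ids[[i]]
        verdict <- vapply(grp, function(a) {
            classifyId(a, records[[.stripFlag(a)]], modes, targetOrganism)
        }, character(1), USE.NAMES = FALSE)
        kept <- grp[verdict == "keep"]
        removed <- grp[verdict != "keep"]
        newIds[[i]] <- kept
        ov[[i]] <- .overviewRow(table@rowIds[i], grp, kept, removed,
                                character(), sep)
        ## one detail record per distinct removed identifier per row
        drm <- !duplicated(removed)
        dt[[i]] <- do.call(rbind, lapply(which(drm), function(k) {
            a <- removed[k]
            rec <- records[[.stripFlag(a)]]
            meta <- switch(verdict[match(a, grp)],
                decoy = "flag=REV__",
                contaminant = "flag=CON__",
                obsolete = if (is.null(rec)) "not found" else "obsolete",
                wrong_organism = paste0("organism=", rec$organism),
                unreviewed = "unreviewed in snapshot",
                "")
            .detailRows(table@rowIds[i], a, verdict[match(a, grp)], meta)
        }))
    }
    overview <- do.call(rbind, ov)
    detail <- do.call(rbind, c(dt, list(.emptyDetail())))
    rownames(overview) <- rownames(detail) <- NULL
    out <- initialize(table, ids = newIds)
    if (!keepEmpty)
        out <- .subsetRows(out, lengths(newIds) > 0L)
    list(table = out, overview = overview, detail = detail)
}
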