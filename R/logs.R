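## data_model: overview/detail logging shared by all harmonization stages.

.REASONS <- c("wrong_organism", "unreviewed", "obsolete", "contaminant",
              "decoy", "no_gene_name", "not_in_namespace", "no_ortholog")

.emptyOverview <- function() {
    data.frame(row_id = integer(), previous_ids = character(),
               kept_ids = character(), removed_ids = character(),
               added_ids = character(), n_previous = integer(),
               n_kept = integer(), n_removed = integer(),
               n_added = integer(), stringsAsFactors = FALSE)
}

.emptyDetail <- function() {
    data.frame(row_id = integer(), identifier = character(),
               reason = character(), metadata = character(),
               stringsAsFactors = FALSE)
}

## One overview record.  `previous` must equal kept + removed as multisets;
## callers construct kept/removed by partitioning previous, so the invariant
## holds by construction and is asserted here as a guard.
.overviewRow <- function(rowId, previous, kept, removed, added, sep) {
    stopifnot(length(previous) == length(kept) + length(removed))
    data.frame(row_id = rowId,
               previous_ids = .joinGroup(previous, sep),
               kept_ids = .joinGroup(kept, sep),
               removed_ids = .joinGroup(removed, sep),
               added_ids = .joinGroup(added, sep),
               n_previous = length(previous), n_kept = length(kept),
               n_removed = length(removed), n_added = length(added),
               stringsAsFactors = FALSE)
}

.detailRows <- function(rowId, identifiers, reason, metadata = "") {
    if (!length(identifiers))
        return(.emptyDetail())
    stopifnot(reason %in% .REASONS)
    data.frame(row_id = rowId, identifier = identifiers, reason = reason,
               metadata = metadata, stringsAsFactors = FALSE)
}

#' Merge per-step logs into one HarmonizationLog
#'
#' Each harmonization function returns its own overview and detail records;
#' this concatenates them in pipeline order and labels every record with its
#' step name, so loss and gain can be traced per stage across a whole run.
#'
#' @param stepLogs named list; each element is a list with components
#'   \code{overview} and \code{detail} (as returned by the harmonization
#'   functions).  Names give the step labels, in pipeline order.
#' @return a \linkS4class{HarmonizationLog}.
#' @examples
#' mergeLogs(list())          # empty log
#' @export
mergeLogs <- function(stepLogs) {
    if (!length(stepLogs))
        return(new("HarmonizationLog",
                   overview = cbind(data.frame(step = character()),
                                    .emptyOverview()),
                   detail = cbind(data.frame(step = character()),
                                  .emptyDetail())))
    if (is.null(names(stepLogs)) || any(!nzchar(names(stepLogs))))
        names(stepLogs) <- paste0("step", seq_along(stepLogs))
    ov <- do.call(rbind, lapply(names(stepLogs), function(nm) {
        o <- stepLogs[[nm]]$overview
        if (is.null(o) || !nrow(o)) return(NULL)
        cbind(data.frame(step = nm, stringsAsFactors = FALSE), o)
    }))
    dt <- do.call(rbind, lapply(names(stepLogs), function(nm) {
        d <- stepLogs[[nm]]$detail
        if (is.null(d) || !nrow(d)) return(NULL)
        cbind(data.frame(step = nm, stringsAsFactors = FALSE), d)
    }))
    if (is.null(ov)) ov <- cbind(data.frame(step = character()),
                                 .emptyOverview())
    if (is.null(dt)) dt <- cbind(data.frame(step = character()),
                                 .emptyDetail())
    rownames(ov) <- rownames(dt) <- NULL
    new("HarmonizationLog", overview = ov, detail = dt)
}

#' @rdname HarmonizationLog-class
#' @export
setMethod("overviewLog", "HarmonizationLog", function(x) x@overview)

#' @rdname HarmonizationLog-class
#' @export
setMethod("detailLog", "HarmonizationLog", function(x) x@detail)

setMethod("show", "HarmonizationLog", function(object) {
    cat("HarmonizationLog:", nrow(object@overview), "overview records,",
        nrow(object@detail), "detail records\n")
    s <- logSummary(object)
    if (nrow(s)) {
        cat("  per step (kept / removed / added identifiers):\n")
        for (i in seq_len(nrow(s)))
            cat(sprintf("    %-12s %d / %d / %d\n", s$step[i], s$n_kept[i],
                        s$n_removed[i], s$n_added[i]))
    }
})

#' Per-step summary counts of a HarmonizationLog
#'
#' @param log a \linkS4class{HarmonizationLog}.
#' @return data.frame with one row per step: n_rows, n_previous, n_kept,
#'   n_removed, n_added, summed over the step's overview records.
#' @export
logSummary <- function(log) {
    stopifnot(is(log, "HarmonizationLog"))
    ov <- log@overview
    if (!nrow(ov))
        return(data.frame(step = character(), n_rows = integer(),
                          n_previous = integer(), n_kept = integer(),
                          n_removed = integer(), n_added = integer(),
                          stringsAsFactors = FALSE))
    steps <- unique(ov$step)
    do.call(rbind, lapply(steps, function(st) {
        s <- ov[ov$step == st, , drop = FALSE]
        data.frame(step = st, n_rows = nrow(s),
                   n_previous = sum(s$n_previous), n_kept = sum(s$n_kept),
                   n_removed = sum(s$n_removed), n_added = sum(s$n_added),
                   stringsAsFactors = FALSE)
    }))
}

#' Serialize a HarmonizationLog to disk
#'
#' Writes two TSV files (\code{<prefix>_overview.tsv},
#' \code{<prefix>_detail.tsv}) plus one JSON summary
#' (\code{<prefix>_summary.json}) with the per-step counts.
#'
#' @param log a \linkS4class{HarmonizationLog}.
#' @param prefix output path prefix.
#' @return character vector of the three paths written, invisibly.
#' @export
writeLogs <- function(log, prefix) {
    stopifnot(is(log, "HarmonizationLog"))
    paths <- paste0(prefix, c("_overview.tsv", "_detail.tsv",
                              "_summary.json"))
    utils::write.table(log@overview, paths[1], sep = "\t", quote = TRUE,
                       row.names = FALSE)
    utils::write.table(log@detail, paths[2], sep = "\t", quote = TRUE,
                       row.names = FALSE)
    jsonlite::write_json(logSummary(log), paths[3], dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
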