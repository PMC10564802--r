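## cli/pipeline: chain harmonization stages over several studies from one
## declarative config, with per-stage logs and a reproducible run manifest.

.STAGE_NAMES <- c("filter", "remap", "reduce", "orthologs")

## Which column type each stage needs and produces; used to validate the
## whole plan before anything is executed.
.stageNeeds <- c(filter = "protein", remap = "protein", reduce = "gene",
                 orthologs = "gene")

#' Run the harmonization pipeline from a config
#'
#' Executes an ordered list of stages (\code{filter}, \code{remap},
#' \code{reduce}, \code{orthologs}) over one or more study tables,
#' optionally followed by an intersection analysis, writing harmonized
#' tables, per-stage overview/detail logs and a run manifest (config,
#' provider checksums, seed, package version) into the output directory.
#' The whole plan is validated against each study's column types before
#' any stage runs: e.g. protein-ID filtering of a gene-only study is
#' rejected up front.
#'
#' The config is a list (or a JSON file path) with elements:
#' \describe{
#'   \item{provider_dir}{directory holding the annotation snapshot.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{integer RNG seed recorded in the manifest (default 42).}
#'   \item{studies}{list of study descriptors: \code{path},
#'     \code{study_id}, \code{id_column}, \code{organism}, optional
#'     \code{gene_column}, \code{sep}, \code{id_type}
#'     ("protein"/"gene").}
#'   \item{stages}{ordered list of stage descriptors: \code{name} plus
#'     the stage's parameters (\code{modes}, \code{target_organism},
#'     \code{mode}, \code{fasta}, \code{ground}, \code{keep_empty},
#'     ...); an optional \code{studies} field restricts a stage to a
#'     subset of study ids.}
#'   \item{intersect}{optional: list(min_studies) to run the
#'     intersection analysis on the harmonized tables.}
#'   \item{output_mode}{"replace" (default) or "add_column" for the
#'     harmonized study tables.}
#' }
#'
#' @param config list or path to a JSON file.
#' @return invisibly, a list with \code{tables} (harmonized
#'   \linkS4class{StudyTable}s), \code{logs} (named list of
#'   \linkS4class{HarmonizationLog}s per study), \code{intersection}
#'   (\linkS4class{IntersectionResult} or NULL) and \code{manifest}.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                      simplifyDataFrame = FALSE)
    stopifnot(is.list(config))
    for (f in c("provider_dir", "out_dir", "studies", "stages"))
        if (is.null(config[[f]]))
            stop("config misses required field '", f, "'", call. = FALSE)
    if (!length(config$stages))
        stop("config declares an empty stage list", call. = FALSE)
    seed <- if (is.null(config$seed)) 42L else as.integer(config$seed)
    outMode <- if (is.null(config$output_mode)) "replace"
               else config$output_mode
    provider <- loadProvider(config$provider_dir)

    studies <- lapply(config$studies, function(s) {
        readStudyTable(s$path, idColumnName = s$id_column,
                       organism = s$organism,
                       studyId = if (is.null(s$study_id))
                           sub("\\.[^.]*$", "", basename(s$path))
                           else s$study_id,
                       geneColumnName = s$gene_column,
                       sep = if (is.null(s$sep)) ";" else s$sep,
                       idType = if (is.null(s$id_type)) "protein"
                                else s$id_type)
    })
    names(studies) <- vapply(studies, studyId, character(1))

    ## validate the plan before executing anything
    stages <- config$stages
    for (sid in names(studies)) {
        hasProtein <- nzchar(studies[[sid]]@idColumn)
        hasGene <- length(studies[[sid]]@genes) > 0L
        for (st in stages) {
            if (!st$name %in% .STAGE_NAMES)
                stop("unknown stage '", st$name, "'", call. = FALSE)
            if (!is.null(st$studies) && !sid %in% st$studies)
                next
            need <- .stageNeeds[[st$name]]
            if (need == "protein" && !hasProtein)
                stop("stage '", st$name, "' needs protein IDs but study '",
                     sid, "' provides gene IDs only", call. = FALSE)
            if (need == "gene" && !hasGene)
                stop("stage '", st$name, "' needs gene names but study '",
                     sid, "' has none at that point (add a remap stage ",
                     "first)", call. = FALSE)
            if (st$name == "remap") hasGene <- TRUE
        }
    }

    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    logs <- stats::setNames(vector("list", length(studies)),
                            names(studies))
    for (sid in names(studies)) {
        stepLogs <- list()
        tb <- studies[[sid]]
        for (st in stages) {
            if (!is.null(st$studies) && !sid %in% st$studies)
                next
            keepEmpty <- isTRUE(st$keep_empty)
            res <- switch(st$name,
                filter = filterProteinIds(tb, provider,
                    modes = unlist(st$modes),
                    targetOrganism = if (is.null(st$target_organism))
                        organism(tb) else st$target_organism,
                    keepEmpty = keepEmpty),
                remap = remapGeneNames(tb, provider,
                    mode = if (is.null(st$mode)) "uniprot_primary"
                           else st$mode,
                    fastaPath = st$fasta, keepEmpty = keepEmpty,
                    skipFilled = isTRUE(st$skip_filled)),
                reduce = reduceGeneNames(tb, provider,
                    ground = if (is.null(st$ground)) "ensembl"
                             else st$ground,
                    keepEmpty = keepEmpty),
                orthologs = mapOrthologs(tb, provider,
                    targetOrganism = st$target_organism,
                    keepEmpty = keepEmpty))
            tb <- res$table
            stepLogs[[st$name]] <- res
        }
        studies[[sid]] <- tb
        logs[[sid]] <- mergeLogs(stepLogs)
        writeStudyTable(tb, file.path(config$out_dir,
            paste0(sid, "_harmonized.tsv")), mode = outMode)
        writeLogs(logs[[sid]], file.path(config$out_dir, sid))
    }

    intersection <- NULL
    if (!is.null(config$intersect)) {
        ms <- if (is.null(config$intersect$min_studies)) 2L
              else as.integer(config$intersect$min_studies)
        intersection <- intersectStudies(unname(studies), ms)
        writeIntersections(intersection,
                           file.path(config$out_dir, "intersection"))
    }

    provFiles <- file.path(config$provider_dir, .providerFiles)
    manifest <- list(
        package_version = as.character(utils::packageVersion("proteoHarm")),
        seed = seed,
        config = config,
        provider_checksums = as.list(tools::md5sum(provFiles)),
        studies = names(studies),
        stages = vapply(stages, `[[`, character(1), "name"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(list(tables = studies, logs = logs,
                   intersection = intersection, manifest = manifest))
}
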