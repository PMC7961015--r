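## Delimited text I/O: UTF-8, header row, tab separated, '.' decimal.

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

readTsv <- function(path) {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, fileEncoding = "UTF-8")
}

#' Flatten an MxifCellSet to a wide cell table
#'
#' One row per cell: all \code{colData} columns plus
#' \code{<marker>_nuclear} and \code{<marker>_cell} raw intensity columns.
#' [readCellTable()] reverses the conversion.
#'
#' @param cells an [MxifCellSet].
#' @return data.frame.
#' @export
asCellTable <- function(cells) {
    df <- as.data.frame(colData(cells))
    nuc <- t(assay(cells, "nuclear"))
    cel <- t(assay(cells, "cell"))
    colnames(nuc) <- paste0(colnames(nuc), "_nuclear")
    colnames(cel) <- paste0(colnames(cel), "_cell")
    cbind(df, as.data.frame(nuc), as.data.frame(cel), row.names = NULL)
}

#' Read a wide cell table into an MxifCellSet
#'
#' @param x path to a delimited cell table, or a data.frame.
#' @param panel the [MarkerPanel] the table was produced under.
#' @return an [MxifCellSet].
#' @export
readCellTable <- function(x, panel) {
    df <- if (is.character(x)) readTsv(x) else x
    markers <- panel@markers$marker
    markers <- markers[paste0(markers, "_nuclear") %in% names(df)]
    nuc <- t(as.matrix(df[paste0(markers, "_nuclear")]))
    cel <- t(as.matrix(df[paste0(markers, "_cell")]))
    rownames(nuc) <- rownames(cel) <- markers
    colnames(nuc) <- colnames(cel) <- df$cell_id
    meta <- df[, !grepl("_nuclear$|_cell$", names(df)), drop = FALSE]
    cd <- DataFrame(meta, row.names = df$cell_id)
    MxifCellSet(nuc, cel, cd, panel)
}

#' Write a generated cohort to delimited text files
#'
#' Writes \code{cells.tsv}, \code{patients.tsv}, \code{fovs.tsv} and a
#' structured \code{truth.json} (true profiles, outcomes, per-cell true
#' clusters, slide offsets, artifact flags) into a directory.
#'
#' @param cohort list from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(asCellTable(cohort$cells), file.path(dir, "cells.tsv"))
    writeTsv(cohort$patients, file.path(dir, "patients.tsv"))
    writeTsv(cohort$fovs, file.path(dir, "fovs.tsv"))
    tr <- cohort$truth
    jsonlite::write_json(
        list(profiles = tr$profiles,
             outcome = as.list(tr$outcome),
             cellCluster = unname(tr$cellCluster),
             cellId = names(tr$cellCluster),
             slideOffsets = as.list(tr$slideOffsets),
             artifacts = tr$artifacts,
             seed = tr$config@seed),
        file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
    invisible(dir)
}

#' Serialise / restore an Escore model
#'
#' Structured key-value (JSON) round trip for [EscoreModel] objects.
#'
#' @param model an [EscoreModel].
#' @param path file path.
#' @export
writeEscoreModel <- function(model, path) {
    jsonlite::write_json(
        list(slopeC56 = model@slopeC56, slopeC24 = model@slopeC24,
             intercept = model@intercept, baseRate = model@baseRate,
             linearThreshold = model@linearThreshold,
             source = model@source),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeEscoreModel
#' @export
readEscoreModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("EscoreModel", slopeC56 = x$slopeC56, slopeC24 = x$slopeC24,
        intercept = x$intercept, baseRate = x$baseRate,
        linearThreshold = x$linearThreshold, source = x$source)
}

#' Serialise / restore a fitted cluster model
#'
#' Stores centroids, marker order, seed and the frozen standardisation
#' parameters (when supplied) as JSON.
#'
#' @param model a [ClusterModel].
#' @param path file path.
#' @param params optional standardisation parameters from
#'   [standardizeClusteringMarkers()].
#' @export
writeClusterModel <- function(model, path, params = NULL) {
    jsonlite::write_json(
        list(k = model@k, centers = model@centers,
             labels = rownames(model@centers), markers = model@markers,
             n = model@n, seed = model@seed,
             totWithinSS = model@totWithinSS, params = params),
        path, digits = NA, auto_unbox = TRUE)
    invisible(path)
}

#' @rdname writeClusterModel
#' @export
readClusterModel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    centers <- matrix(unlist(x$centers), nrow = x$k,
                      dimnames = list(x$labels, x$markers))
    model <- new("ClusterModel", k = as.integer(x$k), centers = centers,
                 markers = x$markers, n = as.integer(x$n),
                 seed = as.integer(x$seed), totWithinSS = x$totWithinSS)
    list(model = model, params = x$params)
}
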