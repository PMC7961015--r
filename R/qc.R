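#' Registration quality score of a cell
#'
#' Correlates a cell's baseline nuclear patch with the corresponding patch
#' from each later staining round. The per-round score is the Pearson
#' correlation clipped to [0, 1] (negative correlations score 0); a score of
#' 1 means perfect registration, 0 means the cell was lost or replaced. The
#' summary score is the minimum across rounds, because the cell must be
#' aligned in every round.
#'
#' @param baseline numeric matrix (nuclear patch at baseline).
#' @param rounds a matrix or list of matrices, one per later round.
#' @return list with \code{perRound} (numeric scores in [0, 1]) and
#'   \code{summary} (their minimum).
#' @export
scoreRegistration <- function(baseline, rounds) {
    if (is.matrix(rounds)) rounds <- list(rounds)
    if (length(baseline) < 4L) stop("patches must have at least 4 pixels")
    b <- as.vector(baseline)
    per <- vapply(rounds, function(p) {
        if (!identical(dim(p), dim(baseline)))
            stop("round patch shape differs from baseline")
        v <- as.vector(p)
        if (stats::sd(b) == 0 || stats::sd(v) == 0) {
            warning("zero-variance patch: complete signal loss, score 0")
            return(0)
        }
        min(max(stats::cor(b, v), 0), 1)
    }, numeric(1))
    list(perRound = per, summary = min(per))
}

.cellFrame <- function(cells) {
    if (is(cells, "MxifCellSet"))
        as.data.frame(colData(cells))
    else as.data.frame(cells)
}

.requireFields <- function(df, fields, what = "cell") {
    miss <- setdiff(fields, names(df))
    if (length(miss))
        stop(sprintf("missing required %s field(s): %s", what,
                     paste(miss, collapse = ", ")))
    bad <- fields[vapply(df[fields], anyNA, logical(1))]
    if (length(bad)) {
        id <- df$cell_id[which(is.na(df[[bad[1]]]))[1]]
        stop(sprintf("missing value in field '%s' (cell_id %s)",
                     bad[1], id))
    }
    invisible(TRUE)
}

#' Cell-level filtering
#'
#' Applies the cell filters: epithelial tissue class, 1--2 nuclei, every
#' sub-cellular compartment area strictly between the pixel bounds, and a
#' registration summary (minimum per-round score) at least the threshold.
#' A cell can violate several rules; the audit tallies every rule hit.
#'
#' @param cells an [MxifCellSet] or a data.frame of cell records.
#' @param criteria a [QcCriteria].
#' @return list with \code{cells} (retained, same class as input) and
#'   \code{audit} (a [FilterAudit]).
#' @export
filterCells <- function(cells, criteria = qcCriteria()) {
    df <- .cellFrame(cells)
    .requireFields(df, c("cell_id", "tissue_class", "n_nuclei",
                         "area_nucleus_px", "area_membrane_px",
                         "area_cytoplasm_px"))
    regCols <- grep("^reg_r", names(df), value = TRUE)
    if (!length(regCols)) stop("missing required cell field(s): reg_r<round>")

    okTissue <- df$tissue_class == "epithelial"
    okNuclei <- df$n_nuclei >= criteria@nucleiMin &
        df$n_nuclei <= criteria@nucleiMax
    areas <- df[c("area_nucleus_px", "area_membrane_px",
                  "area_cytoplasm_px")]
    okArea <- Reduce(`&`, lapply(areas, function(a)
        a > criteria@areaMinPx & a < criteria@areaMaxPx))
    regSummary <- do.call(pmin, df[regCols])
    okReg <- regSummary >=
        criteria@registrationThreshold - criteria@registrationTol

    keep <- okTissue & okNuclei & okArea & okReg
    rules <- list(tissue = sum(!okTissue), nuclei = sum(!okNuclei),
                  area = sum(!okArea), registration = sum(!okReg))
    audit <- filterAudit("cells", nrow(df), sum(!keep), sum(keep), rules)
    out <- if (is(cells, "MxifCellSet")) cells[, keep]
           else cells[keep, , drop = FALSE]
    list(cells = out, audit = audit)
}

#' Field-of-view filtering
#'
#' Retains fields that passed manual quality review and whose DCIS content
#' \code{pct_dcis / (pct_dcis + pct_normal)} is at least the threshold
#' (fields at exactly the boundary are retained). Fields with no evaluable
#' tissue (both percentages zero) are excluded under the rule
#' \code{"no_evaluable_tissue"}.
#'
#' @param fovs data.frame of field records (\code{fov_id}, \code{pct_dcis},
#'   \code{pct_normal}, \code{manual_quality_pass}).
#' @param criteria a [QcCriteria].
#' @return list with \code{fovs} (retained) and \code{audit}.
#' @export
filterFovs <- function(fovs, criteria = qcCriteria()) {
    .requireFields(fovs, c("fov_id", "pct_dcis", "pct_normal",
                           "manual_quality_pass"), what = "FOV")
    tot <- fovs$pct_dcis + fovs$pct_normal
    evaluable <- tot > 0
    frac <- ifelse(evaluable, fovs$pct_dcis / tot, NA_real_)
    okDcis <- evaluable & frac >= criteria@dcisFractionMin
    okManual <- as.logical(fovs$manual_quality_pass)
    keep <- okManual & okDcis
    rules <- list(manual_quality = sum(!okManual),
                  dcis_fraction = sum(evaluable & !okDcis),
                  no_evaluable_tissue = sum(!evaluable))
    audit <- filterAudit("fovs", nrow(fovs), sum(!keep), sum(keep), rules)
    list(fovs = fovs[keep, , drop = FALSE], audit = audit)
}

#' Patient-level filtering for outcome analysis
#'
#' Excludes patients with fewer cells than the minimum after the upstream
#' cell and field filters, non-event patients followed for less than the
#' minimum follow-up, and event patients whose event occurred at or beyond
#' the maximum window (possible second primaries).
#'
#' @param patients data.frame of patient records (\code{patient_id},
#'   \code{bce}, \code{followup_years}).
#' @param cells an [MxifCellSet] or data.frame of cells surviving upstream
#'   filters (used for per-patient cell counts).
#' @param criteria a [QcCriteria].
#' @return list with \code{patients} (retained) and \code{audit}.
#' @export
filterPatients <- function(patients, cells, criteria = qcCriteria()) {
    .requireFields(patients, c("patient_id", "bce", "followup_years"),
                   what = "patient")
    df <- .cellFrame(cells)
    orphans <- setdiff(df$patient_id, patients$patient_id)
    if (length(orphans))
        stop("cells reference unknown patient(s): ",
             paste(utils::head(orphans, 5), collapse = ", "))
    counts <- table(df$patient_id)
    nCells <- as.integer(counts[patients$patient_id])
    nCells[is.na(nCells)] <- 0L
    okCount <- nCells >= criteria@minCellsPerPatient
    okFollow <- ifelse(patients$bce,
                       patients$followup_years <
                           criteria@bceMaxFollowupYears,
                       patients$followup_years >=
                           criteria@nonBceMinFollowupYears)
    keep <- okCount & okFollow
    rules <- list(
        few_cells = sum(!okCount),
        short_followup_nonbce = sum(!patients$bce & !okFollow),
        long_followup_bce = sum(patients$bce & !okFollow))
    audit <- filterAudit("patients", nrow(patients), sum(!keep), sum(keep),
                         rules)
    list(patients = patients[keep, , drop = FALSE], audit = audit)
}
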