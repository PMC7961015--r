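#' Construct a marker panel
#'
#' @param markers data.frame with columns \code{marker}, \code{round},
#'   \code{summarization}, \code{role}. When \code{summarization} is missing
#'   it is filled in from the field convention (nuclear median for ER, PR,
#'   p21 and Ki67; whole-cell median otherwise).
#' @param referenceExposure named numeric vector of nominal exposure times
#'   (ms), one entry per staining round present in \code{markers}.
#' @return a [MarkerPanel].
#' @export
markerPanel <- function(markers, referenceExposure) {
    if (is.null(markers$summarization))
        markers$summarization <-
            ifelse(markers$marker %in% NUCLEAR_MARKERS,
                   "nuclear_median", "cell_median")
    if (is.null(names(referenceExposure)))
        stop("referenceExposure must be named by round")
    new("MarkerPanel", markers = markers,
        referenceExposure = referenceExposure)
}

#' Default 9-marker analysis panel
#'
#' The four clustering markers (ER, HER2, cMET, SLC7A5), four univariate
#' background markers (PR, p53, p21, Ki67) and EGFR with role
#' \code{"excluded"} (its staining was too weak to analyse). Staining rounds
#' follow the published round plan; nominal exposures are per-round
#' constants in milliseconds.
#'
#' @return a [MarkerPanel].
#' @export
defaultPanel <- function() {
    m <- data.frame(
        marker = c("ER", "PR", "cMET", "HER2", "p53", "SLC7A5", "EGFR",
                   "p21", "Ki67"),
        round  = c(4L, 4L, 6L, 7L, 8L, 12L, 13L, 13L, 15L),
        role   = c("clustering", "univariate_only", "clustering",
                   "clustering", "univariate_only", "clustering",
                   "excluded", "univariate_only", "univariate_only"),
        stringsAsFactors = FALSE)
    ref <- c("4" = 100, "6" = 150, "7" = 120, "8" = 100, "12" = 200,
             "13" = 150, "15" = 250)
    markerPanel(m, ref)
}

#' @describeIn markerPanel markers with an analysis role (clustering or
#'   univariate), i.e. the panel minus excluded and segmentation-only
#'   markers.
#' @param panel a [MarkerPanel].
#' @export
analysisMarkers <- function(panel) {
    m <- panel@markers
    m$marker[m$role %in% c("clustering", "univariate_only")]
}

#' @describeIn markerPanel the clustering markers, in canonical order.
#' @export
clusteringMarkers <- function(panel) {
    m <- panel@markers
    intersect(CLUSTERING_MARKERS, m$marker[m$role == "clustering"])
}

panelRounds <- function(panel) sort(unique(panel@markers$round))

#' Construct QC criteria
#'
#' All arguments default to the published filtering rules; see
#' [QcCriteria-class].
#'
#' @param nucleiMin,nucleiMax,areaMinPx,areaMaxPx,registrationThreshold,registrationTol,dcisFractionMin,minCellsPerPatient,nonBceMinFollowupYears,bceMaxFollowupYears
#'   see [QcCriteria-class].
#' @return a [QcCriteria].
#' @export
qcCriteria <- function(nucleiMin = 1, nucleiMax = 2, areaMinPx = 10,
                       areaMaxPx = 1500, registrationThreshold = 1.0,
                       registrationTol = 1e-9, dcisFractionMin = 0.5,
                       minCellsPerPatient = 100,
                       nonBceMinFollowupYears = 3,
                       bceMaxFollowupYears = 10) {
    new("QcCriteria", nucleiMin = nucleiMin, nucleiMax = nucleiMax,
        areaMinPx = areaMinPx, areaMaxPx = areaMaxPx,
        registrationThreshold = registrationThreshold,
        registrationTol = registrationTol,
        dcisFractionMin = dcisFractionMin,
        minCellsPerPatient = minCellsPerPatient,
        nonBceMinFollowupYears = nonBceMinFollowupYears,
        bceMaxFollowupYears = bceMaxFollowupYears)
}

filterAudit <- function(stage, input, excluded, output, rules) {
    new("FilterAudit",
        stages = data.frame(stage = stage, input = input,
                            excluded = excluded, output = output,
                            stringsAsFactors = FALSE),
        rules = if (length(rules))
            data.frame(stage = stage, rule = names(rules),
                       count = unname(unlist(rules)),
                       stringsAsFactors = FALSE)
        else data.frame(stage = character(), rule = character(),
                        count = integer(), stringsAsFactors = FALSE))
}

#' Combine filtering audits of consecutive stages
#'
#' @param ... [FilterAudit] objects in stage order.
#' @return a [FilterAudit] whose stages compose.
#' @export
combineAudits <- function(...) {
    auds <- list(...)
    new("FilterAudit",
        stages = do.call(rbind, lapply(auds, slot, "stages")),
        rules = do.call(rbind, lapply(auds, slot, "rules")))
}

#' @rdname FilterAudit-class
#' @export
setMethod("auditStages", "FilterAudit", function(x) x@stages)

#' @rdname FilterAudit-class
#' @export
setMethod("auditRules", "FilterAudit", function(x) x@rules)

setMethod("show", "FilterAudit", function(object) {
    cat("FilterAudit with", nrow(object@stages), "stage(s)\n")
    print(object@stages, row.names = FALSE)
    if (nrow(object@rules)) {
        cat("rule tallies:\n")
        print(object@rules, row.names = FALSE)
    }
})

#' Construct an MxifCellSet
#'
#' @param nuclear,cell marker x cell matrices of raw median intensities.
#' @param colData per-cell metadata (see [MxifCellSet-class]).
#' @param panel a [MarkerPanel].
#' @return an [MxifCellSet].
#' @export
MxifCellSet <- function(nuclear, cell, colData, panel) {
    se <- SummarizedExperiment(
        assays = list(nuclear = nuclear, cell = cell),
        colData = colData)
    metadata(se)$panel <- panel
    new("MxifCellSet", se)
}

#' @rdname MxifCellSet-class
#' @export
setMethod("panel", "MxifCellSet", function(x) metadata(x)$panel)

setMethod("show", "MxifCellSet", function(object) {
    cd <- colData(object)
    cat("MxifCellSet:", ncol(object), "cells,", nrow(object), "markers,",
        length(unique(cd$patient_id)), "patients,",
        length(unique(cd$slide_id)), "slides\n")
    cat("  tissue classes:",
        paste(names(table(cd$tissue_class)), table(cd$tissue_class),
              sep = "=", collapse = ", "), "\n")
})

#' @rdname ClusterModel-class
#' @export
setMethod("centers", "ClusterModel", function(x) x@centers)

setMethod("show", "ClusterModel", function(object) {
    cat("ClusterModel: k =", object@k, "on", object@n, "cells",
        sprintf("(markers: %s)\n", paste(object@markers, collapse = ", ")))
    print(round(object@centers, 3))
})

#' @rdname ConsensusResult-class
#' @export
setMethod("pacValues", "ConsensusResult", function(x) x@pac)

#' @rdname ConsensusResult-class
#' @export
setMethod("chosenK", "ConsensusResult", function(x) x@chosenK)

#' @rdname ConsensusResult-class
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
    m <- x@matrices[[as.character(k)]]
    if (is.null(m))
        stop("no consensus matrix stored for k = ", k,
             " (re-run with keepMatrices = TRUE)")
    m
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult over k =", paste(range(object@ks), collapse = ".."),
        sprintf("(%d reps, %.0f%% subsampling)\n",
                object@reps, 100 * object@fraction))
    print(round(object@pac, 4))
    cat("chosen k:", object@chosenK, "\n")
})

setMethod("show", "EscoreModel", function(object) {
    cat(sprintf("EscoreModel (%s): score = %.3f * %%C5&6 %+.3f * %%C2&4\n",
                object@source, object@slopeC56, object@slopeC24))
    cat(sprintf("  high risk iff score > %.3f  (probability > %.3f)\n",
                object@linearThreshold, object@baseRate))
})

setMethod("show", "CohortConfig", function(object) {
    cat("CohortConfig:", object@nPatients, "patients,",
        sprintf("BCE fraction %.3f, mode %s, seed %d\n",
                object@bceFraction, object@outcomeMode, object@seed))
})
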