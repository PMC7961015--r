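#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @import SummarizedExperiment
NULL

## Canonical marker order used for clustering throughout the package.
CLUSTERING_MARKERS <- c("ER", "HER2", "cMET", "SLC7A5")

## Markers summarised by median *nuclear* intensity; everything else uses the
## median over the whole cell.
NUCLEAR_MARKERS <- c("ER", "PR", "p21", "Ki67")

#' Marker panel definition
#'
#' Maps each marker of an iterative-staining (MxIF) panel to its staining
#' round, its per-cell summarisation (median nuclear vs median whole-cell
#' intensity) and its analysis role. The panel also carries the nominal
#' (reference) exposure time of each round, which makes exposure correction
#' deterministic rather than data-dependent.
#'
#' @slot markers data.frame with columns \code{marker}, \code{round},
#'   \code{summarization} (\code{"nuclear_median"} or \code{"cell_median"})
#'   and \code{role} (\code{"clustering"}, \code{"univariate_only"},
#'   \code{"segmentation_only"} or \code{"excluded"}).
#' @slot referenceExposure named numeric vector of nominal exposure times in
#'   milliseconds, one per staining round (names are round numbers).
#'
#' @seealso [markerPanel()], [defaultPanel()]
#' @export
setClass("MarkerPanel",
    slots = c(markers = "data.frame", referenceExposure = "numeric"))

setValidity("MarkerPanel", function(object) {
    m <- object@markers
    need <- c("marker", "round", "summarization", "role")
    if (!all(need %in% names(m)))
        return(paste("markers must have columns:", paste(need, collapse = ", ")))
    if (anyDuplicated(m$marker))
        return("duplicated marker names")
    if (!all(m$summarization %in% c("nuclear_median", "cell_median")))
        return("summarization must be 'nuclear_median' or 'cell_median'")
    if (!all(m$role %in% c("clustering", "univariate_only",
                           "segmentation_only", "excluded")))
        return("invalid role")
    ## nuclear markers must use the nuclear median; everything else the
    ## whole-cell median
    nuc <- m$marker %in% NUCLEAR_MARKERS
    if (any(m$summarization[nuc] != "nuclear_median"))
        return("ER, PR, p21 and Ki67 must use nuclear_median summarization")
    ana <- m$role %in% c("clustering", "univariate_only")
    if (any(m$summarization[!nuc & ana] != "cell_median"))
        return("non-nuclear analysis markers must use cell_median summarization")
    if ("EGFR" %in% m$marker && m$role[m$marker == "EGFR"] != "excluded")
        return("EGFR must have role 'excluded'")
    cl <- m$marker[m$role == "clustering"]
    if (length(cl) && !setequal(cl, CLUSTERING_MARKERS))
        return("clustering markers must be exactly ER, HER2, cMET, SLC7A5")
    rounds <- unique(m$round)
    if (!all(as.character(rounds) %in% names(object@referenceExposure)))
        return("referenceExposure must name every staining round")
    if (any(object@referenceExposure <= 0))
        return("reference exposures must be positive")
    TRUE
})

#' Cell-level quality-control criteria
#'
#' Thresholds of the cell, field-of-view and patient filters. Defaults encode
#' the published filtering rules: epithelial cells with 1--2 nuclei, all
#' sub-cellular compartment areas strictly between 10 and 1500 pixels, a
#' perfect per-round registration score, fields with a DCIS fraction of at
#' least 0.5, at least 100 cells per patient, non-event patients followed for
#' at least 3 years and event patients with events before 10 years.
#'
#' @slot nucleiMin,nucleiMax integer bounds (inclusive) on nuclei per cell.
#' @slot areaMinPx,areaMaxPx exclusive pixel bounds on each compartment area.
#' @slot registrationThreshold minimum registration summary score (the
#'   minimum correlation across staining rounds).
#' @slot registrationTol numeric tolerance applied to the registration
#'   threshold, because empirical correlations rarely equal 1 exactly.
#' @slot dcisFractionMin minimum \code{pctDcis/(pctDcis + pctNormal)};
#'   fields at exactly this boundary are retained.
#' @slot minCellsPerPatient minimum retained cells per patient.
#' @slot nonBceMinFollowupYears minimum follow-up for non-event patients.
#' @slot bceMaxFollowupYears exclusive upper bound on time-to-event for
#'   event patients.
#' @export
setClass("QcCriteria",
    slots = c(nucleiMin = "numeric", nucleiMax = "numeric",
              areaMinPx = "numeric", areaMaxPx = "numeric",
              registrationThreshold = "numeric", registrationTol = "numeric",
              dcisFractionMin = "numeric", minCellsPerPatient = "numeric",
              nonBceMinFollowupYears = "numeric",
              bceMaxFollowupYears = "numeric"),
    prototype = list(nucleiMin = 1, nucleiMax = 2, areaMinPx = 10,
                     areaMaxPx = 1500, registrationThreshold = 1.0,
                     registrationTol = 1e-9, dcisFractionMin = 0.5,
                     minCellsPerPatient = 100, nonBceMinFollowupYears = 3,
                     bceMaxFollowupYears = 10))

setValidity("QcCriteria", function(object) {
    if (object@nucleiMin > object@nucleiMax) return("nucleiMin > nucleiMax")
    if (object@areaMinPx >= object@areaMaxPx) return("areaMinPx >= areaMaxPx")
    if (object@registrationThreshold < 0 || object@registrationThreshold > 1)
        return("registrationThreshold must lie in [0, 1]")
    if (object@dcisFractionMin < 0 || object@dcisFractionMin > 1)
        return("dcisFractionMin must lie in [0, 1]")
    TRUE
})

#' Filtering audit trail
#'
#' Records, for each filtering stage, how many records entered, how many were
#' excluded and how many remain, together with per-rule exclusion tallies.
#' A record may violate several rules at once; the per-rule tallies count
#' each violated rule, so they can sum to more than the number of excluded
#' records. Stage conservation (input - excluded = output) is enforced by the
#' class validity.
#'
#' @slot stages data.frame with columns \code{stage}, \code{input},
#'   \code{excluded}, \code{output}.
#' @slot rules data.frame with columns \code{stage}, \code{rule},
#'   \code{count}.
#' @export
setClass("FilterAudit",
    slots = c(stages = "data.frame", rules = "data.frame"))

setValidity("FilterAudit", function(object) {
    s <- object@stages
    if (!all(c("stage", "input", "excluded", "output") %in% names(s)))
        return("stages must have columns stage, input, excluded, output")
    if (any(s$input - s$excluded != s$output))
        return("stage conservation violated: input - excluded != output")
    if (nrow(s) > 1L && any(s$output[-nrow(s)] != s$input[-1L]))
        return("stages do not compose: output of stage k != input of stage k+1")
    TRUE
})

#' Container for segmented MxIF cells
#'
#' A [SummarizedExperiment::SummarizedExperiment] with two assays of raw
#' marker intensities per segmented cell -- \code{"nuclear"} (median nuclear
#' intensity) and \code{"cell"} (median whole-cell intensity), markers in
#' rows and cells in columns -- plus per-cell metadata in \code{colData}
#' (identifiers, tissue class, nuclei count, compartment areas, per-round
#' registration scores \code{reg_r<round>} and actual exposure times
#' \code{exp_r<round>}). The [MarkerPanel] travels in \code{metadata(x)$panel}.
#'
#' @export
setClass("MxifCellSet", contains = "SummarizedExperiment")

setValidity("MxifCellSet", function(object) {
    if (!all(c("nuclear", "cell") %in% assayNames(object)))
        return("assays 'nuclear' and 'cell' are required")
    need <- c("cell_id", "patient_id", "slide_id", "fov_id", "core_id",
              "tissue_class", "n_nuclei", "area_nucleus_px",
              "area_membrane_px", "area_cytoplasm_px")
    miss <- setdiff(need, colnames(colData(object)))
    if (length(miss))
        return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    pan <- metadata(object)$panel
    if (is.null(pan) || !is(pan, "MarkerPanel"))
        return("metadata(x)$panel must be a MarkerPanel")
    TRUE
})

#' Fitted k-means model
#'
#' @slot k number of clusters.
#' @slot centers k x p matrix of centroids in the (standardised) marker
#'   space; row names are cluster labels.
#' @slot markers marker (column) order the model was fitted on.
#' @slot n number of cells the model was fitted on.
#' @slot seed RNG seed used for the fit.
#' @slot totWithinSS total within-cluster sum of squares of the best restart.
#' @export
setClass("ClusterModel",
    slots = c(k = "integer", centers = "matrix", markers = "character",
              n = "integer", seed = "integer", totWithinSS = "numeric"))

setValidity("ClusterModel", function(object) {
    if (object@k < 2L) return("k must be >= 2")
    if (nrow(object@centers) != object@k) return("centers must have k rows")
    if (anyDuplicated.matrix(object@centers) > 0)
        return("centroids must be pairwise distinct")
    TRUE
})

#' Consensus clustering result
#'
#' Per candidate k: the PAC (proportion of ambiguously clustered pairs) and,
#' optionally, the consensus matrix whose entry (i, j) is the fraction of
#' subsamples containing both cells i and j in which they were co-clustered
#' (NA when the pair was never co-sampled; diagonal 1).
#'
#' @slot ks candidate numbers of clusters.
#' @slot pac named numeric vector of PAC values, one per k.
#' @slot matrices named list of consensus matrices (possibly empty, for
#'   large inputs where storing n x n matrices per k is wasteful).
#' @slot chosenK the k minimising PAC (ties go to the smallest k).
#' @slot fraction subsampling fraction.
#' @slot reps number of subsampling repetitions per k.
#' @slot seed RNG seed.
#' @export
setClass("ConsensusResult",
    slots = c(ks = "integer", pac = "numeric", matrices = "list",
              chosenK = "integer", fraction = "numeric", reps = "integer",
              seed = "integer"))

setValidity("ConsensusResult", function(object) {
    if (length(object@pac) != length(object@ks))
        return("one PAC value per candidate k required")
    ok <- is.na(object@pac) | (object@pac >= 0 & object@pac <= 1)
    if (!all(ok)) return("PAC values must lie in [0, 1]")
    for (m in object@matrices) {
        if (!isSymmetric.matrix(unname(m), tol = 1e-12))
            return("consensus matrices must be symmetric")
        v <- m[!is.na(m)]
        if (length(v) && (min(v) < 0 || max(v) > 1))
            return("consensus entries must lie in [0, 1]")
    }
    TRUE
})

#' Logistic Escore risk model
#'
#' Linear risk score over patient cluster profiles:
#' \deqn{Escore = b_{56} \cdot \%C5\&6 + b_{24} \cdot \%C2\&4}
#' with covariates on the 0--100 percentage scale. A patient is high risk
#' when the score strictly exceeds \code{linearThreshold}. Thresholding the
#' predicted probability at the cohort base rate is equivalent to
#' thresholding the linear score at \code{qlogis(baseRate) - intercept};
#' this equivalence is enforced by the class validity.
#'
#' @slot slopeC56 coefficient on the percentage of cells in clusters 5 and 6.
#' @slot slopeC24 coefficient on the percentage of cells in clusters 2 and 4.
#' @slot intercept logistic intercept.
#' @slot baseRate probability threshold (cohort event rate).
#' @slot linearThreshold cut on the linear score for the high-risk call.
#' @slot source \code{"fitted"} or \code{"published"}.
#' @seealso [fitEscore()], [publishedEscoreModel()], [escore()]
#' @export
setClass("EscoreModel",
    slots = c(slopeC56 = "numeric", slopeC24 = "numeric",
              intercept = "numeric", baseRate = "numeric",
              linearThreshold = "numeric", source = "character"))

setValidity("EscoreModel", function(object) {
    if (object@baseRate <= 0 || object@baseRate >= 1)
        return("baseRate must lie strictly inside (0, 1)")
    thr <- stats::qlogis(object@baseRate) - object@intercept
    if (abs(thr - object@linearThreshold) > 1e-8)
        return("linearThreshold must equal logit(baseRate) - intercept")
    TRUE
})

#' Synthetic cohort configuration
#'
#' All knobs of the synthetic MxIF cohort generator. See [cohortConfig()]
#' for defaults and units; every random draw of the generator flows from the
#' single \code{seed}.
#'
#' @export
setClass("CohortConfig",
    slots = c(nPatients = "integer", bceFraction = "numeric",
              cellsPerPatient = "numeric", groupProfileMeans = "matrix",
              profileConcentration = "numeric", outcomeMode = "character",
              logisticParams = "numeric", nSlides = "integer",
              slideOffsets = "numeric", exposureTimes = "numeric",
              artifactRates = "numeric", followupModel = "list",
              nBackgroundMarkers = "integer", coresPerPatient = "integer",
              fovsPerCore = "integer", stromalFraction = "numeric",
              erPrCorrelation = "numeric", archetypes = "list",
              markerLog2Mean = "numeric", markerLog2Sd = "numeric",
              seed = "integer"))

setValidity("CohortConfig", function(object) {
    if (object@nPatients < 1L) return("invalid field nPatients: must be >= 1")
    if (object@bceFraction < 0 || object@bceFraction > 1)
        return("invalid field bceFraction: must lie in [0, 1]")
    if (object@cellsPerPatient[["mean"]] < 1)
        return("invalid field cellsPerPatient: mean must be >= 1")
    gm <- object@groupProfileMeans
    if (!all(dim(gm) == c(2L, 6L)))
        return("invalid field groupProfileMeans: must be a 2 x 6 matrix")
    if (any(abs(rowSums(gm) - 1) > 1e-9))
        return("invalid field groupProfileMeans: rows must sum to 1")
    if (any(gm < 0))
        return("invalid field groupProfileMeans: entries must be >= 0")
    if (object@profileConcentration <= 0)
        return("invalid field profileConcentration: must be > 0")
    if (!object@outcomeMode %in% c("group_conditional", "logistic"))
        return("invalid field outcomeMode")
    if (any(object@artifactRates < 0 | object@artifactRates > 1))
        return("invalid field artifactRates: fractions must lie in [0, 1]")
    if (object@stromalFraction < 0 || object@stromalFraction > 1)
        return("invalid field stromalFraction: must lie in [0, 1]")
    if (length(object@slideOffsets) != object@nSlides)
        return("invalid field slideOffsets: one offset per slide required")
    if (abs(object@erPrCorrelation) > 1)
        return("invalid field erPrCorrelation: must lie in [-1, 1]")
    arch <- object@archetypes
    if (!all(c("meanZ", "sdZ") %in% names(arch)))
        return("invalid field archetypes: needs meanZ and sdZ")
    if (any(arch$sdZ <= 0))
        return("invalid field archetypes: sdZ must be strictly positive")
    if (anyDuplicated(apply(sign(arch$meanZ), 1L, paste, collapse = "/")))
        return("invalid field archetypes: high/low sign patterns must differ")
    TRUE
})
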