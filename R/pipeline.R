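withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages end to end: synthetic cohort generation (or a
#' supplied cohort), field-of-view and cell QC, preprocessing, clustering
#' of all post-QC cells, patient-level outcome exclusions, univariate
#' marker screen, patient cluster profiles with the Escore model, and the
#' Kaplan-Meier / log-rank analysis of the binary risk groups. Mirrors the
#' published workflow order, in which all nucleated epithelial cells are
#' clustered and the patient-level exclusions apply only to the outcome
#' analysis.
#'
#' Consensus selection of k runs on a random subsample of at most
#' \code{consensusCells} cells (pair-count matrices are quadratic in cell
#' count); the final k-means fit always uses all post-QC cells.
#'
#' @param config a [CohortConfig] for the synthetic cohort.
#' @param cohort optional pre-generated cohort (as from [generateCohort()]);
#'   when supplied, \code{config} is ignored for generation.
#' @param criteria a [QcCriteria].
#' @param kRange candidate k for consensus selection.
#' @param useConsensus if FALSE, skip consensus and use \code{fixedK}.
#' @param fixedK number of clusters when \code{useConsensus = FALSE}.
#' @param consensusCells subsample size cap for consensus clustering.
#' @param consensusReps subsampling repetitions per k.
#' @param escoreModel \code{"fit"} to fit the logistic model on this
#'   cohort, or \code{"published"} for the frozen published coefficients.
#' @param outDir optional output directory; when given, every stage writes
#'   its tables as it completes (partial outputs are retained on failure).
#' @param seed seed for the clustering stages (cohort generation uses
#'   \code{config@seed}).
#' @return a run report: list with audits, stage outputs and metrics.
#' @export
runPipeline <- function(config = cohortConfig(),
                        cohort = NULL,
                        criteria = qcCriteria(),
                        kRange = 2:15,
                        useConsensus = FALSE,
                        fixedK = 6L,
                        consensusCells = 5000L,
                        consensusReps = 50L,
                        escoreModel = c("fit", "published"),
                        outDir = NULL,
                        seed = 1L) {
    escoreModel <- match.arg(escoreModel)
    report <- list(seed = seed)
    emit <- function(name, df) {
        if (!is.null(outDir)) {
            dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
            writeTsv(df, file.path(outDir, paste0(name, ".tsv")))
        }
    }

    ## ---- simulate -------------------------------------------------------
    cohort <- withStage("simulate", {
        if (is.null(cohort)) generateCohort(config) else cohort
    })
    cells <- cohort$cells
    patients <- cohort$patients
    report$nCellsSegmented <- ncol(cells)

    ## ---- qc -------------------------------------------------------------
    qc <- withStage("qc", {
        fv <- filterFovs(cohort$fovs, criteria)
        inFov <- colData(cells)$fov_id %in% fv$fovs$fov_id
        fovCellAudit <- filterAudit("cells_in_excluded_fovs",
                                    ncol(cells), sum(!inFov), sum(inFov),
                                    list(excluded_fov = sum(!inFov)))
        cellsInFov <- cells[, inFov]
        fc <- filterCells(cellsInFov, criteria)
        list(cells = fc$cells, fovs = fv$fovs,
             fovAudit = fv$audit,
             cellAudit = combineAudits(fovCellAudit, fc$audit))
    })
    message(sprintf("qc: %d of %d cells retained", ncol(qc$cells),
                    ncol(cells)))
    report$fovAudit <- auditStages(qc$fovAudit)
    emit("audit_fovs", report$fovAudit)

    ## ---- preprocess -----------------------------------------------------
    normalized <- withStage("preprocess", preprocessCells(qc$cells))

    ## ---- cluster (all post-QC cells) ------------------------------------
    clu <- withStage("cluster", {
        std <- standardizeClusteringMarkers(normalized)
        if (useConsensus) {
            idx <- if (nrow(std$x) > consensusCells)
                withr::with_seed(seed, sort(sample.int(nrow(std$x),
                                                       consensusCells)))
            else seq_len(nrow(std$x))
            cons <- consensusCluster(std$x[idx, , drop = FALSE],
                                     kRange = kRange, reps = consensusReps,
                                     seed = seed, keepMatrices = FALSE)
            k <- chosenK(cons)
        } else {
            cons <- NULL
            k <- as.integer(fixedK)
        }
        model <- kmeansFit(std$x, k, seed = seed + 1L)
        if (k == nrow(config@archetypes$meanZ))
            model <- canonicalizeLabels(model, config@archetypes)$model
        assignments <- assignClusters(model, std$x)
        list(std = std, consensus = cons, k = k, model = model,
             assignments = assignments)
    })
    report$pac <- if (!is.null(clu$consensus)) pacValues(clu$consensus)
    report$chosenK <- clu$k
    asg <- data.frame(cell_id = colnames(normalized),
                      cluster = clu$assignments)
    emit("assignments", asg)

    ## ---- patient-level outcome exclusions -------------------------------
    outcome <- withStage("patient_filter", {
        fp <- filterPatients(patients, qc$cells, criteria)
        keepCell <- colData(qc$cells)$patient_id %in% fp$patients$patient_id
        patCellAudit <- filterAudit("cells_of_excluded_patients",
                                    ncol(qc$cells), sum(!keepCell),
                                    sum(keepCell),
                                    list(excluded_patient = sum(!keepCell)))
        list(patients = fp$patients, audit = fp$audit,
             keepCell = keepCell,
             cellAudit = combineAudits(qc$cellAudit, patCellAudit))
    })
    report$cellAudit <- auditStages(outcome$cellAudit)
    report$patientAudit <- auditStages(outcome$audit)
    report$nCellsOutcome <- sum(outcome$keepCell)
    emit("audit_cells", report$cellAudit)
    emit("audit_patients", report$patientAudit)
    message(sprintf("outcome analysis: %d patients, %d cells",
                    nrow(outcome$patients), report$nCellsOutcome))

    pat <- outcome$patients
    bce <- as.logical(pat$bce)

    ## ---- univariate screen ----------------------------------------------
    report$univariate <- withStage("univariate", {
        normOut <- normalized[, outcome$keepCell]
        pv <- aggregatePatients(normOut)
        pv <- pv[pat$patient_id, , drop = FALSE]
        compareGroups(pv, bce)
    })
    emit("univariate", report$univariate)

    ## ---- profiles + Escore ----------------------------------------------
    esc <- withStage("escore", {
        ids <- colData(qc$cells)$patient_id[outcome$keepCell]
        profiles <- clusterProfile(clu$assignments[outcome$keepCell],
                                   ids, k = clu$k)
        profiles <- profiles[pat$patient_id, , drop = FALSE]
        model <- if (escoreModel == "fit") fitEscore(profiles, bce)
                 else publishedEscoreModel()
        scores <- escore(profiles, model)
        metrics <- evaluateModel(scores, bce, model)
        cv <- loocvEscore(profiles, bce)
        list(profiles = profiles, model = model, scores = scores,
             classes = classifyRisk(scores, model),
             metrics = metrics, loocv = cv)
    })
    report$escoreModel <- esc$model
    report$metrics <- esc$metrics
    report$loocvAuc <- esc$loocv$auc
    pred <- data.frame(patient_id = pat$patient_id,
                       pctC56 = escoreCovariates(esc$profiles)$pctC56,
                       pctC24 = escoreCovariates(esc$profiles)$pctC24,
                       score = unname(esc$scores),
                       probability = unname(
                           escoreProbability(esc$profiles, esc$model)),
                       class = as.character(esc$classes))
    emit("predictions", pred)
    emit("profiles", data.frame(patient_id = rownames(esc$profiles),
                                bce = bce, esc$profiles,
                                check.names = FALSE))
    if (!is.null(outDir))
        writeEscoreModel(esc$model, file.path(outDir, "escore_model.json"))

    ## ---- survival --------------------------------------------------------
    report$survival <- withStage("survival", {
        lr <- logrankTest(pat$followup_years, bce, esc$classes)
        km <- lapply(split(seq_len(nrow(pat)), esc$classes), function(ix)
            if (length(ix)) kmEstimate(pat$followup_years[ix], bce[ix]))
        list(logrank = lr, km = km)
    })
    if (!is.null(outDir)) {
        jsonlite::write_json(
            list(seed = seed, chosenK = report$chosenK,
                 metrics = report$metrics, loocvAuc = report$loocvAuc,
                 logrank = report$survival$logrank),
            file.path(outDir, "metrics.json"),
            digits = NA, auto_unbox = TRUE)
    }
    report$profiles <- esc$profiles
    report$assignments <- clu$assignments
    report$model <- clu$model
    report
}
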