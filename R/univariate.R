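#' Patient-level marker aggregation
#'
#' Aggregates per-cell summarised (median) intensities to one value per
#' patient per marker by the arithmetic mean.
#'
#' @param normalized SummarizedExperiment from [preprocessCells()], or a
#'   marker x cell matrix.
#' @param patientIds patient identifier per cell (taken from
#'   \code{colData} when a SummarizedExperiment is supplied).
#' @return patients x markers matrix of mean intensities.
#' @export
aggregatePatients <- function(normalized, patientIds = NULL) {
    mat <- if (is(normalized, "SummarizedExperiment")) {
        if (is.null(patientIds))
            patientIds <- colData(normalized)$patient_id
        assay(normalized, "normalized")
    } else normalized
    if (is.null(patientIds) || length(patientIds) != ncol(mat))
        stop("one patient id per cell required")
    if (any(table(patientIds) < 1L)) stop("each patient needs >= 1 cell")
    t(vapply(split(seq_along(patientIds), patientIds),
             function(ix) rowMeans(mat[, ix, drop = FALSE]),
             numeric(nrow(mat))))
}

#' Two-group marker screen with FDR control
#'
#' Welch two-sample t-test of patient-level marker means between outcome
#' groups, with Benjamini-Hochberg control of the false discovery rate at
#' \code{q} (default 0.2) across markers.
#'
#' @param patientValues patients x markers matrix from
#'   [aggregatePatients()].
#' @param outcomes logical event indicator per patient (TRUE = BCE), in
#'   row order of \code{patientValues}.
#' @param q false discovery rate.
#' @return data.frame with columns \code{marker}, \code{meanBce},
#'   \code{meanNonBce}, \code{t}, \code{p}, \code{significant}.
#' @export
compareGroups <- function(patientValues, outcomes, q = 0.2) {
    outcomes <- as.logical(outcomes)
    if (length(outcomes) != nrow(patientValues))
        stop("one outcome per patient required")
    if (sum(outcomes) < 2L || sum(!outcomes) < 2L)
        stop("each outcome group needs at least 2 patients")
    res <- do.call(rbind, lapply(colnames(patientValues), function(m) {
        x <- patientValues[outcomes, m]
        y <- patientValues[!outcomes, m]
        if (stats::sd(c(x, y)) == 0) {
            tt <- list(statistic = 0, p.value = 1)
        } else {
            tt <- stats::t.test(x, y, var.equal = FALSE,
                                alternative = "two.sided")
        }
        data.frame(marker = m, meanBce = mean(x), meanNonBce = mean(y),
                   t = unname(tt$statistic), p = tt$p.value,
                   stringsAsFactors = FALSE)
    }))
    res$significant <- bhSelect(res$p, q)
    res
}

#' Benjamini-Hochberg selection
#'
#' Standard step-up procedure: with p-values sorted ascending, find the
#' largest i with \code{p(i) <= i * q / m} and reject hypotheses 1..i.
#' Implemented through [stats::p.adjust()], whose BH adjustment is
#' equivalent to the step-up rule.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param q false discovery rate.
#' @return logical vector: TRUE where the hypothesis is rejected.
#' @export
bhSelect <- function(p, q = 0.2) {
    if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH") <= q
}
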