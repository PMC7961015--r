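#' Patient cluster profiles
#'
#' The compositional profile of each patient: the fraction of that
#' patient's cells assigned to each of the k clusters (absent clusters get
#' 0). Profiles sum to 1 by construction.
#'
#' @param assignments integer cluster label per cell.
#' @param patientIds patient identifier per cell.
#' @param k number of clusters.
#' @return patients x k matrix of proportions.
#' @export
clusterProfile <- function(assignments, patientIds, k = 6L) {
    if (length(assignments) != length(patientIds))
        stop("one assignment per cell required")
    if (!length(assignments))
        stop("no cells: every patient needs at least one assigned cell")
    tab <- table(factor(patientIds),
                 factor(assignments, levels = seq_len(k)))
    prof <- unclass(tab / rowSums(tab))
    dimnames(prof) <- list(rownames(tab), as.character(seq_len(k)))
    prof
}

## the two Escore covariates, on the 0-100 percentage scale
escoreCovariates <- function(profiles) {
    stopifnot(ncol(profiles) >= 6L)
    data.frame(
        pctC56 = 100 * (profiles[, 5] + profiles[, 6]),
        pctC24 = 100 * (profiles[, 2] + profiles[, 4]),
        row.names = NULL)
}

#' The published Escore model
#'
#' The frozen published risk model: score = 1.77 * \%C5&6 - 2.78 * \%C2&4,
#' high risk when the score exceeds 13, equivalent to thresholding the
#' predicted probability at the cohort base rate 0.255 (13/51). The
#' unpublished intercept is derived from that equivalence
#' (\code{qlogis(0.255) - 13}).
#'
#' @return an [EscoreModel].
#' @export
publishedEscoreModel <- function() {
    baseRate <- 13 / 51
    thr <- 13
    new("EscoreModel", slopeC56 = 1.77, slopeC24 = -2.78,
        intercept = stats::qlogis(baseRate) - thr,
        baseRate = baseRate, linearThreshold = thr,
        source = "published")
}

#' Fit the logistic Escore model
#'
#' Unpenalised maximum-likelihood logistic regression of the event on the
#' two percentage covariates \%C5&6 and \%C2&4, with intercept. The
#' probability threshold is the cohort base rate (mean outcome) and the
#' equivalent linear-score threshold is \code{qlogis(baseRate) -
#' intercept}. Constant covariates contribute slope 0 (intercept-only
#' limit); complete separation is reported as an error rather than fitted
#' silently.
#'
#' @param profiles patients x k (>= 6) matrix from [clusterProfile()].
#' @param outcomes logical event indicator per patient, in profile row
#'   order.
#' @return an [EscoreModel].
#' @export
fitEscore <- function(profiles, outcomes) {
    outcomes <- as.logical(outcomes)
    if (length(outcomes) != nrow(profiles))
        stop("one outcome per patient required")
    if (!any(outcomes) || all(outcomes))
        stop("both outcomes must be present to fit the model")
    cov <- escoreCovariates(profiles)
    dat <- data.frame(y = outcomes, cov)
    suspect <- FALSE
    fit <- withCallingHandlers(
        stats::glm(y ~ pctC56 + pctC24, family = stats::binomial(),
                   data = dat),
        warning = function(w) {
            if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                      conditionMessage(w)))
                suspect <<- TRUE
            invokeRestart("muffleWarning")
        })
    co <- stats::coef(fit)
    co[is.na(co)] <- 0          # constant covariate: intercept-only limit
    ## if the fitted direction separates the outcomes completely, the ML
    ## estimate does not exist (the likelihood increases without bound);
    ## glm's stopping tolerance can mask this without any warning
    eta <- co[1] + co[2] * dat$pctC56 + co[3] * dat$pctC24
    if ((co[2] != 0 || co[3] != 0) &&
        max(eta[!outcomes]) < min(eta[outcomes]))
        stop("complete separation: the maximum-likelihood logistic fit ",
             "does not exist. Inspect the covariates, reduce the ",
             "profile separation, or use the published model instead.")
    if (!fit$converged)
        stop("logistic fit did not converge")
    baseRate <- mean(outcomes)
    new("EscoreModel", slopeC56 = unname(co["pctC56"]),
        slopeC24 = unname(co["pctC24"]),
        intercept = unname(co["(Intercept)"]),
        baseRate = baseRate,
        linearThreshold = stats::qlogis(baseRate) - unname(co["(Intercept)"]),
        source = "fitted")
}

#' Linear Escore of patient profiles
#'
#' \code{slopeC56 * \%C5&6 + slopeC24 * \%C2&4} on the 0--100 percentage
#' scale.
#'
#' @param profiles patients x k (>= 6) proportion matrix, or a single
#'   profile vector.
#' @param model an [EscoreModel].
#' @return numeric score per patient.
#' @export
escore <- function(profiles, model = publishedEscoreModel()) {
    if (is.null(dim(profiles))) profiles <- rbind(profiles)
    cov <- escoreCovariates(profiles)
    stats::setNames(
        model@slopeC56 * cov$pctC56 + model@slopeC24 * cov$pctC24,
        rownames(profiles))
}

#' @describeIn escore predicted event probability,
#'   \code{plogis(intercept + score)}.
#' @export
escoreProbability <- function(profiles, model = publishedEscoreModel()) {
    stats::plogis(model@intercept + escore(profiles, model))
}

#' Binary risk classification
#'
#' High risk iff the linear score strictly exceeds the model's threshold
#' (a score exactly at the threshold is low risk). Equivalent to comparing
#' the predicted probability against the base rate.
#'
#' @param scores numeric Escore values.
#' @param model an [EscoreModel].
#' @return factor with levels \code{low}, \code{high}.
#' @export
classifyRisk <- function(scores, model = publishedEscoreModel()) {
    if (any(!is.finite(scores))) stop("scores must be finite")
    factor(ifelse(scores > model@linearThreshold, "high", "low"),
           levels = c("low", "high"))
}

## midrank Mann-Whitney AUC; ties contribute 1/2
aucMannWhitney <- function(scores, outcomes) {
    outcomes <- as.logical(outcomes)
    n1 <- sum(outcomes); n0 <- sum(!outcomes)
    if (n1 == 0L || n0 == 0L) stop("both outcomes required for AUC")
    r <- rank(scores)
    (sum(r[outcomes]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics at the model threshold
#'
#' Confusion counts of the binary risk call against the observed outcome,
#' sensitivity, specificity, error rate, and the AUC of the continuous
#' score (midrank Mann-Whitney statistic; ties count 1/2).
#'
#' @param scores numeric Escore values per patient.
#' @param outcomes logical event indicator per patient.
#' @param model an [EscoreModel].
#' @return list with \code{tp}, \code{fn}, \code{tn}, \code{fp},
#'   \code{sensitivity}, \code{specificity}, \code{errorRate}, \code{auc}.
#' @export
evaluateModel <- function(scores, outcomes, model = publishedEscoreModel()) {
    outcomes <- as.logical(outcomes)
    if (!any(outcomes) || all(outcomes))
        stop("at least one patient of each outcome required")
    cls <- classifyRisk(scores, model)
    tp <- sum(cls == "high" & outcomes)
    fn <- sum(cls == "low" & outcomes)
    tn <- sum(cls == "low" & !outcomes)
    fp <- sum(cls == "high" & !outcomes)
    list(tp = tp, fn = fn, tn = tn, fp = fp,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         errorRate = (fp + fn) / length(outcomes),
         auc = aucMannWhitney(scores, outcomes))
}

#' Leave-one-out cross-validation of the Escore model
#'
#' Each patient is held out in turn, the logistic model refit on the
#' remaining patients (cluster assignments stay fixed; only the regression
#' is refit), and the held-out predicted probability recorded. The LOOCV
#' AUC pools the held-out probabilities. Folds whose refit fails to
#' converge are flagged and excluded from the AUC.
#'
#' @param profiles patients x k (>= 6) proportion matrix.
#' @param outcomes logical event indicator per patient.
#' @return list with \code{probabilities} (held-out, NA for failed folds),
#'   \code{auc}, \code{nFolds}, \code{failedFolds}.
#' @export
loocvEscore <- function(profiles, outcomes) {
    outcomes <- as.logical(outcomes)
    n <- nrow(profiles)
    if (n < 10L) stop("LOOCV requires at least 10 patients")
    probs <- rep(NA_real_, n)
    failed <- integer(0)
    for (i in seq_len(n)) {
        m <- tryCatch(fitEscore(profiles[-i, , drop = FALSE], outcomes[-i]),
                      error = function(e) NULL)
        if (is.null(m)) { failed <- c(failed, i); next }
        probs[i] <- escoreProbability(profiles[i, , drop = FALSE], m)
    }
    ok <- !is.na(probs)
    auc <- if (any(outcomes[ok]) && any(!outcomes[ok]))
        aucMannWhitney(probs[ok], outcomes[ok]) else NA_real_
    list(probabilities = stats::setNames(probs, rownames(profiles)),
         auc = auc, nFolds = n, failedFolds = failed)
}

#' Risk-class concordance across duplicate tissue cores
#'
#' Classifies each core of each multi-core patient separately and reports
#' whether all cores of a patient land in the same risk class.
#'
#' @param profiles cores x k (>= 6) proportion matrix (one row per core).
#' @param patientIds patient identifier per core.
#' @param model an [EscoreModel].
#' @return list with \code{table} (patient, core count, classes, concordant
#'   flag) and \code{concordance} (fraction of multi-core patients whose
#'   cores agree).
#' @export
coreConcordance <- function(profiles, patientIds,
                            model = publishedEscoreModel()) {
    if (length(patientIds) != nrow(profiles))
        stop("one patient id per core required")
    cls <- classifyRisk(escore(profiles, model), model)
    split_ <- split(as.character(cls), patientIds)
    multi <- Filter(function(v) length(v) >= 2L, split_)
    if (!length(multi))
        stop("at least one patient with >= 2 cores required")
    tab <- data.frame(
        patient_id = names(multi),
        nCores = vapply(multi, length, integer(1)),
        classes = vapply(multi, paste, character(1), collapse = "/"),
        concordant = vapply(multi, function(v) length(unique(v)) == 1L,
                            logical(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    list(table = tab, concordance = mean(tab$concordant))
}
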