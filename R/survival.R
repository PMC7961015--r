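#' Kaplan-Meier estimate of the disease-free interval
#'
#' Product-limit estimator via [survival::survfit()]. Survival starts at 1
#' and is non-increasing; censored times reduce the risk set only. At tied
#' times the event is handled before the censoring (the standard risk-set
#' convention of the product-limit estimator).
#'
#' @param time years to event or censoring (> 0).
#' @param event logical: TRUE if the breast cancer event occurred.
#' @return data.frame with columns \code{time}, \code{nRisk},
#'   \code{nEvent}, \code{nCensor}, \code{surv}.
#' @export
kmEstimate <- function(time, event) {
    if (!length(time)) stop("at least one record required")
    if (any(time <= 0)) stop("times must be > 0")
    fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                             conf.type = "none")
    data.frame(time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
               nCensor = fit$n.censor, surv = fit$surv)
}

#' Two-group log-rank test
#'
#' Standard log-rank test (hypergeometric variance) of the disease-free
#' interval between the two Escore risk groups, via
#' [survival::survdiff()].
#'
#' @param time years to event or censoring.
#' @param event logical event indicator.
#' @param group two-level grouping (e.g. the binary risk class).
#' @return list with \code{chisq}, \code{df}, \code{p}.
#' @export
logrankTest <- function(time, event, group) {
    group <- as.factor(group)
    group <- droplevels(group)
    if (nlevels(group) != 2L) stop("exactly 2 groups required")
    ## survdiff errors on degenerate data with no events; the statistic is
    ## then 0 by definition (no observed-minus-expected contributions)
    if (!any(as.integer(event) == 1L))
        return(list(chisq = 0, df = 1L, p = 1))
    sd <- survival::survdiff(
        survival::Surv(time, as.integer(event)) ~ group)
    df <- length(sd$n) - 1L
    list(chisq = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}
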