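#' Exposure-time correction
#'
#' Rescales a raw intensity acquired at `exposureMs` to the intensity it
#' would have had at the round's nominal reference exposure, assuming a
#' linear detector response: \code{corrected = raw * referenceMs /
#' exposureMs}.
#'
#' @param raw raw intensity (>= 0); vectorised.
#' @param exposureMs actual exposure time in ms (> 0).
#' @param referenceMs nominal reference exposure in ms (> 0).
#' @export
exposureCorrect <- function(raw, exposureMs, referenceMs) {
    if (any(exposureMs <= 0) || any(referenceMs <= 0))
        stop("exposure times must be positive")
    if (any(raw < 0)) stop("raw intensities must be >= 0")
    raw * referenceMs / exposureMs
}

#' log2 transform with pseudo-count
#'
#' \code{log2(x + offset)}; the offset (default 1) keeps zero intensities
#' finite and the transform monotone.
#'
#' @param x exposure-corrected intensity (>= 0).
#' @param offset positive pseudo-count.
#' @export
logTransform <- function(x, offset = 1) {
    if (offset <= 0) stop("offset must be > 0")
    log2(x + offset)
}

#' Remove slide batch effects by median centring
#'
#' Per marker, subtracts each slide's median and adds back the grand median
#' over all cells, so that after normalisation every slide has the same
#' median as the pooled data. Robust and rank-preserving within slide.
#'
#' @param values numeric vector (one marker) or matrix (markers x cells).
#' @param slide slide identifier per cell.
#' @return centred values, same shape as input.
#' @export
normalizeSlides <- function(values, slide) {
    if (is.matrix(values)) {
        out <- values
        for (i in seq_len(nrow(values)))
            out[i, ] <- normalizeSlides(values[i, ], slide)
        return(out)
    }
    slide <- as.character(slide)
    if (length(slide) != length(values))
        stop("one slide id per cell required")
    grand <- stats::median(values)
    for (s in unique(slide)) {
        sel <- slide == s
        if (!any(sel)) {
            warning("empty slide group '", s, "' skipped")
            next
        }
        values[sel] <- values[sel] - stats::median(values[sel]) + grand
    }
    values
}

#' Select the per-marker summarisation
#'
#' Picks, for every analysis marker, the nuclear median (ER, PR, p21, Ki67)
#' or the whole-cell median (all other markers), and drops markers whose
#' panel role is \code{"excluded"} or \code{"segmentation_only"}.
#'
#' @param nuclear,cell marker x cell matrices (any consistent scale).
#' @param panel a [MarkerPanel].
#' @return matrix with one row per analysis marker.
#' @export
summarizeCells <- function(nuclear, cell, panel) {
    keep <- analysisMarkers(panel)
    miss <- setdiff(keep, rownames(nuclear))
    if (length(miss))
        stop("marker(s) missing from intensity data: ",
             paste(miss, collapse = ", "))
    pm <- panel@markers
    out <- matrix(NA_real_, length(keep), ncol(nuclear),
                  dimnames = list(keep, colnames(nuclear)))
    for (m in keep) {
        summ <- pm$summarization[pm$marker == m]
        out[m, ] <- if (summ == "nuclear_median") nuclear[m, ] else cell[m, ]
    }
    out
}

#' Cap extreme values and standardise
#'
#' Winsorises a column at its 1st and 99th percentiles (linear-interpolation
#' quantiles) and standardises to zero mean and unit standard deviation
#' using the post-capping mean and sd. The capping bounds and moments are
#' returned so the identical transform can be applied to held-out cells.
#'
#' @param x numeric vector with at least 2 distinct values.
#' @param tail fraction capped on each side (default 0.01).
#' @return list with \code{values}, \code{lower}, \code{upper},
#'   \code{mean}, \code{sd}.
#' @export
capAndStandardize <- function(x, tail = 0.01) {
    if (length(unique(x)) < 2L)
        stop("degenerate data: column is constant (sd = 0)")
    q <- stats::quantile(x, c(tail, 1 - tail), names = FALSE, type = 7)
    x[x < q[1]] <- q[1]
    x[x > q[2]] <- q[2]
    m <- mean(x); s <- stats::sd(x)
    if (s == 0) stop("degenerate data: column is constant after capping")
    list(values = (x - m) / s, lower = q[1], upper = q[2],
         mean = m, sd = s)
}

#' @describeIn capAndStandardize apply previously fitted capping bounds and
#'   moments to new values.
#' @param params list as returned by [capAndStandardize()].
#' @export
applyCapStandardize <- function(x, params) {
    x[x < params$lower] <- params$lower
    x[x > params$upper] <- params$upper
    (x - params$mean) / params$sd
}

## cap+standardise each row of a marker x cell matrix
capStandardizeMatrix <- function(mat, tail = 0.01) {
    params <- vector("list", nrow(mat))
    names(params) <- rownames(mat)
    out <- mat
    for (m in rownames(mat)) {
        cs <- capAndStandardize(mat[m, ], tail)
        out[m, ] <- cs$values
        params[[m]] <- cs[c("lower", "upper", "mean", "sd")]
    }
    list(z = out, params = params)
}

applyCapStandardizeMatrix <- function(mat, params) {
    for (m in rownames(mat))
        mat[m, ] <- applyCapStandardize(mat[m, ], params[[m]])
    mat
}

#' Preprocess raw cell intensities
#'
#' Runs the full preprocessing chain on an [MxifCellSet]: exposure-time
#' correction against the panel's per-round nominal exposures, log2
#' transform (pseudo-count 1), per-marker summarisation choice (nuclear vs
#' whole-cell median), and per-slide median centring. The result is a
#' [SummarizedExperiment::SummarizedExperiment] with one assay
#' \code{"normalized"} (analysis markers x cells); the slide medians used
#' are stored in \code{metadata(x)$transform} so the identical transform is
#' reproducible on held-out cells.
#'
#' Capping and standardisation of the clustering markers is deliberately
#' not applied here -- it is fitted on the final post-QC cell set by
#' [clusterCells()] / [standardizeClusteringMarkers()], and its parameters
#' frozen for all downstream use.
#'
#' @param cells an [MxifCellSet].
#' @param log2Offset pseudo-count of the log2 transform.
#' @return a SummarizedExperiment of normalised intensities.
#' @export
preprocessCells <- function(cells, log2Offset = 1) {
    stopifnot(is(cells, "MxifCellSet"))
    panel <- panel(cells)
    cd <- colData(cells)
    pm <- panel@markers
    ref <- panel@referenceExposure

    correctLog <- function(assay) {
        out <- assay
        for (i in seq_len(nrow(pm))) {
            m <- pm$marker[i]
            if (!m %in% rownames(assay)) next
            rnd <- as.character(pm$round[i])
            expo <- cd[[paste0("exp_r", rnd)]]
            if (is.null(expo))
                stop("missing exposure column exp_r", rnd)
            out[m, ] <- logTransform(
                exposureCorrect(assay[m, ], expo, ref[[rnd]]), log2Offset)
        }
        out
    }
    nuc <- correctLog(assay(cells, "nuclear"))
    cel <- correctLog(assay(cells, "cell"))
    summarized <- summarizeCells(nuc, cel, panel)
    normalized <- normalizeSlides(summarized, cd$slide_id)

    se <- SummarizedExperiment(assays = list(normalized = normalized),
                               colData = cd)
    metadata(se)$panel <- panel
    metadata(se)$transform <- list(
        log2Offset = log2Offset,
        referenceExposure = ref,
        slideMedians = lapply(
            stats::setNames(nm = rownames(summarized)),
            function(m) vapply(split(summarized[m, ], cd$slide_id),
                               stats::median, numeric(1))),
        grandMedians = apply(summarized, 1L, stats::median))
    se
}

#' Standardise the clustering markers of a normalised matrix
#'
#' Caps 1\% on both tails and standardises each clustering marker to zero
#' mean and unit sd, returning both the standardised matrix (cells x
#' markers, ready for k-means) and the frozen transform parameters.
#'
#' @param normalized SummarizedExperiment from [preprocessCells()], or a
#'   marker x cell matrix.
#' @param markers markers to use (default the canonical clustering set).
#' @param tail capped fraction per tail.
#' @return list with \code{x} (cells x markers standardised matrix) and
#'   \code{params} (per-marker capping bounds and moments).
#' @export
standardizeClusteringMarkers <- function(normalized,
                                         markers = CLUSTERING_MARKERS,
                                         tail = 0.01) {
    mat <- if (is(normalized, "SummarizedExperiment"))
        assay(normalized, "normalized") else normalized
    miss <- setdiff(markers, rownames(mat))
    if (length(miss))
        stop("clustering marker(s) not present: ",
             paste(miss, collapse = ", "))
    cs <- capStandardizeMatrix(mat[markers, , drop = FALSE], tail)
    list(x = t(cs$z), params = cs$params)
}
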