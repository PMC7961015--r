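#' Default cell-cluster archetypes
#'
#' Six phenotype archetypes over the standardised (z-score) space of the
#' four clustering markers ER, HER2, cMET and SLC7A5:
#' cluster 1 low for all four markers; cluster 2 high ER, low HER2/cMET/
#' SLC7A5; cluster 3 high SLC7A5, low HER2; cluster 4 high ER and cMET, low
#' HER2 and SLC7A5; cluster 5 high HER2 and SLC7A5, low-moderate cMET, low
#' ER; cluster 6 high HER2, low ER/cMET/SLC7A5.
#'
#' The numeric levels are chosen so that (i) archetypes are well separated
#' relative to the default within-cluster spread (minimum distance about six
#' standard deviations) and (ii) the six phenotypes are balanced: no single
#' marker contrast dominates the coarse structure, so every merge of
#' archetypes into fewer groups has competing alternatives of near-equal
#' cost. Property (ii) mirrors heatmaps of real cluster structure, where
#' each pair of phenotypes differs along its own axis, and it is what makes
#' the number of clusters identifiable by consensus stability.
#'
#' @param sdZ within-cluster standard deviation in z-units (a scalar or a
#'   6 x 4 matrix). The default 0.5 keeps archetypes separable but
#'   overlapping in their tails, matching the mixed-duct appearance of real
#'   tissue.
#' @return list with \code{meanZ} (6 x 4) and \code{sdZ} (6 x 4) matrices,
#'   rows labelled 1..6, columns ER, HER2, cMET, SLC7A5.
#' @export
defaultArchetypes <- function(sdZ = 0.5) {
    meanZ <- matrix(c(
        -1.208, -1.272, -1.502, -0.743,
         1.965, -1.272, -1.502, -0.743,
        -1.208, -1.272, -0.179,  2.141,
         1.965, -1.272,  2.312, -0.743,
        -1.208,  2.391,  0.132,  3.159,
        -1.208,  2.391, -1.502, -0.743),
        nrow = 6L, byrow = TRUE,
        dimnames = list(as.character(1:6), CLUSTERING_MARKERS))
    if (length(sdZ) == 1L)
        sdZ <- matrix(sdZ, 6L, 4L, dimnames = dimnames(meanZ))
    list(meanZ = meanZ, sdZ = sdZ)
}

#' Group-conditional mean cluster proportions
#'
#' The published mean cluster proportions per outcome group. Only clusters
#' 2, 4, 5 and 6 were reported; clusters 1 and 3 split the remaining mass
#' equally within each outcome group.
#'
#' @return 2 x 6 matrix, rows \code{BCE} and \code{nonBCE}.
#' @export
defaultGroupProfileMeans <- function() {
    matrix(c(.166, .030, .166, .063, .245, .330,
             .230, .176, .230, .165, .085, .114),
           nrow = 2L, byrow = TRUE,
           dimnames = list(c("BCE", "nonBCE"), as.character(1:6)))
}

#' Configure a synthetic MxIF cohort
#'
#' Defaults emulate the study cohort: 51 patients (13 with a breast cancer
#' event), about 2,000 epithelial cells per patient before QC (roughly 75k
#' after filtering), six cluster archetypes over ER/HER2/cMET/SLC7A5,
#' group-conditional Dirichlet patient profiles centred on the published
#' group means, four slides with additive log2 batch offsets, per-round
#' exposure-time variation, and QC artifacts (multi-nucleate cells,
#' out-of-range compartment areas, misregistered cells, low-DCIS fields).
#'
#' @param nPatients number of patients.
#' @param bceFraction fraction with a breast cancer event; when
#'   \code{nPatients * bceFraction} is integral the event count is exact.
#' @param cellsPerPatient named vector \code{c(mean=, dispersion=)} of the
#'   negative-binomial cell count per patient (pre-QC epithelial cells).
#' @param groupProfileMeans 2 x 6 matrix (rows BCE, nonBCE) of expected
#'   cluster proportions; rows must sum to 1.
#' @param profileConcentration Dirichlet concentration of per-patient
#'   profiles around their group mean. The group-conditional default 1
#'   produces strongly duct-dominated profiles whose implied risk-model
#'   discrimination matches the reported cohort performance; in logistic
#'   mode the default is 400 so that the two-covariate logistic model is
#'   statistically identified (probabilities off saturation) at the
#'   percentage scale of the published coefficients.
#' @param outcomeMode \code{"group_conditional"} (outcome drawn first,
#'   profile conditional on outcome) or \code{"logistic"} (profile drawn
#'   from the pooled Dirichlet, outcome drawn from a logistic model on the
#'   \%C5&6 and \%C2&4 covariates).
#' @param logisticParams named vector \code{c(intercept=, slopeC56=,
#'   slopeC24=)} on the 0--100 percentage scale; the default intercept -12
#'   yields about a 25\% event rate under the default concentration.
#' @param nSlides,slideOffsets slide count and additive log2 batch shifts.
#' @param artifactRates named fractions \code{multinucleate},
#'   \code{badArea}, \code{misregistered} (cell-level) and
#'   \code{lowDcisFov} (field-level).
#' @param followupModel list: \code{nonBceRange} (uniform support, years),
#'   \code{bceMedianYears}, \code{bceShape} (Weibull event-time model) and
#'   \code{bceMaxYears} (truncation, to keep events within the outcome
#'   window).
#' @param nBackgroundMarkers number of non-clustering analysis markers
#'   (0..4: PR, p53, p21, Ki67 in that order).
#' @param coresPerPatient,fovsPerCore tissue sampling layout.
#' @param stromalFraction fraction of additional stromal cells relative to
#'   epithelial cells.
#' @param erPrCorrelation cell-level correlation between ER and PR z-scores.
#' @param archetypes as returned by [defaultArchetypes()].
#' @param seed RNG seed; every random draw of the generator flows from it.
#' @return a [CohortConfig].
#' @export
cohortConfig <- function(nPatients = 51,
                         bceFraction = 13 / 51,
                         cellsPerPatient = c(mean = 2000, dispersion = 10),
                         groupProfileMeans = defaultGroupProfileMeans(),
                         profileConcentration = NULL,
                         outcomeMode = c("group_conditional", "logistic"),
                         logisticParams = c(intercept = -12,
                                            slopeC56 = 1.77,
                                            slopeC24 = -2.78),
                         nSlides = 4,
                         slideOffsets = c(0, 0.35, -0.25, 0.15),
                         exposureTimes = NULL,
                         artifactRates = c(multinucleate = 0.05,
                                           badArea = 0.03,
                                           misregistered = 0.10,
                                           lowDcisFov = 0.10),
                         followupModel = list(nonBceRange = c(3, 17),
                                              bceMedianYears = 2.5,
                                              bceShape = 1.5,
                                              bceMaxYears = 10),
                         nBackgroundMarkers = 4,
                         coresPerPatient = 1,
                         fovsPerCore = 4,
                         stromalFraction = 0.3,
                         erPrCorrelation = 0.8,
                         archetypes = defaultArchetypes(),
                         seed = 1L) {
    outcomeMode <- match.arg(outcomeMode)
    if (is.null(profileConcentration))
        profileConcentration <-
            if (outcomeMode == "logistic") 400 else 1
    if (is.null(exposureTimes))
        exposureTimes <- defaultPanel()@referenceExposure
    new("CohortConfig",
        nPatients = as.integer(nPatients), bceFraction = bceFraction,
        cellsPerPatient = cellsPerPatient,
        groupProfileMeans = groupProfileMeans,
        profileConcentration = profileConcentration,
        outcomeMode = outcomeMode, logisticParams = logisticParams,
        nSlides = as.integer(nSlides), slideOffsets = slideOffsets,
        exposureTimes = exposureTimes, artifactRates = artifactRates,
        followupModel = followupModel,
        nBackgroundMarkers = as.integer(nBackgroundMarkers),
        coresPerPatient = as.integer(coresPerPatient),
        fovsPerCore = as.integer(fovsPerCore),
        stromalFraction = stromalFraction,
        erPrCorrelation = erPrCorrelation,
        archetypes = archetypes,
        markerLog2Mean = c(ER = 10, HER2 = 10.5, cMET = 9.5, SLC7A5 = 10,
                           PR = 8, p53 = 8, p21 = 8, Ki67 = 8),
        markerLog2Sd = c(ER = 1.2, HER2 = 1.2, cMET = 1.2, SLC7A5 = 1.2,
                         PR = 1.2, p53 = 1, p21 = 1, Ki67 = 1),
        seed = as.integer(seed))
}

rdirichlet <- function(n, alpha) {
    x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
                nrow = n, byrow = TRUE)
    ## guard against all-zero rows at very small concentrations
    z <- rowSums(x) == 0
    if (any(z)) x[z, ] <- 1
    x / rowSums(x)
}

## Draw cells in archetype z-space. Exported because the consensus-
## clustering checks operate on this matrix directly.
#' Simulate standardised marker values from cluster archetypes
#'
#' @param n number of cells.
#' @param archetypes as [defaultArchetypes()].
#' @param weights mixture weights over archetypes (default uniform).
#' @param seed RNG seed (optional; when NULL the current RNG stream is
#'   used, so callers can embed this in a larger seeded simulation).
#' @return list with \code{z} (n x 4 matrix) and \code{cluster} (integer
#'   labels).
#' @export
rArchetypeCells <- function(n, archetypes = defaultArchetypes(),
                            weights = NULL, seed = NULL) {
    draw <- function() {
        k <- nrow(archetypes$meanZ)
        if (is.null(weights)) weights <- rep(1 / k, k)
        cl <- sample.int(k, n, replace = TRUE, prob = weights)
        z <- archetypes$meanZ[cl, , drop = FALSE] +
            archetypes$sdZ[cl, , drop = FALSE] *
                matrix(stats::rnorm(n * ncol(archetypes$meanZ)), n)
        rownames(z) <- NULL
        list(z = z, cluster = cl)
    }
    if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a synthetic MxIF cohort
#'
#' Draws patients, outcomes, per-patient cluster profiles, cells with
#' archetype-driven marker z-scores, and converts the z-scores to raw linear
#' intensities by inverting the preprocessing chain (slide offset in log2
#' space, inverse log2, multiplication by actual/reference exposure), so the
#' package's preprocessing is exercised end to end. QC artifacts
#' (multi-nucleate cells, out-of-range compartment areas, misregistered
#' cells, low-DCIS fields) are injected at the configured rates; stromal
#' cells are added as a separate tissue class.
#'
#' @param config a [CohortConfig].
#' @return list with elements \code{cells} (an [MxifCellSet]),
#'   \code{patients} (data.frame), \code{fovs} (data.frame) and
#'   \code{truth} (list: per-cell true cluster and z-scores, per-cell true
#'   log2 intensities of the selected compartment, per-patient true profiles
#'   and outcomes, artifact flags, slide offsets, the config).
#'   Deterministic given \code{config@seed}.
#' @export
generateCohort <- function(config) {
    validObject(config)
    withr::with_seed(config@seed, .generateCohort(config))
}

.generateCohort <- function(config) {
    panel <- defaultPanel()
    keepBg <- c("PR", "p53", "p21", "Ki67")[seq_len(config@nBackgroundMarkers)]
    pm <- panel@markers
    pm <- pm[pm$role == "clustering" | pm$marker %in% c(keepBg, "EGFR"), ]
    panel <- markerPanel(pm, panel@referenceExposure)
    rounds <- panelRounds(panel)
    arch <- config@archetypes
    nArch <- nrow(arch$meanZ)

    ## ---- patients -------------------------------------------------------
    nP <- config@nPatients
    pid <- sprintf("P%03d", seq_len(nP))
    nBce <- round(nP * config@bceFraction)
    gm <- config@groupProfileMeans
    conc <- config@profileConcentration

    if (config@outcomeMode == "group_conditional") {
        bce <- seq_len(nP) %in% sample.int(nP, nBce)
        profiles <- matrix(NA_real_, nP, nArch)
        if (any(bce))
            profiles[bce, ] <- rdirichlet(sum(bce), conc * gm["BCE", ])
        if (any(!bce))
            profiles[!bce, ] <- rdirichlet(sum(!bce), conc * gm["nonBCE", ])
    } else {
        pooled <- colMeans(gm)
        profiles <- rdirichlet(nP, conc * pooled)
        x1 <- 100 * (profiles[, 5] + profiles[, 6])
        x2 <- 100 * (profiles[, 2] + profiles[, 4])
        lp <- config@logisticParams
        eta <- lp[["intercept"]] + lp[["slopeC56"]] * x1 +
            lp[["slopeC24"]] * x2
        bce <- stats::runif(nP) < stats::plogis(eta)
    }
    dimnames(profiles) <- list(pid, as.character(seq_len(nArch)))

    fu <- config@followupModel
    followup <- numeric(nP)
    if (any(!bce))
        followup[!bce] <- stats::runif(sum(!bce), fu$nonBceRange[1],
                                       fu$nonBceRange[2])
    if (any(bce)) {
        scale <- fu$bceMedianYears / log(2)^(1 / fu$bceShape)
        ## inverse-CDF draw truncated below the outcome window
        umax <- stats::pweibull(fu$bceMaxYears, fu$bceShape, scale)
        followup[bce] <- stats::qweibull(
            stats::runif(sum(bce), 0, umax), fu$bceShape, scale)
    }
    patients <- data.frame(
        patient_id = pid, bce = bce,
        followup_years = followup,
        hormone_therapy = stats::runif(nP) < 0.56,
        radiotherapy = stats::runif(nP) < 0.74,
        surgery = TRUE,
        age = round(stats::runif(nP, 34, 75)),
        grade = sample(1:3, nP, replace = TRUE),
        stringsAsFactors = FALSE)

    ## ---- layout: slides, cores, FOVs -----------------------------------
    slideOf <- sprintf("S%d", rep_len(seq_len(config@nSlides), nP))
    names(slideOf) <- pid
    coreIds <- unlist(lapply(pid, function(p)
        sprintf("%s_core%d", p, seq_len(config@coresPerPatient))))
    fovTab <- do.call(rbind, lapply(coreIds, function(co) {
        p <- sub("_core\\d+$", "", co)
        data.frame(fov_id = sprintf("%s_fov%d", co,
                                    seq_len(config@fovsPerCore)),
                   patient_id = p, slide_id = unname(slideOf[p]),
                   core_id = co, stringsAsFactors = FALSE)
    }))
    nF <- nrow(fovTab)
    lowDcis <- stats::runif(nF) < config@artifactRates[["lowDcisFov"]]
    fovTab$pct_dcis <- ifelse(lowDcis, stats::runif(nF, 5, 45),
                              stats::runif(nF, 55, 95))
    fovTab$pct_normal <- 100 - fovTab$pct_dcis
    fovTab$manual_quality_pass <- TRUE

    ## ---- epithelial cells ----------------------------------------------
    cp <- config@cellsPerPatient
    nCells <- pmax(1L, stats::rnbinom(nP, size = cp[["dispersion"]],
                                      mu = cp[["mean"]]))
    cellPat <- rep(pid, nCells)
    nE <- length(cellPat)
    patIdx <- match(cellPat, pid)
    cl <- integer(nE)
    for (i in seq_len(nP)) {
        sel <- patIdx == i
        cl[sel] <- sample.int(nArch, sum(sel), replace = TRUE,
                              prob = profiles[i, ])
    }
    drawn <- rArchetypeCells(nE, arch, weights = NULL, seed = NULL)
    ## replace the uniform-mixture labels by the profile-driven ones while
    ## reusing the same noise field
    zNoise <- (drawn$z - arch$meanZ[drawn$cluster, , drop = FALSE]) /
        arch$sdZ[drawn$cluster, , drop = FALSE]
    zEpi <- arch$meanZ[cl, , drop = FALSE] +
        arch$sdZ[cl, , drop = FALSE] * zNoise
    colnames(zEpi) <- CLUSTERING_MARKERS

    ## ---- stromal cells --------------------------------------------------
    nS <- round(nE * config@stromalFraction)
    if (nS > 0) {
        sPat <- sample(cellPat, nS, replace = TRUE)
        zStr <- matrix(stats::rnorm(nS * 4, mean = -1.5, sd = 0.7), nS,
                       dimnames = list(NULL, CLUSTERING_MARKERS))
    } else {
        sPat <- character(0)
        zStr <- matrix(numeric(0), 0, 4,
                       dimnames = list(NULL, CLUSTERING_MARKERS))
    }
    tissue <- c(rep("epithelial", nE), rep("stromal", nS))
    cellPat <- c(cellPat, sPat)
    z <- rbind(zEpi, zStr)
    trueCluster <- c(cl, rep(NA_integer_, nS))
    n <- nE + nS
    cellId <- sprintf("c%07d", seq_len(n))
    slide <- unname(slideOf[cellPat])

    ## assign cells to their patient's cores and FOVs
    core <- sprintf("%s_core%d", cellPat,
                    sample.int(config@coresPerPatient, n, replace = TRUE))
    fov <- sprintf("%s_fov%d", core,
                   sample.int(config@fovsPerCore, n, replace = TRUE))

    ## ---- morphometry and registration ----------------------------------
    nNuclei <- sample(1:2, n, replace = TRUE, prob = c(0.7, 0.3))
    areaNuc <- stats::runif(n, 50, 500)
    areaMem <- stats::runif(n, 100, 900)
    areaCyt <- stats::runif(n, 100, 1200)
    reg <- matrix(1.0, n, length(rounds),
                  dimnames = list(NULL, paste0("reg_r", rounds)))

    ar <- config@artifactRates
    multi <- stats::runif(n) < ar[["multinucleate"]]
    nNuclei[multi] <- sample(3:5, sum(multi), replace = TRUE)
    bad <- stats::runif(n) < ar[["badArea"]]
    if (any(bad)) {
        which3 <- sample.int(3, sum(bad), replace = TRUE)
        badVal <- ifelse(stats::runif(sum(bad)) < 0.5,
                         stats::runif(sum(bad), 1, 10),
                         stats::runif(sum(bad), 1500, 3000))
        areaNuc[bad][which3 == 1] <- badVal[which3 == 1]
        areaMem[bad][which3 == 2] <- badVal[which3 == 2]
        areaCyt[bad][which3 == 3] <- badVal[which3 == 3]
    }
    misreg <- stats::runif(n) < ar[["misregistered"]]
    if (any(misreg)) {
        rr <- sample.int(length(rounds), sum(misreg), replace = TRUE)
        reg[cbind(which(misreg), rr)] <- stats::runif(sum(misreg), 0.2, 0.95)
    }

    ## ---- exposure times -------------------------------------------------
    ref <- panel@referenceExposure[as.character(rounds)]
    ## slide 1 imaged at nominal exposure; later slides re-imaged at
    ## halved/doubled exposures for some rounds
    expFactor <- matrix(1, config@nSlides, length(rounds),
                        dimnames = list(sprintf("S%d",
                                                seq_len(config@nSlides)),
                                        as.character(rounds)))
    if (config@nSlides > 1)
        expFactor[-1, ] <- sample(c(0.5, 1, 2),
                                  (config@nSlides - 1) * length(rounds),
                                  replace = TRUE, prob = c(.25, .5, .25))
    expMat <- matrix(rep(ref, each = n), n) *
        expFactor[slide, , drop = FALSE]
    colnames(expMat) <- paste0("exp_r", rounds)

    ## ---- marker intensities via the inverse preprocessing chain --------
    markers <- panel@markers$marker
    offs <- config@slideOffsets[match(slide,
                                      sprintf("S%d",
                                              seq_len(config@nSlides)))]
    pShift <- stats::rnorm(nP, 0, 0.3)
    names(pShift) <- pid
    mMean <- config@markerLog2Mean
    mSd <- config@markerLog2Sd

    trueLog2 <- matrix(NA_real_, length(markers), n,
                       dimnames = list(markers, cellId))
    zBg <- NULL
    for (m in markers) {
        if (m %in% CLUSTERING_MARKERS) {
            v <- mMean[[m]] + mSd[[m]] * z[, m]
        } else if (m == "EGFR") {
            v <- stats::rnorm(n, 4, 0.5)   # weak, excluded from analysis
        } else if (m == "PR") {
            rho <- config@erPrCorrelation
            zPr <- rho * z[, "ER"] +
                sqrt(1 - rho^2) * stats::rnorm(n)
            v <- mMean[[m]] + mSd[[m]] * zPr + pShift[cellPat]
        } else {
            v <- mMean[[m]] + mSd[[m]] * stats::rnorm(n) + pShift[cellPat]
        }
        trueLog2[m, ] <- v
    }

    nucAssay <- matrix(NA_real_, length(markers), n,
                       dimnames = dimnames(trueLog2))
    cellAssay <- nucAssay
    for (i in seq_along(markers)) {
        m <- markers[i]
        rnd <- as.character(panel@markers$round[i])
        expo <- expMat[, paste0("exp_r", rnd)]
        refE <- ref[[rnd]]
        vSel <- trueLog2[m, ] + offs          # slide batch effect in log2
        vOth <- vSel - 0.4 + stats::rnorm(n, 0, 0.15)
        rawSel <- (2^vSel - 1) * expo / refE  # invert log2 + exposure corr.
        rawOth <- (2^vOth - 1) * expo / refE
        if (panel@markers$summarization[i] == "nuclear_median") {
            nucAssay[i, ] <- rawSel; cellAssay[i, ] <- rawOth
        } else {
            cellAssay[i, ] <- rawSel; nucAssay[i, ] <- rawOth
        }
    }

    cd <- DataFrame(
        cell_id = cellId, patient_id = cellPat, slide_id = slide,
        fov_id = fov, core_id = core, tissue_class = tissue,
        n_nuclei = nNuclei, area_nucleus_px = areaNuc,
        area_membrane_px = areaMem, area_cytoplasm_px = areaCyt)
    for (cc in colnames(reg)) cd[[cc]] <- reg[, cc]
    for (cc in colnames(expMat)) cd[[cc]] <- expMat[, cc]
    rownames(cd) <- cellId
    colnames(nucAssay) <- colnames(cellAssay) <- cellId

    cells <- MxifCellSet(nucAssay, cellAssay, cd, panel)

    truth <- list(
        cellCluster = stats::setNames(trueCluster, cellId),
        cellZ = `rownames<-`(z, cellId),
        trueLog2 = trueLog2,
        profiles = profiles,
        outcome = stats::setNames(bce, pid),
        followup = stats::setNames(followup, pid),
        slideOffsets = stats::setNames(config@slideOffsets,
                                       sprintf("S%d",
                                               seq_len(config@nSlides))),
        artifacts = data.frame(cell_id = cellId, multinucleate = multi,
                               badArea = bad, misregistered = misreg,
                               stringsAsFactors = FALSE),
        lowDcisFov = stats::setNames(lowDcis, fovTab$fov_id),
        config = config)

    list(cells = cells, patients = patients, fovs = fovTab, truth = truth)
}

#' Simulate paired nuclear image patches for registration scoring
#'
#' Each cell gets a baseline nuclear (DAPI-like) patch and one patch per
#' later staining round, rendered from the same underlying smooth intensity
#' field sampled at coordinates shifted by the cell's misregistration
#' offset. An offset of zero reproduces the baseline patch exactly; larger
#' offsets decorrelate the pair.
#'
#' @param offsets numeric vector of per-cell misregistration offsets in
#'   pixels (>= 0); one baseline/round pair is generated per element.
#' @param nRounds number of later rounds per cell.
#' @param size patch side length in pixels.
#' @param noiseSd standard deviation of additive acquisition noise on the
#'   round patches (0 keeps offset-0 patches identical to baseline).
#' @param seed RNG seed.
#' @return list of per-cell lists with elements \code{baseline} (size x
#'   size matrix) and \code{rounds} (list of matrices).
#' @export
generateNuclearPatches <- function(offsets, nRounds = 1L, size = 32L,
                                   noiseSd = 0, seed = 1L) {
    if (any(offsets < 0)) stop("offsets must be >= 0 pixels")
    withr::with_seed(seed, {
        lapply(offsets, function(off) {
            ## smooth field: superposition of nuclear blobs
            nb <- 8L
            cx <- stats::runif(nb, 1, size)
            cy <- stats::runif(nb, 1, size)
            amp <- stats::runif(nb, 0.5, 1.5)
            sig <- stats::runif(nb, 2, 4)
            field <- function(dx) {
                gx <- seq_len(size)
                out <- matrix(0, size, size)
                for (b in seq_len(nb)) {
                    ex <- exp(-((gx + dx - cx[b])^2) / (2 * sig[b]^2))
                    ey <- exp(-((gx - cy[b])^2) / (2 * sig[b]^2))
                    out <- out + amp[b] * outer(ex, ey)
                }
                out
            }
            base <- field(0)
            rounds <- lapply(seq_len(nRounds), function(r) {
                p <- field(off)
                if (noiseSd > 0)
                    p <- p + matrix(stats::rnorm(size^2, 0, noiseSd),
                                    size, size)
                p
            })
            list(baseline = base, rounds = rounds)
        })
    })
}
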