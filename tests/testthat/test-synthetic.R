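test_that("cohort generation is deterministic given the seed", {
    a <- generateCohort(smallConfig(seed = 5))
    b <- generateCohort(smallConfig(seed = 5))
    expect_identical(asCellTable(a$cells), asCellTable(b$cells))
    expect_identical(a$patients, b$patients)
    expect_identical(a$fovs, b$fovs)
    expect_identical(a$truth$profiles, b$truth$profiles)
    c <- generateCohort(smallConfig(seed = 6))
    expect_false(identical(a$patients$followup_years,
                           c$patients$followup_years))
})

test_that("outcome counts are exact when n * fraction is integral", {
    co <- generateCohort(cohortConfig(
        nPatients = 51, bceFraction = 13 / 51,
        cellsPerPatient = c(mean = 2, dispersion = 5), seed = 7))
    expect_identical(sum(co$patients$bce), 13L)
    expect_identical(nrow(co$patients), 51L)
})

test_that("follow-up times respect the outcome windows", {
    co <- generateCohort(smallConfig(seed = 21, nPatients = 60))
    p <- co$patients
    expect_true(all(p$followup_years[!p$bce] >= 3))
    expect_true(all(p$followup_years[!p$bce] <= 17))
    expect_true(all(p$followup_years[p$bce] < 10))
    expect_true(all(p$followup_years > 0))
})

test_that("empirical cell proportions converge to the group means at high concentration", {
    ## law-of-large-numbers check: huge Dirichlet concentration pins each
    ## patient's profile to its group mean; 2000 cells/patient then pin the
    ## empirical cell-cluster proportions to the profile
    co <- generateCohort(cleanConfig(
        seed = 13, nPatients = 6,
        cellsPerPatient = c(mean = 2000, dispersion = 1e6),
        profileConcentration = 1e7))
    cl <- co$truth$cellCluster
    pat <- SummarizedExperiment::colData(co$cells)$patient_id
    gm <- rbind(bceMeanProfile, nonBceMeanProfile)
    for (p in unique(pat)) {
        emp <- tabulate(cl[pat == p], 6) / sum(pat == p)
        mean_ <- gm[2L - co$truth$outcome[p], ]
        expect_lt(max(abs(emp - mean_)), 0.02)
    }
})

test_that("true patient profiles are recoverable through the full pipeline", {
    ## artifact-free, well-separated data: preprocess, standardize, cluster
    ## at k = 6, canonicalize, profile; compare to the generator truth
    co <- generateCohort(cleanConfig(
        seed = 17, nPatients = 8,
        cellsPerPatient = c(mean = 1200, dispersion = 1e6)))
    norm <- preprocessCells(co$cells)
    std <- standardizeClusteringMarkers(norm)
    model <- canonicalizeLabels(kmeansFit(std$x, 6, seed = 1))$model
    asg <- assignClusters(model, std$x)
    prof <- clusterProfile(asg,
                           SummarizedExperiment::colData(co$cells)$patient_id)
    tru <- co$truth$profiles[rownames(prof), ]
    expect_lt(max(abs(prof - tru)), 0.05)
})

test_that("all generator randomness flows from the single config seed", {
    ## no hidden global RNG state: the global stream is untouched
    set.seed(999)
    before <- .Random.seed
    invisible(generateCohort(smallConfig(seed = 3)))
    expect_identical(.Random.seed, before)
})

test_that("invalid configurations name the offending field", {
    expect_error(cohortConfig(bceFraction = 1.4), "bceFraction")
    expect_error(cohortConfig(cellsPerPatient = c(mean = 0.2, dispersion = 1)),
                 "cellsPerPatient")
    bad <- defaultGroupProfileMeans()
    bad[1, ] <- bad[1, ] * 2
    expect_error(cohortConfig(groupProfileMeans = bad), "groupProfileMeans")
    expect_error(cohortConfig(artifactRates = c(multinucleate = -0.1,
                                                badArea = 0, misregistered = 0,
                                                lowDcisFov = 0)),
                 "artifactRates")
})

test_that("archetype sign patterns are distinct and dispersions positive", {
    arch <- defaultArchetypes()
    pat <- apply(sign(arch$meanZ), 1, paste, collapse = "/")
    expect_identical(anyDuplicated(pat), 0L)
    expect_true(all(arch$sdZ > 0))
    expect_identical(rownames(arch$meanZ), as.character(1:6))
})

test_that("zero-offset nuclear patches are identical; offsets decorrelate", {
    p0 <- generateNuclearPatches(0, seed = 1)[[1]]
    expect_identical(p0$baseline, p0$rounds[[1]])
    expect_equal(scoreRegistration(p0$baseline, p0$rounds)$summary, 1.0)

    ## a patch replaced by independent noise is uncorrelated with baseline
    rs <- withr::with_seed(2, vapply(seq_len(100), function(i) {
        p <- generateNuclearPatches(0, seed = i)[[1]]
        noise <- matrix(rnorm(length(p$baseline)), nrow(p$baseline))
        abs(cor(as.vector(p$baseline), as.vector(noise)))
    }, numeric(1)))
    expect_gt(mean(rs < 0.2), 0.9)
    expect_lt(mean(rs), 0.1)
})

test_that("patch correlation is non-increasing in misregistration offset", {
    offs <- c(0, 2, 4, 8)
    cors <- vapply(seq_len(100), function(i) {
        ps <- generateNuclearPatches(offs, seed = 100 + i)
        vapply(ps, function(p)
            cor(as.vector(p$baseline), as.vector(p$rounds[[1]])),
            numeric(1))
    }, numeric(length(offs)))
    avg <- rowMeans(cors)
    expect_true(all(diff(avg) <= 0))
    expect_equal(avg[1], 1.0)
})
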