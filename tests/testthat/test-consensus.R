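twoClouds <- function(n = 200, sep = 8, seed = 1) {
    withr::with_seed(seed, {
        x <- rbind(matrix(rnorm(n * 2), n),
                   matrix(rnorm(n * 2, mean = sep), n))
        colnames(x) <- c("a", "b")
        x
    })
}

test_that("k-means recovers well-separated clouds and is deterministic", {
    x <- twoClouds()
    fit <- kmeansFit(x, 2, seed = 3)
    asg <- assignClusters(fit, x)
    ## every point stays with its cloud
    expect_identical(length(unique(asg[1:200])), 1L)
    expect_identical(length(unique(asg[201:400])), 1L)
    expect_false(asg[1] == asg[201])
    ## centroids sit within 3 SEM of the cloud means
    sem <- 3 / sqrt(200)
    for (cl in 1:2) {
        mu <- colMeans(x[asg == cl, ])
        expect_lt(max(abs(centers(fit)[as.character(cl), ] - mu)), sem)
    }
    refit <- kmeansFit(x, 2, seed = 3)
    expect_identical(centers(fit), centers(refit))
    expect_identical(asg, assignClusters(refit, x))

    expect_error(kmeansFit(x, 1), "k must be >= 2")
    expect_error(kmeansFit(x[1:3, ], 5), "at least k rows")
})

test_that("assignment is nearest-centroid with ties to the lowest label", {
    ctr <- rbind(`1` = c(0, 0), `2` = c(2, 0), `3` = c(4, 0))
    model <- new("ClusterModel", k = 3L, centers = ctr,
                 markers = character(0), n = 3L, seed = 1L,
                 totWithinSS = 0)
    expect_identical(assignClusters(model, rbind(c(2, 0))), 2L)
    ## equidistant between centroids 1 and 2
    expect_identical(assignClusters(model, rbind(c(1, 0))), 1L)
    expect_identical(assignClusters(model, rbind(c(3, 0))), 2L)
    ## assignments of the fitting set reproduce the fit's own objective
    x <- twoClouds()
    fit <- kmeansFit(x, 2, seed = 5)
    asg <- assignClusters(fit, x)
    wss <- sum((x - centers(fit)[as.character(asg), ])^2)
    expect_equal(wss, fit@totWithinSS, tolerance = 1e-8)
})

test_that("consensus entries are crisp for separated data and bounded always", {
    x <- twoClouds(n = 60)
    cons <- consensusCluster(x, kRange = 2, reps = 20, fraction = 0.8,
                             seed = 7, keepMatrices = TRUE)
    cm <- consensusMatrix(cons, 2)
    expect_true(isSymmetric(unname(cm), tol = 1e-12))
    off <- cm[upper.tri(cm)]
    def <- off[!is.na(off)]
    expect_true(all(def %in% c(0, 1)))
    expect_equal(unname(pacValues(cons)), 0)
    expect_true(all(diag(cm) == 1))

    ## fraction = 1: no subsampling variation, deterministic best fit
    consFull <- consensusCluster(x, kRange = 2, reps = 5, fraction = 1,
                                 seed = 7, keepMatrices = TRUE)
    offF <- consensusMatrix(consFull, 2)[upper.tri(cm)]
    expect_true(all(offF %in% c(0, 1)))

    expect_error(consensusCluster(x, kRange = 2, reps = 1), "reps")
    expect_error(consensusCluster(x, kRange = 2, reps = 5, fraction = 0),
                 "fraction")
})

test_that("PAC counts strictly interior entries and matches brute force", {
    m01 <- rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 1))
    expect_equal(computePAC(m01), 0)
    mHalf <- matrix(0.5, 4, 4); diag(mHalf) <- 1
    expect_equal(computePAC(mHalf), 1)
    m3 <- rbind(c(1, 0, 0.5), c(0, 1, 1), c(0.5, 1, 1))
    expect_equal(computePAC(m3), 1 / 3)
    ## entries exactly at the bounds are unambiguous
    mb <- rbind(c(1, 0.1), c(0.1, 1))
    expect_equal(computePAC(mb), 0)

    bruteforce <- function(cm, lo, up) {
        num <- 0; den <- 0
        for (i in seq_len(nrow(cm) - 1)) for (j in (i + 1):ncol(cm)) {
            v <- cm[i, j]
            if (!is.na(v)) {
                den <- den + 1
                if (v > lo && v < up) num <- num + 1
            }
        }
        num / den
    }
    withr::with_seed(11, {
        for (t in seq_len(30)) {
            n <- sample(3:50, 1)
            cm <- matrix(round(runif(n * n), 2), n)
            cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
            diag(cm) <- 1
            cm[sample(length(cm), n)] <- NA  # some undefined pairs
            cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
            expect_equal(computePAC(cm), bruteforce(cm, 0.1, 0.9))
        }
    })
})

test_that("k selection takes the PAC argmin with ties to the smallest k", {
    expect_identical(selectK(c(`2` = 0.30, `3` = 0.05, `4` = 0.20)), 3L)
    expect_identical(selectK(c(`2` = 0.10, `3` = 0.10)), 2L)
    expect_identical(selectK(c(`7` = 0.4)), 7L)
    expect_error(selectK(numeric(0)), "candidate")
})

test_that("canonical labels recover a shuffled archetype assignment", {
    arch <- defaultArchetypes()
    shuffle <- c(4L, 1L, 6L, 2L, 5L, 3L)
    ctr <- arch$meanZ[shuffle, ]
    rownames(ctr) <- as.character(1:6)
    model <- new("ClusterModel", k = 6L, centers = ctr,
                 markers = c("ER", "HER2", "cMET", "SLC7A5"), n = 100L, seed = 1L,
                 totWithinSS = 0)
    res <- canonicalizeLabels(model, arch)
    expect_identical(res$mapping, shuffle)
    expect_equal(centers(res$model), arch$meanZ)

    ## small perturbations do not change the matching
    noisy <- model
    noisy@centers <- ctr + withr::with_seed(2, matrix(rnorm(24, 0, 0.1), 6))
    res2 <- canonicalizeLabels(noisy, arch)
    expect_identical(res2$mapping, shuffle)

    ## k mismatch: labels left in fit order with a warning
    m2 <- kmeansFit(twoClouds(), 2, seed = 1)
    expect_warning(res3 <- canonicalizeLabels(m2, arch), "archetypes")
    expect_identical(res3$mapping, 1:2)
})

test_that("within-cluster consensus exceeds between-cluster consensus on average", {
    cells <- rArchetypeCells(400, seed = 31)
    cons <- consensusCluster(cells$z, kRange = 6, reps = 25, seed = 31,
                             keepMatrices = TRUE)
    cm <- consensusMatrix(cons, 6)
    same <- outer(cells$cluster, cells$cluster, `==`)
    ut <- upper.tri(cm) & !is.na(cm)
    expect_gt(mean(cm[ut & same]), mean(cm[ut & !same]))
    expect_gt(mean(cm[ut & same]) - mean(cm[ut & !same]), 0.5)
})

test_that("PAC-based selection recovers the six archetype phenotypes", {
    for (seed in c(101, 202)) {
        cells <- rArchetypeCells(2500, seed = seed)
        cons <- consensusCluster(cells$z, kRange = 2:9, reps = 25,
                                 fraction = 0.8, seed = seed,
                                 keepMatrices = FALSE)
        expect_identical(chosenK(cons), 6L)
    }
})
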