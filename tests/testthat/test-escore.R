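test_that("cluster profiles count proportions over all k clusters", {
    prof <- clusterProfile(c(1, 1, 2, 3), rep("A", 4), k = 6)
    expect_equal(unname(prof["A", ]), c(0.5, 0.25, 0.25, 0, 0, 0))
    prof2 <- clusterProfile(rep(6, 10), rep("B", 10), k = 6)
    expect_equal(unname(prof2["B", ]), c(0, 0, 0, 0, 0, 1))
    many <- clusterProfile(sample(1:6, 300, replace = TRUE),
                           rep(c("A", "B", "C"), each = 100), k = 6)
    expect_equal(unname(rowSums(many)), rep(1, 3), tolerance = 1e-9)
    expect_true(all(many >= 0))
    expect_error(clusterProfile(integer(0), character(0)), "no cells")
})

test_that("the published model reproduces the printed worked examples", {
    m <- publishedEscoreModel()
    expect_equal(m@baseRate, 13 / 51)
    expect_equal(m@linearThreshold, 13)

    bce <- escore(bceMeanProfile, m)
    nonbce <- escore(nonBceMeanProfile, m)
    ## 1.77 * 57.5 - 2.78 * 9.3 and 1.77 * 19.9 - 2.78 * 34.1
    expect_equal(unname(bce), 75.921, tolerance = 1e-9)
    expect_equal(unname(nonbce), -59.575, tolerance = 1e-9)
    expect_identical(as.character(classifyRisk(bce, m)), "high")
    expect_identical(as.character(classifyRisk(nonbce, m)), "low")

    ## no contribution from clusters 2/4/5/6 scores zero
    expect_equal(unname(escore(c(0.5, 0, 0.5, 0, 0, 0), m)), 0)
    ## a score exactly at the threshold is low risk (strict >)
    expect_identical(as.character(classifyRisk(13, m)), "low")
    expect_identical(as.character(classifyRisk(13 + 1e-9, m)), "high")
})

test_that("escore is monotone in its two covariate blocks", {
    m <- publishedEscoreModel()
    base <- c(0.2, 0.2, 0.2, 0.1, 0.2, 0.1)
    up56 <- base + c(-0.1, 0, 0, 0, 0.1, 0)
    up24 <- base + c(-0.1, 0.1, 0, 0, 0, 0)
    expect_gt(escore(up56, m), escore(base, m))
    expect_lt(escore(up24, m), escore(base, m))
})

test_that("fitting degenerates gracefully and is permutation invariant", {
    withr::with_seed(8, {
        prof <- rdirich(60, rep(1, 6))
        colnames(prof) <- as.character(1:6)
        rownames(prof) <- sprintf("P%02d", 1:60)
        y <- rep(c(TRUE, FALSE), 30)
    })
    fit <- fitEscore(prof, y)
    perm <- withr::with_seed(9, sample(60))
    fit2 <- fitEscore(prof[perm, ], y[perm])
    expect_equal(fit@slopeC56, fit2@slopeC56)
    expect_equal(fit@slopeC24, fit2@slopeC24)
    expect_equal(fit@intercept, fit2@intercept)

    ## constant covariates: slopes 0, intercept-only limit
    flat <- matrix(rep(c(.4, .1, .2, .1, .1, .1), 20), 20, byrow = TRUE)
    yf <- rep(c(TRUE, FALSE), c(5, 15))
    m0 <- fitEscore(flat, yf)
    expect_equal(m0@slopeC56, 0)
    expect_equal(m0@slopeC24, 0)
    expect_equal(m0@intercept, qlogis(0.25))
    expect_equal(m0@linearThreshold, 0)

    ## complete separation is an error, not a silent fit
    sepProf <- rbind(matrix(rep(c(0, 0, .1, 0, .5, .4), 10), 10, byrow = TRUE),
                     matrix(rep(c(.2, .4, .1, .3, 0, 0), 10), 10, byrow = TRUE))
    ysep <- rep(c(TRUE, FALSE), each = 10)
    expect_error(fitEscore(sepProf, ysep), "separation")

    expect_error(fitEscore(prof, rep(TRUE, 60)), "both outcomes")
})

test_that("probability and linear-score classifications agree for fitted models", {
    for (seed in 1:5) {
        withr::with_seed(seed, {
            prof <- rdirich(40, c(2, 1, 2, 1, 1, 1))
            colnames(prof) <- as.character(1:6)
            x1 <- prof[, 5] + prof[, 6]
            y <- runif(40) < plogis(3 * scale(x1))
        })
        if (!any(y) || all(y)) next
        m <- tryCatch(fitEscore(prof, y), error = function(e) NULL)
        if (is.null(m)) next
        sc <- escore(prof, m)
        pr <- escoreProbability(prof, m)
        expect_identical(sc > m@linearThreshold, pr > m@baseRate)
        expect_identical(as.character(classifyRisk(sc, m)),
                         ifelse(pr > m@baseRate, "high", "low"))
    }
})

test_that("classification metrics reproduce confusion arithmetic and ranked AUC", {
    m <- publishedEscoreModel()
    ## 13 events (10 above / 3 below threshold), 38 non-events (8 / 30)
    scores <- c(rep(20, 10), rep(0, 3), rep(20, 8), rep(0, 30))
    y <- rep(c(TRUE, FALSE), c(13, 38))
    met <- evaluateModel(scores, y, m)
    expect_identical(c(met$tp, met$fn, met$tn, met$fp), c(10L, 3L, 30L, 8L))
    expect_equal(met$sensitivity, 10 / 13)
    expect_equal(met$specificity, 30 / 38)
    expect_equal(met$errorRate, 11 / 51)

    ## perfectly separating scores
    ps <- c(rep(1, 5), rep(-1, 5))
    yy <- rep(c(TRUE, FALSE), each = 5)
    expect_equal(evaluateModel(ps, yy, m)$auc, 1)

    ## outcome-independent scores sit at AUC 1/2
    withr::with_seed(33, {
        s <- rnorm(1000); yr <- runif(1000) < 0.3
    })
    expect_lt(abs(evaluateModel(s, yr, m)$auc - 0.5), 0.05)
})

test_that("midrank AUC matches an independent ROC implementation", {
    skip_if_not_installed("pROC")
    withr::with_seed(13, {
        s <- round(rnorm(200), 1)  # ties on purpose
        y <- runif(200) < plogis(s)
    })
    ours <- evaluateModel(s, y, publishedEscoreModel())$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("LOOCV refits once per patient and behaves at the null and under signal", {
    withr::with_seed(14, {
        prof <- rdirich(10, rep(1, 6)); colnames(prof) <- as.character(1:6)
        rownames(prof) <- sprintf("P%02d", 1:10)
        y10 <- rep(c(TRUE, FALSE), 5)
    })
    cv <- loocvEscore(prof, y10)
    expect_identical(cv$nFolds, 10L)
    expect_identical(sum(!is.na(cv$probabilities)) +
                     length(cv$failedFolds), 10L)
    expect_error(loocvEscore(prof[1:9, ], y10[1:9]), "at least 10")

    ## strongly separated profiles: held-out discrimination stays high
    ## (concentration high enough for near-separation, low enough that the
    ## unpenalised fits remain well-posed)
    co <- generateCohort(smallConfig(seed = 51, nPatients = 40,
                                     cellsPerPatient = c(mean = 2, dispersion = 5),
                                     profileConcentration = 6))
    cvs <- loocvEscore(co$truth$profiles, co$truth$outcome)
    expect_gte(cvs$auc, 0.95)
    expect_identical(sum(!is.na(cvs$probabilities)) +
                     length(cvs$failedFolds), 40L)

    ## shuffled outcome labels: no spurious held-out discrimination. Pooled
    ## LOOCV AUC is pessimistically biased below 1/2 under the null (each
    ## held-out case is absent from its own training set, anti-correlating
    ## prediction and label), so the check is one-sided.
    aucs <- vapply(1:8, function(s) {
        ysh <- withr::with_seed(60 + s, sample(co$truth$outcome))
        loocvEscore(co$truth$profiles, ysh)$auc
    }, numeric(1))
    expect_lt(mean(aucs), 0.55)
})

test_that("duplicate cores from the same patient classify concordantly", {
    m <- publishedEscoreModel()
    ## identical duplicate profiles agree trivially
    prof <- rbind(bceMeanProfile, bceMeanProfile)
    rownames(prof) <- NULL
    res <- coreConcordance(prof, c("A", "A"), m)
    expect_true(res$table$concordant)
    expect_equal(res$concordance, 1)

    ## cores on opposite sides of the threshold disagree
    opp <- rbind(bceMeanProfile, nonBceMeanProfile)
    res2 <- coreConcordance(opp, c("A", "A"), m)
    expect_false(res2$table$concordant)

    expect_error(coreConcordance(prof, c("A", "B"), m), ">= 2 cores")

    ## multinomial cores of 1000 cells drawn from well-separated patient
    ## profiles almost always agree
    co <- generateCohort(smallConfig(seed = 71, nPatients = 20,
                                     cellsPerPatient = c(mean = 2, dispersion = 5)))
    tru <- co$truth$profiles
    cores <- withr::with_seed(72, {
        idx <- rep(seq_len(nrow(tru)), each = 2)
        t(apply(tru[idx, ], 1, function(p)
            as.vector(rmultinom(1, 1000, p)) / 1000))
    })
    res3 <- coreConcordance(cores, rep(rownames(tru), each = 2), m)
    expect_gte(res3$concordance, 0.9)
})
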