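test_that("registration scoring follows the correlation contract", {
    base <- matrix(rnorm(64, 5), 8)
    ## identical patches score a perfect 1
    expect_equal(scoreRegistration(base, base)$summary, 1.0)
    ## anti-correlated patches clip to 0
    expect_equal(scoreRegistration(base, -base)$summary, 0.0)
    ## complete signal loss: zero-variance patch scores 0 with a warning
    expect_warning(s <- scoreRegistration(base, matrix(0, 8, 8)),
                   "signal loss")
    expect_equal(s$summary, 0.0)
    ## the summary is the minimum over rounds
    mid <- 0.5 * base + 0.5 * matrix(rnorm(64), 8)
    s <- scoreRegistration(base, list(base, mid, base))
    expect_equal(s$summary, min(s$perRound))
    expect_lt(s$summary, 1.0)
    ## shape guards
    expect_error(scoreRegistration(matrix(1, 1, 2), matrix(1, 1, 2)),
                 "4 pixels")
    expect_error(scoreRegistration(base, matrix(0, 4, 4)), "shape")
})

test_that("cell filters encode the published rules with strict area bounds", {
    ok <- makeCells()
    expect_identical(filterCells(ok)$cells$cell_id, "c001")

    three <- filterCells(makeCells(n_nuclei = 3))
    expect_identical(nrow(three$cells), 0L)
    rules <- auditRules(three$audit)
    expect_identical(rules$count[rules$rule == "nuclei"], 1L)

    ## area exactly at a bound is excluded (strict inequalities)
    expect_identical(nrow(filterCells(makeCells(area_nucleus_px = 10))$cells), 0L)
    expect_identical(nrow(filterCells(makeCells(area_cytoplasm_px = 1500))$cells), 0L)
    expect_identical(nrow(filterCells(makeCells(area_membrane_px = 11))$cells), 1L)

    ## imperfect registration in any round excludes the cell
    expect_identical(nrow(filterCells(makeCells(reg_r7 = 0.8))$cells), 0L)
    ## non-epithelial cells are excluded
    expect_identical(nrow(filterCells(makeCells(tissue_class = "stromal"))$cells), 0L)
})

test_that("a cell violating several rules is tallied under each rule", {
    bad <- makeCells(n_nuclei = 4, reg_r4 = 0.3)
    res <- filterCells(bad)
    rules <- auditRules(res$audit)
    expect_identical(rules$count[rules$rule == "nuclei"], 1L)
    expect_identical(rules$count[rules$rule == "registration"], 1L)
    st <- auditStages(res$audit)
    expect_identical(st$excluded, 1L)
})

test_that("missing cell fields raise errors naming the field", {
    cells <- makeCells()
    cells$n_nuclei <- NULL
    expect_error(filterCells(cells), "n_nuclei")
    cells2 <- makeCells(n = 2)
    cells2$area_membrane_px[2] <- NA
    expect_error(filterCells(cells2), "area_membrane_px")
    expect_error(filterCells(cells2), "c002")
})

test_that("cell filtering is idempotent and order-insensitive", {
    co <- generateCohort(smallConfig(seed = 9))
    res <- filterCells(co$cells)
    again <- filterCells(res$cells)
    expect_identical(auditStages(again$audit)$excluded, 0L)
    expect_identical(ncol(again$cells), ncol(res$cells))

    ## the retained set equals the intersection of single-rule masks,
    ## whatever the order of application
    df <- as.data.frame(SummarizedExperiment::colData(co$cells))
    masks <- list(
        tissue = df$tissue_class == "epithelial",
        nuclei = df$n_nuclei >= 1 & df$n_nuclei <= 2,
        area = df$area_nucleus_px > 10 & df$area_nucleus_px < 1500 &
            df$area_membrane_px > 10 & df$area_membrane_px < 1500 &
            df$area_cytoplasm_px > 10 & df$area_cytoplasm_px < 1500,
        registration = pmin(df$reg_r4, df$reg_r6, df$reg_r7, df$reg_r8,
                            df$reg_r12, df$reg_r13, df$reg_r15) >= 1 - 1e-9)
    for (ord in list(1:4, 4:1, c(2, 4, 1, 3))) {
        keep <- Reduce(`&`, masks[ord])
        expect_identical(sort(df$cell_id[keep]),
                         sort(SummarizedExperiment::colData(res$cells)$cell_id))
    }
})

test_that("exclusion tallies track the configured artifact rates", {
    cfg <- smallConfig(seed = 31, nPatients = 40,
                       cellsPerPatient = c(mean = 500, dispersion = 1e6),
                       stromalFraction = 0)
    co <- generateCohort(cfg)
    n <- ncol(co$cells)
    res <- filterCells(co$cells)
    rules <- auditRules(res$audit)
    cnt <- function(r) rules$count[rules$rule == r]
    for (pair in list(c("nuclei", 0.05), c("area", 0.03),
                      c("registration", 0.10))) {
        rate <- as.numeric(pair[2])
        tol <- 4 * sqrt(n * rate * (1 - rate))
        expect_lt(abs(cnt(pair[1]) - n * rate), tol)
    }
})

test_that("FOV filtering uses the DCIS fraction with boundary retained", {
    fovs <- data.frame(
        fov_id = c("f1", "f2", "f3", "f4", "f5"),
        pct_dcis = c(40, 50, 100, 0, 80),
        pct_normal = c(60, 50, 0, 0, 20),
        manual_quality_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE))
    res <- filterFovs(fovs)
    expect_identical(res$fovs$fov_id, c("f2", "f3"))
    rules <- auditRules(res$audit)
    expect_identical(rules$count[rules$rule == "no_evaluable_tissue"], 1L)
    expect_identical(rules$count[rules$rule == "manual_quality"], 1L)
    st <- auditStages(res$audit)
    expect_identical(st$input - st$excluded, st$output)
})

test_that("patient filtering applies the outcome-analysis exclusions", {
    patients <- data.frame(
        patient_id = c("A", "B", "C", "D", "E"),
        bce = c(FALSE, TRUE, TRUE, TRUE, FALSE),
        followup_years = c(2.0, 12.0, 2.5, 2.5, 9.0))
    cells <- do.call(rbind, lapply(seq_len(nrow(patients)), function(i)
        makeCells(n = c(500, 500, 99, 100, 500)[i],
                  patient_id = patients$patient_id[i])))
    res <- filterPatients(patients, cells)
    ## A: non-BCE followed < 3y; B: BCE at >= 10y; C: fewer than 100 cells
    expect_identical(res$patients$patient_id, c("D", "E"))
    rules <- auditRules(res$audit)
    expect_identical(rules$count[rules$rule == "short_followup_nonbce"], 1L)
    expect_identical(rules$count[rules$rule == "long_followup_bce"], 1L)
    expect_identical(rules$count[rules$rule == "few_cells"], 1L)
})

test_that("orphan cells are a data error", {
    patients <- data.frame(patient_id = "A", bce = FALSE,
                           followup_years = 5)
    cells <- makeCells(patient_id = "GHOST")
    expect_error(filterPatients(patients, cells), "GHOST")
})
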