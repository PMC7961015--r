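## Small cohort configurations used across tests. All fixtures are built in
## code; nothing is read from disk.

smallConfig <- function(seed = 7, ...) {
    args <- list(nPatients = 20, bceFraction = 0.25,
                 cellsPerPatient = c(mean = 300, dispersion = 10),
                 seed = seed)
    args[names(list(...))] <- list(...)
    do.call(cohortConfig, args)
}

## artifact-free, single-slide configuration for exact round-trip checks
cleanConfig <- function(seed = 11, ...) {
    args <- list(nPatients = 6, cellsPerPatient = c(mean = 250, dispersion = 10),
                 nSlides = 1, slideOffsets = 0,
                 artifactRates = c(multinucleate = 0, badArea = 0,
                                   misregistered = 0, lowDcisFov = 0),
                 stromalFraction = 0, seed = seed)
    args[names(list(...))] <- list(...)
    do.call(cohortConfig, args)
}

## minimal hand-built cell record(s) that pass every cell-level filter
makeCells <- function(n = 1, ...) {
    df <- data.frame(
        cell_id = sprintf("c%03d", seq_len(n)),
        patient_id = "P001", slide_id = "S1",
        fov_id = "P001_core1_fov1", core_id = "P001_core1",
        tissue_class = "epithelial", n_nuclei = 1,
        area_nucleus_px = 200, area_membrane_px = 500,
        area_cytoplasm_px = 800,
        reg_r4 = 1.0, reg_r7 = 1.0,
        stringsAsFactors = FALSE)
    over <- list(...)
    for (nm in names(over)) df[[nm]] <- over[[nm]]
    df
}

## group-mean patient profiles printed for the study cohort (clusters 1 and
## 3 split the unprinted remainder equally)
bceMeanProfile <- c(.166, .030, .166, .063, .245, .330)
nonBceMeanProfile <- c(.230, .176, .230, .165, .085, .114)

## independent Dirichlet sampler for test fixtures
rdirich <- function(n, alpha) {
    x <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n,
                byrow = TRUE)
    x / rowSums(x)
}
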