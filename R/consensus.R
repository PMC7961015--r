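## k-means++ seeding: spread the k initial centres by sampling points with
## probability proportional to squared distance from the nearest centre
## already chosen.
kmeansppCenters <- function(x, k) {
    n <- nrow(x)
    ci <- sample.int(n, 1L)
    centers <- x[ci, , drop = FALSE]
    d2 <- rowSums((x - matrix(x[ci, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1L)) {
        if (all(d2 == 0)) ci <- sample.int(n, 1L)
        else ci <- sample.int(n, 1L, prob = d2)
        centers <- rbind(centers, x[ci, , drop = FALSE])
        d2 <- pmin(d2, rowSums((x - matrix(x[ci, ], n, ncol(x),
                                           byrow = TRUE))^2))
    }
    centers
}

## one Lloyd fit from a k-means++ seed; retries a fresh seed on the rare
## empty-cluster failure
kmeansOnce <- function(x, k, iterMax = 100L) {
    for (attempt in 1:5) {
        fit <- tryCatch(
            suppressWarnings(stats::kmeans(x, kmeansppCenters(x, k),
                                           iter.max = iterMax,
                                           algorithm = "Lloyd")),
            error = function(e) NULL)
        if (!is.null(fit)) return(fit)
    }
    stop("k-means failed repeatedly (k = ", k, ")")
}

#' Fit k-means with k-means++ initialisation
#'
#' Lloyd's algorithm seeded by k-means++, best of \code{restarts} runs by
#' total within-cluster sum of squares. Deterministic given \code{seed}.
#'
#' @param x cells x markers numeric matrix (standardised).
#' @param k number of clusters (>= 2).
#' @param seed RNG seed.
#' @param restarts number of independent restarts.
#' @param iterMax Lloyd iteration cap.
#' @return a [ClusterModel].
#' @export
kmeansFit <- function(x, k, seed = 1L, restarts = 5L, iterMax = 100L) {
    x <- as.matrix(x)
    if (k < 2L) stop("k must be >= 2")
    if (nrow(x) < k) stop("need at least k rows")
    if (!all(is.finite(x))) stop("values must be finite")
    best <- withr::with_seed(seed, {
        best <- NULL
        for (r in seq_len(restarts)) {
            fit <- kmeansOnce(x, k, iterMax)
            if (is.null(best) || fit$tot.withinss < best$tot.withinss)
                best <- fit
        }
        best
    })
    centers <- best$centers
    rownames(centers) <- as.character(seq_len(k))
    new("ClusterModel", k = as.integer(k), centers = centers,
        markers = colnames(x) %||% character(0),
        n = nrow(x), seed = as.integer(seed),
        totWithinSS = best$tot.withinss)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign cells to the nearest centroid
#'
#' Euclidean nearest-centroid assignment; distance ties go to the lowest
#' cluster label.
#'
#' @param model a [ClusterModel].
#' @param x cells x markers matrix in the model's marker order.
#' @return integer cluster label per cell.
#' @export
assignClusters <- function(model, x) {
    x <- as.matrix(x)
    if (length(model@markers) && !is.null(colnames(x)) &&
        !identical(colnames(x), model@markers))
        stop("matrix columns must match the model's marker order: ",
             paste(model@markers, collapse = ", "))
    ctr <- model@centers
    ## squared distances via the expansion |x|^2 - 2 x.c + |c|^2
    d2 <- outer(rowSums(x^2), rep(1, nrow(ctr))) -
        2 * x %*% t(ctr) +
        outer(rep(1, nrow(x)), rowSums(ctr^2))
    ## max.col(ties.method = "first") on the negated distances gives the
    ## lowest label among tied minima
    lab <- max.col(-d2, ties.method = "first")
    as.integer(rownames(ctr)[lab])
}

#' Consensus clustering over a range of k
#'
#' For each candidate k, repeatedly subsamples a fraction of the cells
#' without replacement, fits k-means on the subsample, and accumulates how
#' often each pair of cells is co-clustered among the subsamples that
#' contain both. The consensus entry for a pair is co-clustered /
#' co-sampled; pairs never co-sampled are undefined (NA) and excluded from
#' PAC. The chosen k minimises PAC; ties go to the smallest k.
#'
#' @param x cells x markers standardised matrix.
#' @param kRange candidate numbers of clusters.
#' @param reps subsampling repetitions per k (>= 2).
#' @param fraction subsample fraction in (0, 1].
#' @param seed RNG seed; all repetitions flow from it.
#' @param restarts k-means restarts per subsample fit.
#' @param pacBounds lower/upper bounds of the ambiguous interval.
#' @param keepMatrices store the per-k consensus matrices (defaults to TRUE
#'   for up to 2000 cells; for larger inputs only PAC is kept).
#' @return a [ConsensusResult].
#' @export
consensusCluster <- function(x, kRange = 2:15, reps = 100L, fraction = 0.8,
                             seed = 1L, restarts = 3L,
                             pacBounds = c(0.1, 0.9),
                             keepMatrices = nrow(x) <= 2000L) {
    x <- as.matrix(x)
    n <- nrow(x)
    if (reps < 2L) stop("reps must be >= 2")
    if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
    m <- ceiling(fraction * n)
    if (m < max(kRange)) stop("subsample too small for the largest k")

    conn <- matrix(0, n, n)
    samp <- matrix(0, n, n)
    pac <- stats::setNames(numeric(length(kRange)), kRange)
    mats <- list()

    withr::with_seed(seed, {
        for (ki in seq_along(kRange)) {
            k <- kRange[ki]
            cc_reset(conn, samp)
            for (r in seq_len(reps)) {
                idx <- if (m == n) seq_len(n) else sort(sample.int(n, m))
                best <- NULL
                for (s in seq_len(restarts)) {
                    fit <- kmeansOnce(x[idx, , drop = FALSE], k)
                    if (is.null(best) ||
                        fit$tot.withinss < best$tot.withinss)
                        best <- fit
                }
                cc_accumulate(conn, samp, idx, best$cluster)
            }
            pac[ki] <- cc_pac(conn, samp, pacBounds[1], pacBounds[2])$pac
            if (keepMatrices) {
                cm <- ifelse(samp > 0, conn / samp, NA_real_)
                cm[lower.tri(cm)] <- t(cm)[lower.tri(cm)]
                diag(cm) <- 1
                dimnames(cm) <- list(rownames(x), rownames(x))
                mats[[as.character(k)]] <- cm
            }
        }
    })
    new("ConsensusResult", ks = as.integer(kRange), pac = pac,
        matrices = mats, chosenK = selectK(pac),
        fraction = fraction, reps = as.integer(reps),
        seed = as.integer(seed))
}

#' Proportion of ambiguously clustered pairs
#'
#' The fraction of defined unique off-diagonal consensus entries strictly
#' inside \code{(lower, upper)}. Entries exactly at a bound count as
#' unambiguous; pairs never co-sampled (NA) are excluded.
#'
#' @param consensus symmetric consensus matrix (diagonal 1, NAs allowed).
#' @param lower,upper bounds of the ambiguous interval.
#' @return PAC in [0, 1].
#' @export
computePAC <- function(consensus, lower = 0.1, upper = 0.9) {
    if (lower < 0 || upper > 1 || lower >= upper)
        stop("need 0 <= lower < upper <= 1")
    v <- consensus[upper.tri(consensus)]
    v <- v[!is.na(v)]
    if (!length(v)) return(NA_real_)
    mean(v > lower & v < upper)
}

#' Select the number of clusters by minimum PAC
#'
#' @param pac named numeric vector of PAC values (names = k).
#' @return the k with minimal PAC; ties resolve to the smallest k.
#' @export
selectK <- function(pac) {
    if (!length(pac)) stop("at least one candidate k required")
    ks <- as.integer(names(pac))
    ks <- ks[order(pac, ks)]
    ks[1]
}

## all permutations of 1..k (k <= 8 in practice; canonicalisation only
## applies when k equals the number of archetypes)
.permutations <- function(k) {
    if (k == 1L) return(matrix(1L, 1L))
    sub <- .permutations(k - 1L)
    do.call(rbind, lapply(seq_len(k), function(i) {
        cbind(i, sub + (sub >= i))
    }))
}

#' Relabel clusters against reference archetypes
#'
#' Finds the one-to-one assignment of fitted centroids to archetype labels
#' minimising the total Euclidean distance (exact search over permutations),
#' so cluster numbers follow the canonical 1..6 phenotype numbering. When
#' the model's k differs from the number of archetypes the labels are left
#' in fit order with a warning.
#'
#' @param model a [ClusterModel].
#' @param archetypes as [defaultArchetypes()].
#' @return list with \code{model} (relabelled) and \code{mapping} (integer
#'   vector: \code{mapping[i]} is the canonical label of fitted cluster i).
#' @export
canonicalizeLabels <- function(model, archetypes = defaultArchetypes()) {
    ref <- archetypes$meanZ
    k <- model@k
    if (k != nrow(ref)) {
        warning("k = ", k, " does not match the ", nrow(ref),
                " archetypes; labels left in fit order")
        return(list(model = model, mapping = seq_len(k)))
    }
    if (k > 8L) stop("exact label matching supported up to k = 8")
    ctr <- model@centers[, colnames(ref), drop = FALSE]
    d <- as.matrix(stats::dist(rbind(ctr, ref)))[seq_len(k),
                                                 k + seq_len(k)]
    perms <- .permutations(k)
    cost <- apply(perms, 1L, function(p) sum(d[cbind(seq_len(k), p)]))
    mapping <- perms[which.min(cost), ]
    newCenters <- ctr
    rownames(newCenters) <- as.character(mapping)
    newCenters <- newCenters[order(mapping), , drop = FALSE]
    out <- model
    out@centers <- newCenters
    list(model = out, mapping = as.integer(mapping))
}

#' Hierarchically ordered consensus matrix for heatmap display
#'
#' Orders the cells of a stored consensus matrix by complete-linkage
#' clustering of 1 - consensus, the conventional display for visually
#' confirming cluster separation. The ordering is for display only; k
#' selection itself is fully automatic (minimum PAC).
#'
#' @param result a [ConsensusResult] with stored matrices.
#' @param k which candidate k to display.
#' @return the reordered consensus matrix.
#' @export
consensusHeatmapData <- function(result, k) {
    cm <- consensusMatrix(result, k)
    cm0 <- cm
    cm0[is.na(cm0)] <- 0.5      # undefined pairs carry no ordering signal
    ord <- stats::hclust(stats::as.dist(1 - cm0), method = "complete")$order
    cm[ord, ord]
}
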