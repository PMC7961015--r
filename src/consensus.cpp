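#include <Rcpp.h>
using namespace Rcpp;

// Pair-count accumulation for consensus clustering. `conn` and `samp` are
// n x n matrices updated in place (upper triangle only): `samp(i,j)` counts
// how often items i and j were subsampled together, `conn(i,j)` how often
// they were assigned to the same k-means cluster. `idx` is the 1-based index
// vector of the current subsample, `labels` the cluster label of each
// subsampled item. Quadratic in subsample size, hence C++.
// [[Rcpp::export]]
void cc_accumulate(NumericMatrix conn, NumericMatrix samp,
                   IntegerVector idx, IntegerVector labels) {
    const int m = idx.size();
    if (labels.size() != m)
        stop("idx and labels must have equal length");
    // require ascending indices so that, with b as the outer (column) loop,
    // the inner loop writes contiguous cells of one column: this keeps the
    // quadratic update cache-friendly on large matrices
    for (int a = 1; a < m; ++a)
        if (idx[a] <= idx[a - 1])
            stop("idx must be strictly increasing");
    double *cn = conn.begin(), *sp = samp.begin();
    const R_xlen_t n = conn.nrow();
    for (int b = 1; b < m; ++b) {
        const R_xlen_t col = static_cast<R_xlen_t>(idx[b] - 1) * n;
        const int lb = labels[b];
        for (int a = 0; a < b; ++a) {
            const R_xlen_t at = col + (idx[a] - 1);
            sp[at] += 1.0;
            if (labels[a] == lb) cn[at] += 1.0;
        }
    }
}

// PAC from the accumulated pair counts: the fraction of defined unique
// off-diagonal consensus entries strictly inside (lower, upper). Pairs never
// co-sampled are excluded from the denominator.
// [[Rcpp::export]]
List cc_pac(NumericMatrix conn, NumericMatrix samp,
            double lower, double upper) {
    const int n = conn.nrow();
    R_xlen_t defined = 0, ambiguous = 0;
    for (int j = 1; j < n; ++j) {
        for (int i = 0; i < j; ++i) {
            const double s = samp(i, j);
            if (s > 0.0) {
                ++defined;
                const double v = conn(i, j) / s;
                if (v > lower && v < upper) ++ambiguous;
            }
        }
    }
    const double pac = defined > 0 ?
        static_cast<double>(ambiguous) / static_cast<double>(defined) :
        NA_REAL;
    return List::create(_["pac"] = pac,
                        _["defined"] = static_cast<double>(defined),
                        _["ambiguous"] = static_cast<double>(ambiguous));
}

// Zero both accumulator matrices between values of k (avoids reallocating
// two n x n matrices per k).
// [[Rcpp::export]]
void cc_reset(NumericMatrix conn, NumericMatrix samp) {
    std::fill(conn.begin(), conn.end(), 0.0);
    std::fill(samp.begin(), samp.end(), 0.0);
}
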