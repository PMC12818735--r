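#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Rand index between two label vectors, via the contingency-table identity:
//   agreements = C(n,2) + 2*sum_ij C(n_ij,2) - sum_i C(a_i,2) - sum_j C(b_j,2)
// where n_ij is the contingency table, a_i / b_j its margins. Labels must be
// 0-based integers in [0, ka) and [0, kb).
static double ri_kernel(const int* a, const int* b, int n, int ka, int kb,
                        std::vector<long long>& cnt,
                        std::vector<long long>& ra,
                        std::vector<long long>& cb) {
    std::fill(cnt.begin(), cnt.end(), 0LL);
    std::fill(ra.begin(), ra.end(), 0LL);
    std::fill(cb.begin(), cb.end(), 0LL);
    for (int i = 0; i < n; ++i) {
        cnt[(size_t)a[i] * kb + b[i]]++;
        ra[a[i]]++;
        cb[b[i]]++;
    }
    double sij = 0.0, si = 0.0, sj = 0.0;
    for (size_t t = 0; t < cnt.size(); ++t) sij += cnt[t] * (cnt[t] - 1) / 2.0;
    for (int i = 0; i < ka; ++i) si += ra[i] * (ra[i] - 1) / 2.0;
    for (int j = 0; j < kb; ++j) sj += cb[j] * (cb[j] - 1) / 2.0;
    double total = n * (n - 1) / 2.0;
    return (total + 2.0 * sij - si - sj) / total;
}

// [[Rcpp::export]]
double ri_pair_cpp(IntegerVector a, IntegerVector b, int ka, int kb) {
    int n = a.size();
    std::vector<long long> cnt((size_t)ka * kb), ra(ka), cb(kb);
    return ri_kernel(a.begin(), b.begin(), n, ka, kb, cnt, ra, cb);
}

// Rand index for every ordered pair of rows of `parts` (one partition per
// row, labels 0-based in [0, k)). Used by the exhaustive oracle checks.
// [[Rcpp::export]]
NumericMatrix ri_all_pairs_cpp(IntegerMatrix parts, int k) {
    int m = parts.nrow(), n = parts.ncol();
    // row-major copies so each partition is contiguous
    std::vector<std::vector<int>> rows(m, std::vector<int>(n));
    for (int i = 0; i < m; ++i)
        for (int j = 0; j < n; ++j) rows[i][j] = parts(i, j);
    NumericMatrix out(m, m);
    std::vector<long long> cnt((size_t)k * k), ra(k), cb(k);
    for (int i = 0; i < m; ++i) {
        out(i, i) = 1.0;
        for (int j = i + 1; j < m; ++j) {
            double ri = ri_kernel(rows[i].data(), rows[j].data(), n, k, k,
                                  cnt, ra, cb);
            out(i, j) = ri;
            out(j, i) = ri;
        }
    }
    return out;
}
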