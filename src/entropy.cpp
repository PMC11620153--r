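#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Templates are sorted by first coordinate so that only pairs whose first
// elements already lie within r are examined; the counts are identical to
// the naive all-pairs scan.

// Directed match counts (self-match included) for the nt templates of
// length m starting at 0..nt-1, Chebyshev radius r.
static void match_counts(const double *x, int nt, int m, double r,
                         std::vector<double> &cnt) {
    std::vector<int> idx(nt);
    for (int i = 0; i < nt; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [x](int a, int b) { return x[a] < x[b]; });
    cnt.assign(nt, 1.0);  // self-match
    for (int a = 0; a < nt; ++a) {
        int i = idx[a];
        for (int b = a + 1; b < nt && x[idx[b]] - x[i] <= r; ++b) {
            int j = idx[b];
            bool ok = true;
            for (int k = 1; k < m; ++k) {
                double d = x[i + k] - x[j + k];
                if (d > r || d < -r) { ok = false; break; }
            }
            if (ok) { cnt[i] += 1.0; cnt[j] += 1.0; }
        }
    }
}

static double apen_phi(const double *x, int n, int m, double r) {
    int nt = n - m + 1;
    std::vector<double> cnt;
    match_counts(x, nt, m, r, cnt);
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) acc += std::log(cnt[i] / (double)nt);
    return acc / (double)nt;
}

//' Approximate and sample entropy of a numeric series (compiled kernel)
//'
//' Computes ApEn(m, r) as phi(m) - phi(m+1) with self-matches included, and
//' SampEn(m, r) = -log(A/B) over template pairs i != j with both template
//' lengths drawn from the first n - m start positions (self-matches
//' excluded). Distances are Chebyshev. Returns c(apen, sampen); sampen is
//' NA when A or B is zero.
//'
//' @param x numeric vector, length >= m + 2.
//' @param m embedding dimension (>= 1).
//' @param r tolerance radius (>= 0), on the scale of x.
//' @keywords internal
// [[Rcpp::export]]
NumericVector entropy_pair_cpp(NumericVector x, int m, double r) {
    int n = x.size();
    if (m < 1) stop("m must be >= 1");
    if (r < 0) stop("r must be >= 0");
    if (n < m + 2) stop("series too short for embedding dimension m");
    const double *p = REAL(x);

    double apen = apen_phi(p, n, m, r) - apen_phi(p, n, m + 1, r);

    // Sample entropy: both counts over start positions 0..(n-m-1).
    int nt = n - m;
    std::vector<int> idx(nt);
    for (int i = 0; i < nt; ++i) idx[i] = i;
    std::sort(idx.begin(), idx.end(),
              [p](int a, int b) { return p[a] < p[b]; });
    long long A = 0, B = 0;
    for (int a = 0; a < nt; ++a) {
        int i = idx[a];
        for (int b = a + 1; b < nt && p[idx[b]] - p[i] <= r; ++b) {
            int j = idx[b];
            bool ok = true;
            for (int k = 1; k < m; ++k) {
                double d = p[i + k] - p[j + k];
                if (d > r || d < -r) { ok = false; break; }
            }
            if (ok) {
                ++B;
                double d = p[i + m] - p[j + m];
                if (d <= r && d >= -r) ++A;
            }
        }
    }
    double sampen = (A > 0 && B > 0) ? -std::log((double)A / (double)B)
                                     : NA_REAL;
    return NumericVector::create(apen, sampen);
}
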