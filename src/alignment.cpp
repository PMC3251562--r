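#include <Rcpp.h>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

// Shift convention: bin i (0-based) of `a` is compared with bin i + r of `b`.
// Positive r therefore moves `b` to the left relative to `a`; negative r
// moves it to the right. Admissible overlap indices for `a` are
// [max(0, -r), min(L1, L2 - r)).

static double shift_score(const NumericMatrix &a, const NumericMatrix &b,
                          int r, int &n_overlap) {
    const int L1 = a.ncol(), L2 = b.ncol(), T = a.nrow();
    const int i0 = std::max(0, -r);
    const int i1 = std::min(L1, L2 - r);
    n_overlap = i1 - i0;
    double s = 0.0;
    for (int t = 0; t < T; ++t) {
        for (int i = i0; i < i1; ++i) {
            const double d = a(t, i) - b(t, i + r);
            s += d * d;
        }
    }
    return s / (double)(n_overlap * T);
}

static NumericMatrix mirror_matrix(const NumericMatrix &b) {
    NumericMatrix out(b.nrow(), b.ncol());
    const int L = b.ncol();
    for (int t = 0; t < b.nrow(); ++t)
        for (int j = 0; j < L; ++j)
            out(t, j) = b(t, L - 1 - j);
    return out;
}

// [[Rcpp::export]]
List pair_score_cpp(NumericMatrix a, NumericMatrix b, int r) {
    const int i0 = std::max(0, -r);
    const int i1 = std::min((int)a.ncol(), (int)b.ncol() - r);
    if (i1 - i0 < 1)
        stop("shift r=%d yields zero overlap", r);
    int n_overlap = 0;
    const double s = shift_score(a, b, r, n_overlap);
    return List::create(_["score"] = s, _["n_overlap"] = n_overlap);
}

// Exhaustive scan over all shifts satisfying the overlap constraint, in the
// forward and (optionally) mirrored orientation of `b`. Deterministic
// tie-breaking: lowest score, then smaller |r|, then non-mirrored, then
// smaller signed r.
// [[Rcpp::export]]
List best_alignment_cpp(NumericMatrix a, NumericMatrix b, int min_overlap,
                        bool allow_mirror) {
    const int L1 = a.ncol(), L2 = b.ncol();
    bool have = false;
    double best_s = 0.0;
    int best_r = 0, best_m = 0, best_n = 0;
    long n_evaluated = 0;
    const int m_max = allow_mirror ? 1 : 0;
    for (int m = 0; m <= m_max; ++m) {
        NumericMatrix bb = (m == 0) ? b : mirror_matrix(b);
        for (int r = -(L1 - 1); r <= L2 - 1; ++r) {
            const int i0 = std::max(0, -r);
            const int i1 = std::min(L1, L2 - r);
            if (i1 - i0 < min_overlap)
                continue;
            int n = 0;
            const double s = shift_score(a, bb, r, n);
            ++n_evaluated;
            bool better;
            if (!have)
                better = true;
            else if (s != best_s)
                better = s < best_s;
            else if (std::abs(r) != std::abs(best_r))
                better = std::abs(r) < std::abs(best_r);
            else if (m != best_m)
                better = m < best_m;
            else
                better = r < best_r;
            if (better) {
                have = true;
                best_s = s;
                best_r = r;
                best_m = m;
                best_n = n;
            }
        }
    }
    return List::create(_["ok"] = have, _["score"] = best_s, _["r"] = best_r,
                        _["mirrored"] = (best_m == 1), _["n_overlap"] = best_n,
                        _["n_evaluated"] = (double)n_evaluated);
}
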