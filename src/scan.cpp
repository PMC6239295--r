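#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped window placement of a profile on an integer-coded sequence.
// Codes are 1-based; code 21 (non-residue) must map to the sentinel column
// appended by the R caller.
static void best_window(const int* s, int n, const NumericMatrix& S,
                        double* best, int* arg) {
    int L = S.nrow();
    int W = n - L + 1;
    *best = R_NegInf;
    *arg = 1;
    for (int i = 0; i < W; ++i) {
        double tot = 0.0;
        for (int j = 0; j < L; ++j) tot += S(j, s[i + j] - 1);
        if (tot > *best) { *best = tot; *arg = i + 1; }
    }
}

// [[Rcpp::export]]
NumericVector window_scores_max(IntegerVector seq, NumericMatrix S) {
    std::vector<int> s(seq.begin(), seq.end());
    double best; int arg;
    best_window(s.data(), (int)s.size(), S, &best, &arg);
    return NumericVector::create(best, (double)arg);
}

// Does any window placement score at least `thr`? Equivalent to
// (max window score >= thr) but prunes a window as soon as the running sum
// plus the best the remaining columns could add falls short of thr.
static bool any_window_ge(const int* s, int n, const NumericMatrix& S,
                          double thr, const double* sufmax) {
    int L = S.nrow();
    int W = n - L + 1;
    for (int i = 0; i < W; ++i) {
        double tot = 0.0;
        int j = 0;
        for (; j < L; ++j) {
            tot += S(j, s[i + j] - 1);
            if (tot + sufmax[j + 1] < thr) break;
        }
        if (j == L && tot >= thr) return true;
    }
    return false;
}

// Count residue-shuffled decoys whose best window score reaches `observed`.
// Shuffling uses R's RNG (Fisher-Yates), so results are reproducible under
// set.seed(). Stops early once `stop_at` exceedances are seen, at which
// point the final smoothed p-value is already above the caller's cutoff.
// [[Rcpp::export]]
IntegerVector decoy_exceedance_count(IntegerVector seq, NumericMatrix S,
                                     double observed, int n_decoys,
                                     int stop_at) {
    std::vector<int> s(seq.begin(), seq.end());
    int n = (int)s.size();
    int L = S.nrow();
    // suffix sums of per-column maxima, for window pruning
    std::vector<double> sufmax(L + 1, 0.0);
    for (int j = L - 1; j >= 0; --j) {
        double cm = R_NegInf;
        for (int r = 0; r < S.ncol(); ++r)
            if (S(j, r) > cm) cm = S(j, r);
        sufmax[j] = sufmax[j + 1] + cm;
    }
    int count = 0, used = 0;
    for (int d = 0; d < n_decoys; ++d) {
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            std::swap(s[i], s[j]);
        }
        ++used;
        if (any_window_ge(s.data(), n, S, observed, sufmax.data())) {
            ++count;
            if (count >= stop_at) break;
        }
    }
    return IntegerVector::create(count, used);
}
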