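#include <Rcpp.h>
using namespace Rcpp;

// Unit-cost global (Needleman-Wunsch) alignment of two short strings:
// match +1, mismatch -1, gap -1 per base (linear gap cost).  Used to
// decompose an anchored read segment against a reference repeat array into
// substitutions and indel runs; indel runs are subsequently left-shifted by
// the caller, so the traceback tie-break (diagonal > up > left) only needs
// to be deterministic.  Returns c(aligned_a, aligned_b) with '-' gaps.
//
// [[Rcpp::export(name = ".nw_align_cpp")]]
CharacterVector nw_align_cpp(std::string a, std::string b) {
    const int n = static_cast<int>(a.size());
    const int m = static_cast<int>(b.size());
    std::vector<int> F((n + 1) * (m + 1));
    auto at = [m](int i, int j) { return i * (m + 1) + j; };
    for (int i = 0; i <= n; ++i) F[at(i, 0)] = -i;
    for (int j = 0; j <= m; ++j) F[at(0, j)] = -j;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            const int diag = F[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1);
            const int up   = F[at(i - 1, j)] - 1;   // gap in b
            const int left = F[at(i, j - 1)] - 1;   // gap in a
            int best = diag;
            if (up > best) best = up;
            if (left > best) best = left;
            F[at(i, j)] = best;
        }
    }
    std::string ra, rb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            F[at(i, j)] == F[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 1 : -1)) {
            ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
        } else if (i > 0 && F[at(i, j)] == F[at(i - 1, j)] - 1) {
            ra.push_back(a[i - 1]); rb.push_back('-'); --i;
        } else {
            ra.push_back('-'); rb.push_back(b[j - 1]); --j;
        }
    }
    std::reverse(ra.begin(), ra.end());
    std::reverse(rb.begin(), rb.end());
    return CharacterVector::create(ra, rb);
}
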