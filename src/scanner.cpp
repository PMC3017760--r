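#include <Rcpp.h>
using namespace Rcpp;

// Greedy maximal perfect tandem repeat scan.
//
// At each scan position every motif size 1..max_motif is tried; the maximal
// perfect run with that period is measured by forward matching s[j] == s[j+m]
// (an 'N' on either side of the comparison terminates the run, so a reported
// array never contains N).  Only full motif copies count towards the array:
// array_length = motif_size * floor(run_length / motif_size).  The candidate
// with the largest array wins; ties go to the smaller motif size, which also
// guarantees the reported motif is primitive (a non-primitive period p | m
// always yields an array at least as long for p, and p < m wins the tie).
// Scanning resumes immediately after a recorded locus.
//
// [[Rcpp::export(name = ".scan_ssrs_cpp")]]
DataFrame scan_ssrs_cpp(std::string seq, int min_repeats, int max_motif) {
    const int n = static_cast<int>(seq.size());
    std::vector<int> starts, ends, sizes, reps;
    std::vector<std::string> motifs;

    int i = 0;
    while (i < n) {
        if (seq[i] == 'N') { ++i; continue; }
        int best_arr = 0, best_m = 0, best_rep = 0;
        int mmax = std::min(max_motif, (n - i) / min_repeats);
        for (int m = 1; m <= mmax; ++m) {
            int j = i;
            while (j + m < n && seq[j] != 'N' && seq[j + m] != 'N' &&
                   seq[j] == seq[j + m])
                ++j;
            const int run = m + (j - i);        // maximal perfect run length
            const int rn  = run / m;            // full units only
            if (rn >= min_repeats) {
                const int arr = m * rn;
                if (arr > best_arr) { best_arr = arr; best_m = m; best_rep = rn; }
            }
        }
        if (best_arr > 0) {
            starts.push_back(i);
            ends.push_back(i + best_arr);
            motifs.push_back(seq.substr(i, best_m));
            sizes.push_back(best_m);
            reps.push_back(best_rep);
            i += best_arr;
        } else {
            ++i;
        }
    }
    return DataFrame::create(
        _["start"] = starts, _["end"] = ends, _["motif"] = motifs,
        _["motif_size"] = sizes, _["repeat_number"] = reps,
        _["stringsAsFactors"] = false);
}

// Does any qualifying perfect repeat (>= min_repeats full units, motif size
// 1..max_motif) contain 1-based position pos1 of seq?  Used by the
// simulator's background scrub to validate candidate base swaps without
// paying per-call data.frame construction costs.
//
// [[Rcpp::export(name = ".repeat_at_cpp")]]
bool repeat_at_cpp(std::string seq, int pos1, int min_repeats, int max_motif) {
    const int n = static_cast<int>(seq.size());
    const int p = pos1 - 1;
    if (p < 0 || p >= n || seq[p] == 'N') return false;
    for (int m = 1; m <= max_motif; ++m) {
        int a = p;
        while (a > 0 && a - 1 + m < n && seq[a - 1] != 'N' &&
               seq[a - 1 + m] != 'N' && seq[a - 1] == seq[a - 1 + m])
            --a;
        int e = p;
        while (e + m < n && seq[e] != 'N' && seq[e + m] != 'N' &&
               seq[e] == seq[e + m])
            ++e;
        const int len = e + m - a;
        const int reps = len / m;
        if (reps >= min_repeats && p < a + m * reps) return true;
    }
    return false;
}
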