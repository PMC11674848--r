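#include <Rcpp.h>
using namespace Rcpp;

// Ungapped antiparallel duplex scan between a query sequence and the
// reverse complement of a target. seq1 is the query (5'->3'), seq2rc the
// reverse-complemented target, both encoded 0..3 (A,C,G,T) with -1 for
// other letters. stack[a*4+b] is the stacking energy (kcal/mol, <= 0)
// contributed when query positions carrying bases a,b are consecutively
// paired. A mismatch (or non-ACGT base) terminates a stack run. Returns
// the minimum run energy and the 0-based run coordinates on both inputs.
// [[Rcpp::export(name = ".duplex_scan")]]
List duplex_scan(IntegerVector seq1, IntegerVector seq2rc,
                 NumericVector stack) {
    const int n1 = seq1.size(), n2 = seq2rc.size();
    double best = 0.0;
    int b_i = -1, b_j = -1, b_len = 0;
    for (int d = -(n1 - 1); d < n2; ++d) {
        // diagonal: seq1[i] aligned with seq2rc[i + d]
        int i0 = d < 0 ? -d : 0;
        int i1 = std::min(n1, n2 - d);
        int run_start = -1;
        double run_e = 0.0;
        bool prev_match = false;
        for (int i = i0; i <= i1; ++i) {
            bool match = false;
            if (i < i1) {
                int a = seq1[i], b = seq2rc[i + d];
                match = (a >= 0 && a == b);
            }
            if (match) {
                if (prev_match) {
                    run_e += stack[seq1[i - 1] * 4 + seq1[i]];
                } else {
                    run_start = i;
                    run_e = 0.0;
                }
                prev_match = true;
            } else {
                if (prev_match && run_e < best) {
                    best = run_e;
                    b_i = run_start;
                    b_j = run_start + d;
                    b_len = i - run_start;
                }
                prev_match = false;
            }
        }
    }
    return List::create(_["energy"] = best, _["q_start"] = b_i,
                        _["rc_start"] = b_j, _["length"] = b_len);
}
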