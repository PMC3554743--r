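#include <Rcpp.h>
using namespace Rcpp;

// For each read, locate the leftmost position where a prefix of the 3'
// adapter matches with at most floor(max_mismatch_rate * overlap)
// mismatches and overlap >= min_overlap. Returns the 0-based adapter start
// (= insert length), or -1 when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector adapter_match_pos(CharacterVector reads, std::string adapter,
                                int min_overlap, double max_mismatch_rate) {
    int nr = reads.size();
    int alen = (int)adapter.size();
    IntegerVector out(nr);
    for (int r = 0; r < nr; ++r) {
        const char* rd = CHAR(STRING_ELT(reads, r));
        int len = (int)LENGTH(STRING_ELT(reads, r));
        int found = -1;
        for (int p = 0; p + min_overlap <= len; ++p) {
            int ov = std::min(len - p, alen);
            int allowed = (int)std::floor(max_mismatch_rate * ov);
            int mm = 0;
            bool ok = true;
            for (int t = 0; t < ov; ++t) {
                if (rd[p + t] != adapter[t]) {
                    if (++mm > allowed) { ok = false; break; }
                }
            }
            if (ok) { found = p; break; }
        }
        out[r] = found;
    }
    return out;
}
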