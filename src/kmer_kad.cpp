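#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit encoding; k-mers containing any non-ACGT base are invalid.
static inline int base2bits(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return -1;
}

// Roll canonical k-mer codes over a sequence. codes[i] is the canonical code of
// the k-mer starting at 0-based position i, valid[i] FALSE where the window
// contains a non-ACGT base. Positions beyond length-k are not emitted.
static void roll_canonical(const std::string& seq, int k,
                           std::vector<uint64_t>& codes,
                           std::vector<bool>& valid) {
    const size_t L = seq.size();
    const size_t npos = (L >= (size_t)k) ? L - k + 1 : 0;
    codes.assign(npos, 0);
    valid.assign(npos, false);
    if (npos == 0) return;
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    uint64_t fwd = 0, rev = 0;
    int run = 0; // length of current valid-base run
    for (size_t i = 0; i < L; ++i) {
        int b = base2bits(seq[i]);
        if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
        if (++run >= k) {
            size_t p = i - k + 1;
            if (p < npos) {
                codes[p] = fwd < rev ? fwd : rev;
                valid[p] = true;
            }
        }
    }
}

//' @useDynLib contigMend, .registration = TRUE
//' @importFrom Rcpp sourceCpp
// [[Rcpp::export(name = ".contigKmerCounts")]]
List contigKmerCounts(std::string contig, std::vector<std::string> reads, int k) {
    if (k < 3 || k > 31) stop("k must be in [3, 31]");
    std::vector<uint64_t> codes;
    std::vector<bool> valid;
    roll_canonical(contig, k, codes, valid);
    const size_t npos = codes.size();

    // n: copies of each canonical k-mer within the contig
    std::unordered_map<uint64_t, int> ntab;
    ntab.reserve(npos * 2 + 8);
    for (size_t i = 0; i < npos; ++i)
        if (valid[i]) ++ntab[codes[i]];

    // c: abundance in mapped reads, restricted to k-mers present in the contig
    std::unordered_map<uint64_t, double> ctab;
    ctab.reserve(ntab.size() * 2 + 8);
    std::vector<uint64_t> rcodes;
    std::vector<bool> rvalid;
    for (const std::string& rd : reads) {
        roll_canonical(rd, k, rcodes, rvalid);
        for (size_t i = 0; i < rcodes.size(); ++i) {
            if (!rvalid[i]) continue;
            auto it = ntab.find(rcodes[i]);
            if (it != ntab.end()) ctab[rcodes[i]] += 1.0;
        }
    }

    IntegerVector n_at(npos);
    NumericVector c_at(npos);
    LogicalVector ok(npos);
    for (size_t i = 0; i < npos; ++i) {
        if (!valid[i]) {
            n_at[i] = NA_INTEGER;
            c_at[i] = NA_REAL;
            ok[i] = false;
            continue;
        }
        n_at[i] = ntab[codes[i]];
        auto it = ctab.find(codes[i]);
        c_at[i] = (it == ctab.end()) ? 0.0 : it->second;
        ok[i] = true;
    }

    // read abundances of distinct single-copy contig k-mers (depth estimator)
    std::vector<double> sc;
    sc.reserve(ntab.size());
    for (auto& kv : ntab) {
        if (kv.second == 1) {
            auto it = ctab.find(kv.first);
            sc.push_back(it == ctab.end() ? 0.0 : it->second);
        }
    }
    return List::create(_["n"] = n_at, _["c"] = c_at, _["valid"] = ok,
                        _["single_copy_abundance"] = NumericVector(sc.begin(), sc.end()));
}
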