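#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

// 2-bit base codes; A<C<G<T so lexicographic order of ACGT strings equals
// numeric order of the big-endian 2-bit encodings.
static inline int baseCode(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static inline std::string decodeKmer(uint64_t code, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = BASES[code & 3ULL];
        code >>= 2;
    }
    return s;
}

// Encode an ACGT string; returns false if any base is not ACGT.
static inline bool encodeString(const std::string& s, uint64_t& fwd, uint64_t& rev) {
    int k = (int)s.size();
    fwd = 0;
    rev = 0;
    for (int i = 0; i < k; ++i) {
        int b = baseCode(s[i]);
        if (b < 0) return false;
        fwd = (fwd << 2) | (uint64_t)b;
        rev |= ((uint64_t)(3 - b)) << (2 * i);
    }
    return true;
}

//' @noRd
// [[Rcpp::export(name = ".cppCanonicalWindows")]]
CharacterVector cppCanonicalWindows(std::string seq, int k) {
    int n = (int)seq.size();
    int nwin = n - k + 1;
    if (nwin < 1) return CharacterVector(0);
    CharacterVector out(nwin, NA_STRING);
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // number of consecutive valid bases ending at i
    for (int i = 0; i < n; ++i) {
        int b = baseCode(seq[i]);
        if (b < 0) {
            valid = 0;
            fwd = 0;
            rev = 0;
            continue;
        }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
        ++valid;
        if (valid >= k) {
            uint64_t canon = fwd < rev ? fwd : rev;
            out[i - k + 1] = decodeKmer(canon, k);
        }
    }
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".cppCanonicalKmers")]]
CharacterVector cppCanonicalKmers(CharacterVector kmers) {
    int n = kmers.size();
    CharacterVector out(n, NA_STRING);
    for (int i = 0; i < n; ++i) {
        if (kmers[i] == NA_STRING) continue;
        std::string s = as<std::string>(kmers[i]);
        uint64_t fwd, rev;
        if ((int)s.size() < 1 || (int)s.size() > 31) stop("kmer length must be in 1..31");
        if (!encodeString(s, fwd, rev)) continue; // non-ACGT -> NA
        out[i] = decodeKmer(fwd < rev ? fwd : rev, (int)s.size());
    }
    return out;
}

// Count canonical kmer hits of a read set against an indexed kmer set.
// indexKmers: canonical kmer strings (length k each); nodeIds / nodeStarts
// describe, in CSR form, the 1-based allele-node ids each kmer maps to.
//' @noRd
// [[Rcpp::export(name = ".cppCountReads")]]
List cppCountReads(CharacterVector reads, CharacterVector indexKmers,
                   IntegerVector nodeIds, IntegerVector nodeStarts,
                   int k, int nNodes) {
    std::unordered_map<uint64_t, int> lut; // canonical code -> kmer row
    lut.reserve(indexKmers.size() * 2);
    for (int i = 0; i < indexKmers.size(); ++i) {
        std::string s = as<std::string>(indexKmers[i]);
        if ((int)s.size() != k) stop("index kmer of wrong length");
        uint64_t fwd, rev;
        if (!encodeString(s, fwd, rev)) stop("index kmer with non-ACGT base");
        uint64_t canon = fwd < rev ? fwd : rev;
        lut[canon] = i;
    }
    std::vector<double> counts(nNodes, 0.0);
    uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    double totalKmers = 0;
    for (int r = 0; r < reads.size(); ++r) {
        if (reads[r] == NA_STRING) continue;
        const char* s = CHAR(STRING_ELT(reads, r));
        int n = (int)LENGTH(STRING_ELT(reads, r));
        uint64_t fwd = 0, rev = 0;
        int valid = 0;
        for (int i = 0; i < n; ++i) {
            int b = baseCode(s[i]);
            if (b < 0) {
                valid = 0;
                fwd = 0;
                rev = 0;
                continue;
            }
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
            rev = (rev >> 2) | (((uint64_t)(3 - b)) << (2 * (k - 1)));
            ++valid;
            if (valid >= k) {
                totalKmers += 1;
                uint64_t canon = fwd < rev ? fwd : rev;
                auto it = lut.find(canon);
                if (it != lut.end()) {
                    int row = it->second;
                    for (int j = nodeStarts[row]; j < nodeStarts[row + 1]; ++j)
                        counts[nodeIds[j] - 1] += 1.0;
                }
            }
        }
    }
    return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                        _["totalReads"] = (double)reads.size(),
                        _["totalKmers"] = totalKmers);
}
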