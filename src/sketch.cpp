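#include <Rcpp.h>
#include <cstdint>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <string>

using namespace Rcpp;

// Hashes are masked to 53 bits so every value is exactly representable as an
// R double; MinHash only needs a uniform order on k-mers, not the full 64 bits.
static const uint64_t HASH_MASK = (uint64_t(1) << 53) - 1;

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

// FNV-1a over the canonical k-mer, finalised with a seed-dependent mix.
static inline uint64_t hash_kmer(const char* s, int k, uint64_t seed) {
    uint64_t h = 0xCBF29CE484222325ULL;
    for (int i = 0; i < k; ++i) {
        h ^= (uint64_t)(unsigned char)s[i];
        h *= 0x100000001B3ULL;
    }
    return splitmix64(h ^ splitmix64(seed));
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static inline bool valid_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List cpp_sketch(std::string seq, int k, int s, double hash_seed) {
    int n = (int)seq.size();
    if (k < 1 || n < k) stop("sequence shorter than k");
    for (int i = 0; i < n; ++i) seq[i] = (char)toupper((unsigned char)seq[i]);
    uint64_t seed = (uint64_t)hash_seed;

    std::unordered_set<uint64_t> seen;
    seen.reserve((size_t)(n - k + 1));
    std::string canon(k, 'A');
    for (int i = 0; i + k <= n; ++i) {
        bool ok = true;
        for (int j = 0; j < k; ++j) {
            if (!valid_base(seq[i + j])) { ok = false; break; }
        }
        if (!ok) continue;
        // canonical k-mer: lexicographic min of forward and reverse complement
        bool use_rc = false;
        for (int j = 0; j < k; ++j) {
            char f = seq[i + j];
            char r = comp(seq[i + k - 1 - j]);
            if (r < f) { use_rc = true; break; }
            if (f < r) { break; }
        }
        if (use_rc) {
            for (int j = 0; j < k; ++j) canon[j] = comp(seq[i + k - 1 - j]);
        } else {
            for (int j = 0; j < k; ++j) canon[j] = seq[i + j];
        }
        seen.insert(hash_kmer(canon.data(), k, seed) & HASH_MASK);
    }

    std::vector<uint64_t> all(seen.begin(), seen.end());
    size_t keep = std::min((size_t)s, all.size());
    std::partial_sort(all.begin(), all.begin() + keep, all.end());
    NumericVector hashes((R_xlen_t)keep);
    for (size_t i = 0; i < keep; ++i) hashes[i] = (double)all[i];
    return List::create(_["hashes"] = hashes,
                        _["n_distinct"] = (double)all.size());
}

// Mash-style Jaccard estimate from two sorted bottom-s sketches: scan the
// merged order, consider the s smallest union hashes, count those present in
// both. Returns c(jaccard, n_considered).
static inline void merge_jaccard(const NumericVector& a, const NumericVector& b,
                                 int s, double& jaccard, int& considered) {
    R_xlen_t i = 0, j = 0, na = a.size(), nb = b.size();
    int taken = 0, shared = 0;
    while (taken < s && (i < na || j < nb)) {
        if (i < na && j < nb && a[i] == b[j]) {
            ++shared; ++i; ++j;
        } else if (j >= nb || (i < na && a[i] < b[j])) {
            ++i;
        } else {
            ++j;
        }
        ++taken;
    }
    considered = taken;
    jaccard = taken > 0 ? (double)shared / (double)taken : 0.0;
}

// [[Rcpp::export]]
NumericVector cpp_jaccard(NumericVector a, NumericVector b, int s) {
    double j; int t;
    merge_jaccard(a, b, s, j, t);
    return NumericVector::create(j, (double)t);
}

// [[Rcpp::export]]
DataFrame cpp_pairwise(List hash_list, int s, int k, double threshold) {
    R_xlen_t n = hash_list.size();
    std::vector<NumericVector> hs(n);
    for (R_xlen_t i = 0; i < n; ++i) hs[i] = as<NumericVector>(hash_list[i]);
    std::vector<int> ia, ib;
    std::vector<double> jac, dist;
    for (R_xlen_t i = 0; i < n; ++i) {
        for (R_xlen_t j = i + 1; j < n; ++j) {
            double jc; int t;
            merge_jaccard(hs[i], hs[j], s, jc, t);
            double d;
            if (jc <= 0.0) {
                d = 1.0;
            } else {
                d = -std::log(2.0 * jc / (1.0 + jc)) / (double)k;
                if (d > 1.0) d = 1.0;
                if (d < 0.0) d = 0.0;
            }
            if (d <= threshold) {
                ia.push_back((int)i + 1);
                ib.push_back((int)j + 1);
                jac.push_back(jc);
                dist.push_back(d);
            }
        }
    }
    return DataFrame::create(_["i"] = ia, _["j"] = ib,
                             _["jaccard"] = jac, _["distance"] = dist,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
double cpp_hash_string(std::string x, double hash_seed) {
    return (double)(hash_kmer(x.data(), (int)x.size(), (uint64_t)hash_seed) & HASH_MASK);
}
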