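#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// k-mer hashing
//
// A k-mer is packed into a uint64 (2 bits/base, A=0 C=1 G=2 T=3) and mixed
// with the seed through splitmix64. The value is truncated to 53 bits so it
// is exactly representable as an R double; comparisons (minimizer selection)
// use the same truncated value everywhere, keeping digests reproducible.
// ---------------------------------------------------------------------------

static inline uint64_t splitmix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

static inline int base_code(char b) {
    switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline uint64_t hash53(uint64_t kcode, uint64_t seed) {
    return splitmix64(kcode ^ splitmix64(seed)) >> 11;
}

// [[Rcpp::export]]
NumericVector kmer_hash_cpp(CharacterVector kmers, int seed) {
    R_xlen_t n = kmers.size();
    NumericVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string km = as<std::string>(kmers[i]);
        uint64_t code = 0;
        for (size_t j = 0; j < km.size(); ++j) {
            int b = base_code(km[j]);
            if (b < 0) stop("k-mer contains a non-ACGT character: '%s'", km.c_str());
            code = (code << 2) | (uint64_t)b;
        }
        out[i] = (double)hash53(code, (uint64_t)(uint32_t)seed);
    }
    return out;
}

// ---------------------------------------------------------------------------
// Minimizer digestion: slide a length-w window one base at a time, pick the
// constituent k-mer with minimal hash (leftmost on ties), and append its
// integer code (1..4^k) whenever it differs from the previously appended
// value. Windows containing non-ACGT characters are skipped, which is
// equivalent to digesting ACGT segments independently.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector digest_cpp(std::string seq, int k, int w, int seed) {
    int n = (int)seq.size();
    std::vector<int> out;
    if (n < w) return IntegerVector(0);
    uint64_t useed = (uint64_t)(uint32_t)seed;

    // per-position base codes and prefix counts of invalid bases
    std::vector<int> bc(n);
    std::vector<int> bad(n + 1, 0);
    for (int i = 0; i < n; ++i) {
        bc[i] = base_code(seq[i]);
        bad[i + 1] = bad[i] + (bc[i] < 0 ? 1 : 0);
    }
    // packed k-mer codes at each start (valid only where no bad base inside)
    int nk = n - k + 1;
    std::vector<uint64_t> kc(nk, 0);
    for (int i = 0; i < nk; ++i) {
        if (bad[i + k] - bad[i] > 0) continue;
        uint64_t code = 0;
        for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t)bc[i + j];
        kc[i] = code;
    }
    int last = -1;
    int nwin = n - w + 1;
    int span = w - k; // k-mer starts s..s+span
    for (int s = 0; s < nwin; ++s) {
        if (bad[s + w] - bad[s] > 0) continue;
        int best = s;
        uint64_t besth = hash53(kc[s], useed);
        for (int j = s + 1; j <= s + span; ++j) {
            uint64_t h = hash53(kc[j], useed);
            if (h < besth) { besth = h; best = j; }
        }
        int code = (int)kc[best] + 1; // 1-based symbol code
        if (code != last) { out.push_back(code); last = code; }
    }
    return wrap(out);
}

// ---------------------------------------------------------------------------
// Suffix array by prefix doubling (O(n log^2 n)); fine at desk scale.
// Input: integer text (sentinels are negative, data symbols positive).
// Output: 0-based suffix array.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector sa_build_cpp(IntegerVector text) {
    int n = text.size();
    if (n == 0) return IntegerVector(0);
    std::vector<int> sa(n), rnk(n), tmp(n);
    for (int i = 0; i < n; ++i) { sa[i] = i; rnk[i] = text[i]; }
    for (int h = 1;; h <<= 1) {
        auto cmp = [&](int a, int b) {
            if (rnk[a] != rnk[b]) return rnk[a] < rnk[b];
            int ra = a + h < n ? rnk[a + h] : INT_MIN;
            int rb = b + h < n ? rnk[b + h] : INT_MIN;
            return ra < rb;
        };
        std::sort(sa.begin(), sa.end(), cmp);
        tmp[sa[0]] = 0;
        for (int i = 1; i < n; ++i)
            tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
        rnk = tmp;
        if (rnk[sa[n - 1]] == n - 1) break;
    }
    return wrap(sa);
}

// Kasai LCP: lcp[i] = length of common prefix of suffixes sa[i-1], sa[i]; lcp[0]=0.
// [[Rcpp::export]]
IntegerVector lcp_kasai_cpp(IntegerVector text, IntegerVector sa) {
    int n = text.size();
    IntegerVector lcp(n);
    std::vector<int> rnk(n);
    for (int i = 0; i < n; ++i) rnk[sa[i]] = i;
    int h = 0;
    for (int i = 0; i < n; ++i) {
        if (rnk[i] > 0) {
            int j = sa[rnk[i] - 1];
            while (i + h < n && j + h < n && text[i + h] == text[j + h]) ++h;
            lcp[rnk[i]] = h;
            if (h > 0) --h;
        } else {
            h = 0;
        }
    }
    return lcp;
}

// ---------------------------------------------------------------------------
// Thresholds: for each gap between consecutive same-character runs
// (e = last row of the earlier run, s = first row of the later run), the
// threshold is the row of the leftmost minimum of LCP[e+1..s]. Rows strictly
// above the threshold jump up; rows at or below jump down.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector thresholds_build_cpp(IntegerVector lcp, IntegerVector gapE, IntegerVector gapS) {
    int g = gapE.size();
    IntegerVector thr(g);
    for (int i = 0; i < g; ++i) {
        int e = gapE[i], s = gapS[i];
        int best = e + 1, bestv = lcp[e + 1];
        for (int j = e + 2; j <= s; ++j)
            if (lcp[j] < bestv) { bestv = lcp[j]; best = j; }
        thr[i] = best;
    }
    return thr;
}

// ---------------------------------------------------------------------------
// Query core: LF stepping over the run-length BWT with threshold jumps.
// The index is passed as a list of flat integer vectors (all 0-based rows /
// text offsets); see .indexCore() on the R side for the layout.
// ---------------------------------------------------------------------------

struct QIdx {
    int n, r;
    IntegerVector runStarts, runChars, runLengths, occBefore;
    IntegerVector symVals, countsBelow;
    IntegerVector symOff, cStart, cEnd, cIdx, thrOff, thrRows;
    bool hasDoc, hasSA;
    IntegerVector firstLabel, lastLabel, saFirst, saLast;
};

static QIdx parse_idx(List L) {
    QIdx I;
    I.n = as<int>(L["n"]);
    I.runStarts = L["runStarts"]; I.runChars = L["runChars"];
    I.runLengths = L["runLengths"]; I.occBefore = L["occBefore"];
    I.symVals = L["symVals"]; I.countsBelow = L["countsBelow"];
    I.symOff = L["symOff"]; I.cStart = L["cStart"]; I.cEnd = L["cEnd"];
    I.cIdx = L["cIdx"]; I.thrOff = L["thrOff"]; I.thrRows = L["thrRows"];
    I.r = I.runStarts.size();
    I.hasDoc = L.containsElementNamed("firstLabel") && !Rf_isNull(L["firstLabel"]);
    if (I.hasDoc) { I.firstLabel = L["firstLabel"]; I.lastLabel = L["lastLabel"]; }
    I.hasSA = L.containsElementNamed("saFirst") && !Rf_isNull(L["saFirst"]);
    if (I.hasSA) { I.saFirst = L["saFirst"]; I.saLast = L["saLast"]; }
    return I;
}

static inline int find_run(const QIdx &I, int q) {
    // index of the run containing row q
    const int *b = I.runStarts.begin();
    return (int)(std::upper_bound(b, b + I.r, q) - b) - 1;
}

static inline int sym_index(const QIdx &I, int c) {
    const int *b = I.symVals.begin();
    const int *e = b + I.symVals.size();
    const int *it = std::lower_bound(b, e, c);
    if (it == e || *it != c) return -1;
    return (int)(it - b);
}

static inline int lf_row(const QIdx &I, int q) {
    int j = find_run(I, q);
    int ci = sym_index(I, I.runChars[j]);
    return I.countsBelow[ci] + I.occBefore[j] + (q - I.runStarts[j]);
}

// [[Rcpp::export]]
IntegerVector lf_cpp(List idx, IntegerVector rows) {
    QIdx I = parse_idx(idx);
    int m = rows.size();
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) out[i] = lf_row(I, rows[i]);
    return out;
}

// One right-to-left pass over `read` (integer symbols; 0 or any code absent
// from the index alphabet acts as an unknown symbol). Returns PMLs, the
// class-label vector, the resumable state, and (optionally, for MS) the text
// offset candidate recorded at each step.
// [[Rcpp::export]]
List query_run_cpp(List idx, IntegerVector read, int row0, int len0, int lab0,
                   int sa0, bool wantOffsets) {
    QIdx I = parse_idx(idx);
    if (wantOffsets && !I.hasSA)
        stop("index lacks matching-statistics support; rebuild with msSupport = TRUE");
    int m = read.size();
    IntegerVector pml(m), ca(m);
    IntegerVector off(wantOffsets ? m : 0);
    int q = row0, len = len0, lab = lab0;
    long cursa = sa0;
    for (int i = m - 1; i >= 0; --i) {
        int c = read[i];
        int ci = c > 0 ? sym_index(I, c) : -1;
        bool known = ci >= 0 && (I.symOff[ci + 1] > I.symOff[ci]);
        if (!known) { // symbol absent from index alphabet: reset, row unchanged
            len = 0; pml[i] = 0; ca[i] = lab;
            if (wantOffsets) off[i] = -1;
            continue;
        }
        int j = find_run(I, q);
        if (I.runChars[j] == c) { // case 1: extend
            ++len; pml[i] = len; ca[i] = lab;
            q = lf_row(I, q);
            if (wantOffsets) { cursa -= 1; off[i] = (int)cursa; }
        } else { // case 2: threshold jump to the nearest preferred c-run boundary
            int lo = I.symOff[ci], hi = I.symOff[ci + 1];
            const int *cs = I.cStart.begin();
            int a = (int)(std::upper_bound(cs + lo, cs + hi, q) - (cs + lo));
            // runs lo..lo+a-1 end before q; runs lo+a..hi-1 start after q
            bool down; int runG, b;
            if (a == 0) {
                down = true; runG = I.cIdx[lo]; b = I.cStart[lo];
            } else if (a == hi - lo) {
                down = false; runG = I.cIdx[hi - 1]; b = I.cEnd[hi - 1];
            } else {
                int t = I.thrRows[I.thrOff[ci] + (a - 1)];
                if (q < t) { down = false; runG = I.cIdx[lo + a - 1]; b = I.cEnd[lo + a - 1]; }
                else       { down = true;  runG = I.cIdx[lo + a];     b = I.cStart[lo + a]; }
            }
            len = 0; pml[i] = 0;
            if (I.hasDoc) lab = down ? I.firstLabel[runG] : I.lastLabel[runG];
            ca[i] = lab;
            if (wantOffsets) cursa = down ? I.saFirst[runG] : I.saLast[runG];
            q = lf_row(I, b);
            if (wantOffsets) { cursa -= 1; off[i] = (int)cursa; }
        }
    }
    List state = List::create(_["row"] = q, _["len"] = len, _["lastLabel"] = lab,
                              _["sa"] = (int)cursa);
    List out = List::create(_["pml"] = pml, _["ca"] = ca, _["state"] = state);
    if (wantOffsets) out["off"] = off;
    return out;
}

// MS second pass: longest common extension of read[i..] vs text[off[i]..].
// Sentinels in the text are negative and never match read symbols, so
// matches cannot cross document boundaries.
// [[Rcpp::export]]
IntegerVector ms_extend_cpp(IntegerVector text, IntegerVector read, IntegerVector off) {
    int m = read.size(), n = text.size();
    IntegerVector ms(m);
    for (int i = 0; i < m; ++i) {
        if (off[i] < 0) { ms[i] = 0; continue; }
        int l = 0;
        while (i + l < m && off[i] + l < n && read[i + l] == text[off[i] + l]) ++l;
        ms[i] = l;
    }
    return ms;
}
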