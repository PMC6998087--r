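#include <Rcpp.h>
#include <vector>
#include <map>
#include <string>
#include <algorithm>
#include <cctype>
#include <cmath>

using namespace Rcpp;

// IUPAC bitmask: A=1, C=2, G=4, T=8; degenerate codes are unions.
static inline int base_bits(char c) {
    switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return 0;
    }
}

static std::vector<unsigned char> encode(const std::string &s) {
    std::vector<unsigned char> v(s.size());
    for (size_t i = 0; i < s.size(); ++i)
        v[i] = static_cast<unsigned char>(base_bits(s[i]));
    return v;
}

struct AlnResult {
    double identity;   // per requested mode
    int matches;       // matching columns on the optimal path
    int columns;       // total alignment columns incl. terminal gaps
    long score;
};

static const long NEG = -1000000000L;

// Overlap (end-gap-free) global alignment with affine gaps, optionally
// banded.  gap_open is the cost of the first gap position, gap_ext of each
// extension.  Identity mode 0: matches / all alignment columns (terminal
// gap overhangs included); mode 1: matches / length of the shorter sequence.
static AlnResult align_identity(const std::vector<unsigned char> &x,
                                const std::vector<unsigned char> &y,
                                int match, int mismatch,
                                int gap_open, int gap_ext,
                                int band, int mode) {
    const int n = static_cast<int>(x.size());
    const int m = static_cast<int>(y.size());
    AlnResult res{0.0, 0, n + m, NEG};
    if (n == 0 || m == 0) return res;

    // asymmetric band accommodating the length difference
    long full = std::max(n, m);
    long bl = band < 0 ? full : band + std::max(0, n - m);
    long br = band < 0 ? full : band + std::max(0, m - n);

    const int W = m + 1;
    std::vector<long> M0(W), X0(W), Y0(W), M1(W), X1(W), Y1(W);
    std::vector<int> Mm0(W), Xm0(W), Ym0(W), Mm1(W), Xm1(W), Ym1(W);
    std::vector<int> Mc0(W), Xc0(W), Yc0(W), Mc1(W), Xc1(W), Yc1(W);

    for (int j = 0; j <= m; ++j) {
        M0[j] = 0; Mm0[j] = 0; Mc0[j] = j;   // start at (0,j): j overhang cols
        X0[j] = NEG; Y0[j] = NEG; Xm0[j] = Ym0[j] = 0; Xc0[j] = Yc0[j] = 0;
    }

    long best = NEG; int best_m = 0, best_c = n + m;
    // candidates ending at column m (right edge), trailing x overhang
    for (int i = 1; i <= n; ++i) {
        M1[0] = 0; Mm1[0] = 0; Mc1[0] = i;   // start at (i,0)
        X1[0] = NEG; Y1[0] = NEG; Xm1[0] = Ym1[0] = 0; Xc1[0] = Yc1[0] = 0;
        int jlo = (int)std::min((long)m + 1, std::max(1L, (long)i - bl));
        int jhi = (int)std::min((long)m, (long)i + br);
        for (int j = 1; j < jlo; ++j) { M1[j] = X1[j] = Y1[j] = NEG; }
        for (int j = jhi + 1; j <= m; ++j) { M1[j] = X1[j] = Y1[j] = NEG; }
        for (int j = jlo; j <= jhi; ++j) {
            bool is_match = (x[i - 1] & y[j - 1]) != 0;
            long sub = is_match ? match : mismatch;
            // M: consume one of each
            long a = M0[j - 1], b = X0[j - 1], c = Y0[j - 1];
            long mx = std::max(a, std::max(b, c));
            if (mx <= NEG / 2) { M1[j] = NEG; Mm1[j] = 0; Mc1[j] = 0; }
            else {
                M1[j] = mx + sub;
                if (mx == a)      { Mm1[j] = Mm0[j - 1]; Mc1[j] = Mc0[j - 1]; }
                else if (mx == b) { Mm1[j] = Xm0[j - 1]; Mc1[j] = Xc0[j - 1]; }
                else              { Mm1[j] = Ym0[j - 1]; Mc1[j] = Yc0[j - 1]; }
                Mm1[j] += is_match ? 1 : 0; Mc1[j] += 1;
            }
            // X: gap in y (consume x), vertical move
            long xo = (M0[j] <= NEG / 2) ? NEG : M0[j] - gap_open;
            long xe = (X0[j] <= NEG / 2) ? NEG : X0[j] - gap_ext;
            if (xo >= xe) { X1[j] = xo; Xm1[j] = Mm0[j]; Xc1[j] = Mc0[j] + 1; }
            else          { X1[j] = xe; Xm1[j] = Xm0[j]; Xc1[j] = Xc0[j] + 1; }
            if (xo <= NEG / 2 && xe <= NEG / 2) { X1[j] = NEG; Xm1[j] = 0; Xc1[j] = 0; }
            // Y: gap in x (consume y), horizontal move
            long yo = (M1[j - 1] <= NEG / 2) ? NEG : M1[j - 1] - gap_open;
            long ye = (Y1[j - 1] <= NEG / 2) ? NEG : Y1[j - 1] - gap_ext;
            if (yo >= ye) { Y1[j] = yo; Ym1[j] = Mm1[j - 1]; Yc1[j] = Mc1[j - 1] + 1; }
            else          { Y1[j] = ye; Ym1[j] = Ym1[j - 1]; Yc1[j] = Yc1[j - 1] + 1; }
            if (yo <= NEG / 2 && ye <= NEG / 2) { Y1[j] = NEG; Ym1[j] = 0; Yc1[j] = 0; }
        }
        // right-edge end (j = m): free trailing gap in y, overhang n - i cols
        if (jhi == m) {
            long cand[3] = {M1[m], X1[m], Y1[m]};
            int cm[3] = {Mm1[m], Xm1[m], Ym1[m]};
            int cc[3] = {Mc1[m], Xc1[m], Yc1[m]};
            for (int s = 0; s < 3; ++s) {
                if (cand[s] <= NEG / 2) continue;
                int cols = cc[s] + (n - i);
                if (cand[s] > best || (cand[s] == best && cm[s] > best_m)) {
                    best = cand[s]; best_m = cm[s]; best_c = cols;
                }
            }
        }
        std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
        std::swap(Mm0, Mm1); std::swap(Xm0, Xm1); std::swap(Ym0, Ym1);
        std::swap(Mc0, Mc1); std::swap(Xc0, Xc1); std::swap(Yc0, Yc1);
    }
    // bottom-edge end (i = n): free trailing gap in x, overhang m - j cols
    for (int j = 0; j <= m; ++j) {
        long cand[3] = {M0[j], X0[j], Y0[j]};
        int cm[3] = {Mm0[j], Xm0[j], Ym0[j]};
        int cc[3] = {Mc0[j], Xc0[j], Yc0[j]};
        for (int s = 0; s < 3; ++s) {
            if (cand[s] <= NEG / 2) continue;
            int cols = cc[s] + (m - j);
            if (cand[s] > best || (cand[s] == best && cm[s] > best_m)) {
                best = cand[s]; best_m = cm[s]; best_c = cols;
            }
        }
    }
    res.score = best;
    res.matches = best_m;
    res.columns = best_c;
    if (mode == 1) {
        res.identity = best_m / (double)std::min(n, m);
    } else {
        res.identity = best_c > 0 ? best_m / (double)best_c : 0.0;
    }
    return res;
}

// [[Rcpp::export]]
List pair_identity_cpp(std::string a, std::string b,
                       int match = 1, int mismatch = -1,
                       int gap_open = 5, int gap_ext = 1,
                       int band = -1, int mode = 0) {
    AlnResult r = align_identity(encode(a), encode(b), match, mismatch,
                                 gap_open, gap_ext, band, mode);
    return List::create(_["identity"] = r.identity,
                        _["matches"] = r.matches,
                        _["columns"] = r.columns,
                        _["score"] = (double)r.score);
}

static const int KMER_K = 5;
static const int KMER_SPACE = 1024;  // 4^5

static inline int bits_to_2bit(unsigned char b) {
    switch (b) { case 1: return 0; case 2: return 1; case 4: return 2; case 8: return 3; }
    return -1;  // ambiguous
}

static std::vector<unsigned short> kmer_profile(const std::vector<unsigned char> &s) {
    std::vector<unsigned short> prof(KMER_SPACE, 0);
    int code = 0, run = 0;
    for (size_t i = 0; i < s.size(); ++i) {
        int b = bits_to_2bit(s[i]);
        if (b < 0) { run = 0; code = 0; continue; }
        code = ((code << 2) | b) & (KMER_SPACE - 1);
        if (++run >= KMER_K) prof[code]++;
    }
    return prof;
}

// sparse (kmer, count) list of the query, for fast profile intersection
static std::vector<std::pair<int, unsigned short> >
sparse_kmers(const std::vector<unsigned short> &prof) {
    std::vector<std::pair<int, unsigned short> > out;
    for (int i = 0; i < KMER_SPACE; ++i)
        if (prof[i]) out.push_back(std::make_pair(i, prof[i]));
    return out;
}

static long shared_kmers(const std::vector<std::pair<int, unsigned short> > &q,
                         const std::vector<unsigned short> &b) {
    long s = 0;
    for (size_t i = 0; i < q.size(); ++i)
        s += std::min(q[i].second, b[q[i].first]);
    return s;
}

// Greedy centroid clustering over sequences in the given order: each
// sequence joins the first centroid (candidates visited in order of shared
// 5-mer count, ties by centroid creation order) whose alignment identity is
// >= cutoff, else founds a new centroid.  With prefilter = true, centroids
// sharing no 5-mer with the query are not aligned (queries shorter than 5 nt
// are always aligned).
// [[Rcpp::export]]
List greedy_cluster_cpp(CharacterVector seqs, double cutoff,
                        int match = 1, int mismatch = -1,
                        int gap_open = 5, int gap_ext = 1,
                        int band_extra = 4, int mode = 0,
                        bool prefilter = true, bool banded = true) {
    const int n = seqs.size();
    IntegerVector assign(n);
    std::vector<int> cents;                        // centroid seq indices
    std::vector<std::vector<unsigned char> > cseq; // encoded centroids
    std::vector<std::vector<unsigned short> > cprof;
    std::map<std::string, int> cmap;               // exact-duplicate lookup

    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        // identical sequence: identity 1 with its centroid, no alignment
        std::map<std::string, int>::iterator dup = cmap.find(s);
        if (dup != cmap.end()) {
            assign[i] = dup->second + 1;
            continue;
        }
        std::vector<unsigned char> enc = encode(s);
        std::vector<unsigned short> prof = kmer_profile(enc);
        std::vector<std::pair<int, unsigned short> > sq = sparse_kmers(prof);
        long nkmer = 0;
        for (size_t t = 0; t < sq.size(); ++t) nkmer += sq[t].second;

        const int nc = static_cast<int>(cents.size());
        std::vector<std::pair<long, int> > order(nc);
        for (int c = 0; c < nc; ++c)
            order[c] = std::make_pair(-shared_kmers(sq, cprof[c]), c);
        std::stable_sort(order.begin(), order.end());

        int hit = -1;
        for (int c = 0; c < nc; ++c) {
            long shared = -order[c].first;
            int ci = order[c].second;
            if (prefilter && nkmer > 0 && shared == 0) continue;
            int len_a = static_cast<int>(enc.size());
            int len_b = static_cast<int>(cseq[ci].size());
            int band = banded
                ? (int)std::ceil((1.0 - cutoff) * std::max(len_a, len_b)) + band_extra
                : -1;
            AlnResult r = align_identity(enc, cseq[ci], match, mismatch,
                                         gap_open, gap_ext, band, mode);
            if (r.identity >= cutoff) { hit = ci; break; }
        }
        if (hit < 0) {
            cents.push_back(i);
            cseq.push_back(enc);
            cprof.push_back(prof);
            hit = static_cast<int>(cents.size()) - 1;
        }
        assign[i] = hit + 1;  // 1-based cluster id in creation order
        cmap[s] = hit;
        if (i % 256 == 0) Rcpp::checkUserInterrupt();
    }
    IntegerVector centrv(cents.size());
    for (size_t c = 0; c < cents.size(); ++c) centrv[c] = cents[c] + 1;
    return List::create(_["assignment"] = assign, _["centroids"] = centrv);
}
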