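#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
#include <limits>
using namespace Rcpp;

// Banded global affine-gap alignment (Needleman-Wunsch, Gotoh three-state).
// Gap of length k costs open + k * ext (both passed as positive penalties).
// Band: |i - j| <= band + |m - n|, so the corner (m, n) is always reachable.
// Tie-break on equal score: diagonal > gap-in-read (ref base unmatched) >
// gap-in-reference, applied both in the recursion and in the traceback, so
// the alignment is deterministic.
//
// Storage is band-indexed: cell (i, j) lives at slot j - i + w of row i, so
// the diagonal predecessor (i-1, j-1) is the same slot of the previous row,
// the gap-in-ref predecessor (i-1, j) is slot + 1 of the previous row, and
// the gap-in-read predecessor (i, j-1) is slot - 1 of the same row.

static const double NEG = -std::numeric_limits<double>::infinity();

struct AlnResult {
    double score;
    double identity;       // matches / reference length
    std::string ref_row;   // per reference position: aligned read base or '-'
};

static AlnResult band_align_one(const char* read, int m, const char* ref, int n,
                                double match, double mismatch,
                                double gap_open, double gap_ext, int band) {
    const int w = band + std::abs(m - n);
    const int W = 2 * w + 1;
    const double go = gap_open + gap_ext, ge = gap_ext;

    static thread_local std::vector<double> Mp, Xp, Yp, Mc, Xc, Yc;
    static thread_local std::vector<unsigned char> tM, tX, tY;
    if ((int)Mp.size() < W + 2) {
        Mp.resize(W + 2); Xp.resize(W + 2); Yp.resize(W + 2);
        Mc.resize(W + 2); Xc.resize(W + 2); Yc.resize(W + 2);
    }
    const size_t tsz = (size_t)(m + 1) * W;
    if (tM.size() < tsz) { tM.resize(tsz); tX.resize(tsz); tY.resize(tsz); }

    // rows are offset by one slot so that slot-1 / slot+1 reads stay in range
    double *mp = Mp.data() + 1, *xp = Xp.data() + 1, *yp = Yp.data() + 1;
    double *mc = Mc.data() + 1, *xc = Xc.data() + 1, *yc = Yc.data() + 1;
    for (int k = -1; k <= W; ++k) { mp[k] = xp[k] = yp[k] = NEG;
                                    mc[k] = xc[k] = yc[k] = NEG; }

    // row 0: j = 0..min(n, w), slot j + w ... slot = j - 0 + w
    for (int j = 0; j <= std::min(n, w); ++j) {
        int k = j + w;
        if (j == 0) { mp[k] = 0.0; xp[k] = NEG; yp[k] = NEG; }
        else {
            mp[k] = NEG; yp[k] = NEG;
            double a = mp[k - 1] - go, b = xp[k - 1] - ge;
            if (a >= b) { xp[k] = a; tX[k] = 0; } else { xp[k] = b; tX[k] = 1; }
        }
    }

    for (int i = 1; i <= m; ++i) {
        const int jlo = std::max(0, i - w), jhi = std::min(n, i + w);
        const char ri = read[i - 1];
        unsigned char *tMr = tM.data() + (size_t)i * W - i + w;  // index by j
        unsigned char *tXr = tX.data() + (size_t)i * W - i + w;
        unsigned char *tYr = tY.data() + (size_t)i * W - i + w;
        // clear slots just outside the row's valid range
        {
            int klo = jlo - i + w, khi = jhi - i + w;
            mc[klo - 1] = xc[klo - 1] = yc[klo - 1] = NEG;
            if (khi + 1 <= W) mc[khi + 1] = xc[khi + 1] = yc[khi + 1] = NEG;
        }
        for (int j = jlo; j <= jhi; ++j) {
            const int k = j - i + w;
            // diagonal
            if (j > 0) {
                double s = (ri == ref[j - 1]) ? match : -mismatch;
                double best = mp[k]; unsigned char tb = 0;
                if (xp[k] > best) { best = xp[k]; tb = 1; }
                if (yp[k] > best) { best = yp[k]; tb = 2; }
                mc[k] = best + s; tMr[j] = tb;
            } else mc[k] = NEG;
            // gap in read (consume ref)
            if (j > jlo) {
                double a = mc[k - 1] - go, b = xc[k - 1] - ge;
                if (a >= b) { xc[k] = a; tXr[j] = 0; } else { xc[k] = b; tXr[j] = 1; }
            } else xc[k] = NEG;
            // gap in reference (consume read)
            {
                double a = mp[k + 1] - go, b = yp[k + 1] - ge;
                if (a >= b) { yc[k] = a; tYr[j] = 0; } else { yc[k] = b; tYr[j] = 1; }
            }
        }
        std::swap(mp, mc); std::swap(xp, xc); std::swap(yp, yc);
    }

    AlnResult res;
    res.ref_row.assign(n, '-');
    const int kend = n - m + w;
    double sM = mp[kend], sX = xp[kend], sY = yp[kend];
    int state = 0; double best = sM;
    if (sX > best) { best = sX; state = 1; }
    if (sY > best) { best = sY; state = 2; }
    res.score = best;
    int i = m, j = n, matches = 0;
    while (i > 0 || j > 0) {
        size_t off = (size_t)i * W - i + w;
        if (state == 0) {
            res.ref_row[j - 1] = read[i - 1];
            if (read[i - 1] == ref[j - 1]) ++matches;
            state = tM[off + j]; --i; --j;
        } else if (state == 1) {
            state = (tX[off + j] == 0) ? 0 : 1; --j;
        } else {
            state = (tY[off + j] == 0) ? 0 : 2; --i;
        }
    }
    res.identity = n > 0 ? (double)matches / n : 0.0;
    return res;
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, std::string ref,
                     double match, double mismatch,
                     double gap_open, double gap_ext, int band) {
    const int n = reads.size();
    NumericVector score(n), identity(n);
    CharacterVector ref_row(n);
    for (int r = 0; r < n; ++r) {
        SEXP s = STRING_ELT(reads, r);
        AlnResult a = band_align_one(CHAR(s), (int)LENGTH(s),
                                     ref.c_str(), (int)ref.size(),
                                     match, mismatch, gap_open, gap_ext, band);
        score[r] = a.score; identity[r] = a.identity; ref_row[r] = a.ref_row;
    }
    return List::create(_["score"] = score, _["identity"] = identity,
                        _["ref_row"] = ref_row);
}

// Best Hamming prefix match of each read against a set of keys, each key
// compared over its own length. Returns a 2-column matrix: 1-based index of
// the best key (0 = none within max_mm, -1 = ambiguous tie) and the mismatch
// count of the best match. Ties at equal mismatch count: a longer key wins;
// equal length too -> ambiguous.
// [[Rcpp::export]]
IntegerMatrix cpp_best_prefix_match(CharacterVector reads, CharacterVector keys,
                                    int max_mm) {
    const int n = reads.size(), K = keys.size();
    std::vector<std::string> ks(K);
    for (int k = 0; k < K; ++k) ks[k] = as<std::string>(keys[k]);
    IntegerMatrix out(n, 2);
    for (int r = 0; r < n; ++r) {
        const char* rd = CHAR(STRING_ELT(reads, r));
        int rlen = (int)LENGTH(STRING_ELT(reads, r));
        int best = -1, best_mm = max_mm + 1, best_len = -1; bool tie = false;
        for (int k = 0; k < K; ++k) {
            int L = (int)ks[k].size();
            if (L > rlen) continue;
            int mm = 0;
            for (int p = 0; p < L && mm <= max_mm; ++p)
                if (rd[p] != ks[k][p]) ++mm;
            if (mm > max_mm) continue;
            if (mm < best_mm || (mm == best_mm && L > best_len)) {
                best = k; best_mm = mm; best_len = L; tie = false;
            } else if (mm == best_mm && L == best_len) {
                tie = true;
            }
        }
        out(r, 0) = (best < 0) ? 0 : (tie ? -1 : best + 1);
        out(r, 1) = (best < 0) ? NA_INTEGER : best_mm;
    }
    return out;
}

// Apply pre-drawn substitution errors: at each (read_idx, pos) replace the
// base by the one `offset` (1-3) steps away in A,C,G,T order, so the
// replacement always differs from the original. Positions are 1-based.
// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector read_idx,
                               IntegerVector pos, IntegerVector offset) {
    static const char* bases = "ACGT";
    CharacterVector out(clone(seqs));
    int n = read_idx.size();
    std::string buf;
    int last = -1;
    for (int e = 0; e < n; ++e) {
        int r = read_idx[e] - 1;
        if (r != last) {
            if (last >= 0) out[last] = buf;
            buf = as<std::string>(out[r]);
            last = r;
        }
        int p = pos[e] - 1;
        const char* hit = std::strchr(bases, buf[p]);
        if (hit) buf[p] = bases[(int)(hit - bases) + offset[e] & 3];
    }
    if (last >= 0) out[last] = buf;
    return out;
}
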