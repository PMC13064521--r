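// Glocal (read-global, target-local) affine-gap alignment of reads against a
// window target. The read is fully aligned; target end gaps are free. A gap
// of length L costs open + ext * L. Traceback tie preference is
// diagonal (match/mismatch) > up (read-consuming gap) > left
// (target-consuming gap), making the alignment fully deterministic.
//
// Reads that are exact substrings of the target take a fast path (first
// occurrence); in low-error short-read data that is the overwhelming
// majority, which keeps per-window realignment cheap.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <limits>

using namespace Rcpp;

namespace {
const double NEG_INF = -std::numeric_limits<double>::infinity();
enum St { M = 0, X = 1, Y = 2 };  // X: gap in target; Y: gap in read
}

// [[Rcpp::export(name = ".glocal_align_cpp")]]
List glocal_align_cpp(CharacterVector reads, std::string target, double match,
                      double mismatch, double open, double ext,
                      bool want_maps = true) {
  int nr = reads.size();
  int n = (int)target.size();
  NumericVector score(nr);
  IntegerVector tstart(nr), nmatch(nr), nmismatch(nr), gap_opens(nr),
      gap_bases(nr);
  CharacterVector cigar(nr);
  List maps(want_maps ? nr : 0);

  // reusable DP storage sized for the largest read
  int maxm = 0;
  std::vector<std::string> rs(nr);
  for (int r = 0; r < nr; ++r) {
    rs[r] = as<std::string>(reads[r]);
    maxm = std::max(maxm, (int)rs[r].size());
  }
  size_t cells = (size_t)(maxm + 1) * (size_t)(n + 1);
  std::vector<double> Mm(cells), Xm(cells), Ym(cells);
  std::vector<signed char> bM(cells), bX(cells), bY(cells);

  for (int r = 0; r < nr; ++r) {
    const std::string &q = rs[r];
    int m = (int)q.size();
    if (m == 0) stop("empty read sequence");

    // fast path 1: exact substring
    size_t hit = target.find(q);
    bool done = false;
    if (hit != std::string::npos) {
      score[r] = match * m;
      tstart[r] = (int)hit;
      nmatch[r] = m;
      nmismatch[r] = 0;
      gap_opens[r] = 0;
      gap_bases[r] = 0;
      cigar[r] = std::to_string(m) + "M";
      if (want_maps) {
        IntegerVector mp(m);
        for (int i = 0; i < m; ++i) mp[i] = i + 1;
        maps[r] = mp;
      }
      continue;
    }
    // fast path 2: seed-and-extend ungapped placement. With this scoring a
    // mismatch costs 6 and any gap at least 6 while losing a match, so an
    // ungapped alignment with <= 1 mismatch cannot be beaten by a gapped
    // one (best conceivable gapped score is 2m-8 < 2m-6).
    if (m >= 20 && n >= m) {
      const int k0 = 16;
      std::vector<int> cand;
      std::string pre = q.substr(0, k0), suf = q.substr(m - k0);
      size_t p = target.find(pre);
      int found = 0;
      while (p != std::string::npos && found < 8) {
        if ((int)p + m <= n) cand.push_back((int)p);
        ++found;
        p = target.find(pre, p + 1);
      }
      p = target.find(suf);
      found = 0;
      while (p != std::string::npos && found < 8) {
        int off = (int)p - (m - k0);
        if (off >= 0 && off + m <= n) cand.push_back(off);
        ++found;
        p = target.find(suf, p + 1);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      int best_mm = 2, best_off = -1;
      for (size_t c = 0; c < cand.size(); ++c) {
        int off = cand[c], mm = 0;
        for (int i = 0; i < m && mm < best_mm; ++i) {
          if (q[(size_t)i] != target[(size_t)(off + i)]) ++mm;
        }
        if (mm < best_mm) { best_mm = mm; best_off = off; }
      }
      if (best_off >= 0 && best_mm <= 1) {
        score[r] = match * (m - best_mm) + mismatch * best_mm;
        tstart[r] = best_off;
        nmatch[r] = m - best_mm;
        nmismatch[r] = best_mm;
        gap_opens[r] = 0;
        gap_bases[r] = 0;
        cigar[r] = std::to_string(m) + "M";
        if (want_maps) {
          IntegerVector mp(m);
          for (int i = 0; i < m; ++i) mp[i] = i + 1;
          maps[r] = mp;
        }
        done = true;
      }
    }
    // fast path 3: reads overhanging a target end with an exactly matching
    // overlap; the overhang is consumed as one end gap in the read (the DP
    // would produce the same alignment).
    if (!done && m >= 20) {
      const int k0 = 16;
      std::vector<int> cand;
      std::string pre = q.substr(0, k0), suf = q.substr(m - k0);
      size_t p = target.find(pre);
      int found = 0;
      while (p != std::string::npos && found < 8) {
        cand.push_back((int)p);
        ++found;
        p = target.find(pre, p + 1);
      }
      p = target.find(suf);
      found = 0;
      while (p != std::string::npos && found < 8) {
        cand.push_back((int)p - (m - k0));
        ++found;
        p = target.find(suf, p + 1);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      double best_sc = NEG_INF;
      int best_off = 0, best_lo = 0, best_hi = 0;
      for (size_t c = 0; c < cand.size(); ++c) {
        int off = cand[c];
        int lo = std::max(0, off), hi = std::min(n, off + m);
        int ov = hi - lo;
        if (ov < 20 || ov == m) continue;   // full overlap handled above
        bool exact = true;
        for (int i = lo; i < hi; ++i) {
          if (q[(size_t)(i - off)] != target[(size_t)i]) { exact = false; break; }
        }
        if (!exact) continue;
        int ll = lo - off, rr = (off + m) - hi;
        double sc = match * ov - (ll > 0 ? open + ext * ll : 0.0) -
            (rr > 0 ? open + ext * rr : 0.0);
        if (sc > best_sc) {
          best_sc = sc; best_off = off; best_lo = lo; best_hi = hi;
        }
      }
      if (best_sc > NEG_INF) {
        int ll = best_lo - best_off, rr = (best_off + m) - best_hi;
        int ov = best_hi - best_lo;
        score[r] = best_sc;
        tstart[r] = best_lo;
        nmatch[r] = ov;
        nmismatch[r] = 0;
        gap_opens[r] = (ll > 0 ? 1 : 0) + (rr > 0 ? 1 : 0);
        gap_bases[r] = ll + rr;
        std::string cg;
        if (ll > 0) cg += std::to_string(ll) + "I";
        cg += std::to_string(ov) + "M";
        if (rr > 0) cg += std::to_string(rr) + "I";
        cigar[r] = cg;
        if (want_maps) {
          IntegerVector mp(ov);
          for (int i = 0; i < ov; ++i) mp[i] = ll + i + 1;
          maps[r] = mp;
        }
        done = true;
      }
    }
    if (done) continue;

    const size_t C = (size_t)n + 1;
    auto at = [C](int i, int j) { return (size_t)i * C + (size_t)j; };
    for (int j = 0; j <= n; ++j) {   // free leading target
      Mm[at(0, j)] = 0.0; Xm[at(0, j)] = NEG_INF; Ym[at(0, j)] = NEG_INF;
    }
    for (int i = 1; i <= m; ++i) {
      Mm[at(i, 0)] = NEG_INF;
      Ym[at(i, 0)] = NEG_INF;
      Xm[at(i, 0)] = -open - ext * i;  // leading read insertion
      bX[at(i, 0)] = (signed char)(i == 1 ? M : X);
      for (int j = 1; j <= n; ++j) {
        size_t h = at(i, j);
        double sub = (q[(size_t)i - 1] == target[(size_t)j - 1]) ? match
                                                                 : mismatch;
        // diagonal
        {
          size_t d = at(i - 1, j - 1);
          double best = Mm[d]; signed char bs = M;
          if (Xm[d] > best) { best = Xm[d]; bs = X; }
          if (Ym[d] > best) { best = Ym[d]; bs = Y; }
          Mm[h] = best + sub; bM[h] = bs;
        }
        // up: consume read char, gap in target
        {
          size_t u = at(i - 1, j);
          double best = Mm[u] - open - ext; signed char bs = M;
          if (Xm[u] - ext > best) { best = Xm[u] - ext; bs = X; }
          if (Ym[u] - open - ext > best) { best = Ym[u] - open - ext; bs = Y; }
          Xm[h] = best; bX[h] = bs;
        }
        // left: consume target char, gap in read
        {
          size_t l = at(i, j - 1);
          double best = Mm[l] - open - ext; signed char bs = M;
          if (Xm[l] - open - ext > best) { best = Xm[l] - open - ext; bs = X; }
          if (Ym[l] - ext > best) { best = Ym[l] - ext; bs = Y; }
          Ym[h] = best; bY[h] = bs;
        }
      }
    }
    // end: free trailing target; smallest end column wins ties
    double best = NEG_INF; int bj = -1; signed char bstate = M;
    for (int j = 0; j <= n; ++j) {
      size_t h = at(m, j);
      if (Mm[h] > best) { best = Mm[h]; bj = j; bstate = M; }
      if (Xm[h] > best) { best = Xm[h]; bj = j; bstate = X; }
    }
    score[r] = best;

    // traceback
    std::vector<signed char> ops;  // 0 = M, 1 = X (ins in read), 2 = Y (del)
    int i = m, j = bj;
    signed char st = bstate;
    int nma = 0, nmi = 0;
    while (i > 0) {
      size_t h = at(i, j);
      if (st == M) {
        ops.push_back(0);
        if (q[(size_t)i - 1] == target[(size_t)j - 1]) ++nma; else ++nmi;
        st = bM[h]; --i; --j;
      } else if (st == X) {
        ops.push_back(1);
        st = bX[h]; --i;
      } else {
        ops.push_back(2);
        st = bY[h]; --j;
      }
    }
    std::reverse(ops.begin(), ops.end());
    tstart[r] = j;
    nmatch[r] = nma;
    nmismatch[r] = nmi;
    // cigar + gap stats + target->read map
    std::string cg;
    int go = 0, gb = 0;
    {
      size_t p = 0;
      while (p < ops.size()) {
        size_t e = p;
        while (e < ops.size() && ops[e] == ops[p]) ++e;
        int len = (int)(e - p);
        char oc = ops[p] == 0 ? 'M' : (ops[p] == 1 ? 'I' : 'D');
        cg += std::to_string(len);
        cg += oc;
        if (ops[p] != 0) { ++go; gb += len; }
        p = e;
      }
    }
    cigar[r] = cg;
    if (want_maps) {
      std::vector<int> mp;
      int ri = 0;
      for (size_t p = 0; p < ops.size(); ++p) {
        if (ops[p] == 0) { ++ri; mp.push_back(ri); }
        else if (ops[p] == 1) { ++ri; }
        else { mp.push_back(NA_INTEGER); }
      }
      maps[r] = IntegerVector(mp.begin(), mp.end());
    }
    gap_opens[r] = go;
    gap_bases[r] = gb;
  }
  return List::create(_["score"] = score, _["target_start"] = tstart,
                      _["matches"] = nmatch, _["mismatches"] = nmismatch,
                      _["gap_opens"] = gap_opens, _["gap_bases"] = gap_bases,
                      _["cigar"] = cigar, _["maps"] = maps);
}
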