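#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// ---- built-in secondary-structure engine -----------------------------------
//
// Nested (pseudoknot-free) minimum-energy folding under a simple
// stacking-weighted model: a base pair contributes its energy only when the
// pair immediately inside it is also formed (GC -3, AU -2, GU -1 kcal/mol),
// each hairpin loop costs +4, minimum hairpin loop is 3 nt. The empty
// structure has energy 0, so the reported minimum is always <= 0 and is 0
// exactly when pairing is not worthwhile.

static const int INF = 1000000000;

static inline int pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return -2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return -1;
  return INF;
}

struct FoldDP {
  int n;
  const std::string &s;
  std::vector<int> V, Wp; // (n+2)x(n+2), 1-based
  FoldDP(const std::string &seq) : n((int)seq.size()), s(seq),
    V((size_t)(n + 2) * (n + 2), INF), Wp((size_t)(n + 2) * (n + 2), INF) {}
  int &v(int i, int j) { return V[(size_t)i * (n + 2) + j]; }
  int &wp(int i, int j) { return Wp[(size_t)i * (n + 2) + j]; }
  int w(int i, int j) { // best energy of segment, empty allowed
    if (i > j) return 0;
    int x = wp(i, j);
    return x < 0 ? x : 0;
  }
  void run() {
    for (int len = 2; len <= n; ++len) {
      for (int i = 1; i + len - 1 <= n; ++i) {
        int j = i + len - 1;
        // V(i,j): energy given (i,j) paired
        if (j - i >= 4) {
          int e = pair_energy(s[i - 1], s[j - 1]);
          if (e != INF) {
            int best = 4; // hairpin loop closed by (i,j)
            if (j - i - 2 >= 4) {
              int es = pair_energy(s[i], s[j - 2]);
              if (es != INF && v(i + 1, j - 1) < INF)
                best = std::min(best, v(i + 1, j - 1) + e);
            }
            if (i + 1 <= j - 1 && wp(i + 1, j - 1) < INF)
              best = std::min(best, wp(i + 1, j - 1));
            v(i, j) = best;
          }
        }
        // Wp(i,j): best energy with >= 1 pair in segment
        int wbest = (j - 1 >= i) ? wp(i, j - 1) : INF;
        for (int k = i; k <= j - 4; ++k) {
          if (v(k, j) < INF) {
            int left = (k - 1 >= i) ? w(i, k - 1) : 0;
            if (wbest == INF || left + v(k, j) < wbest)
              wbest = left + v(k, j);
          }
        }
        wp(i, j) = wbest;
      }
    }
  }
  void traceV(int i, int j, std::string &db);
  void traceWp(int i, int j, std::string &db);
  void traceW(int i, int j, std::string &db) {
    if (i > j) return;
    if (wp(i, j) < 0) traceWp(i, j, db);
  }
};

void FoldDP::traceV(int i, int j, std::string &db) {
  db[i - 1] = '(';
  db[j - 1] = ')';
  int e = pair_energy(s[i - 1], s[j - 1]);
  if (v(i, j) == 4) return; // hairpin: interior unpaired
  if (j - i - 2 >= 4) {
    int es = pair_energy(s[i], s[j - 2]);
    if (es != INF && v(i + 1, j - 1) < INF && v(i, j) == v(i + 1, j - 1) + e) {
      traceV(i + 1, j - 1, db);
      return;
    }
  }
  traceWp(i + 1, j - 1, db);
}

void FoldDP::traceWp(int i, int j, std::string &db) {
  if (j - 1 >= i && wp(i, j) == wp(i, j - 1)) {
    traceWp(i, j - 1, db);
    return;
  }
  for (int k = i; k <= j - 4; ++k) {
    if (v(k, j) < INF) {
      int left = (k - 1 >= i) ? w(i, k - 1) : 0;
      if (left + v(k, j) == wp(i, j)) {
        traceW(i, k - 1, db);
        traceV(k, j, db);
        return;
      }
    }
  }
  stop("fold traceback failed"); // should be unreachable
}

// [[Rcpp::export(name = ".fold_engine_cpp")]]
List fold_engine_cpp(std::string seq) {
  int n = (int)seq.size();
  std::string db(n, '.');
  if (n < 2) return List::create(_["structure"] = db, _["mfe"] = 0.0);
  FoldDP dp(seq);
  dp.run();
  int mfe = dp.w(1, n);
  if (mfe < 0) dp.traceW(1, n, db);
  return List::create(_["structure"] = db, _["mfe"] = (double)mfe);
}

// ---- adapter trimming -------------------------------------------------------
//
// Best-overlap semi-global search: the 3' adapter is sought as a prefix
// occurrence starting at some read position and running to the read end (or
// the full adapter, with trailing read bases discarded). Score is
// matches - mismatches over the compared region.

// [[Rcpp::export(name = ".trim3_pos_cpp")]]
IntegerVector trim3_pos_cpp(CharacterVector seqs, std::string adapter,
                            int min_overlap, double max_mismatch_rate) {
  int n = seqs.size(), alen = (int)adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int L = (int)s.size();
    int best_score = -1, best_p = -1;
    for (int p = 1; p <= L; ++p) { // adapter starts at read position p (1-based)
      int ov = std::min(L - p + 1, alen);
      if (ov < min_overlap) continue;
      int mism = 0;
      for (int t = 0; t < ov; ++t)
        if (s[p - 1 + t] != adapter[t]) ++mism;
      if ((double)mism > max_mismatch_rate * ov) continue;
      int score = ov - 2 * mism;
      if (score > best_score) { best_score = score; best_p = p; }
    }
    out[r] = (best_p < 0) ? -1 : best_p - 1; // insert length
  }
  return out;
}

// [[Rcpp::export(name = ".trim5_len_cpp")]]
IntegerVector trim5_len_cpp(CharacterVector seqs, std::string adapter,
                            int min_overlap, double max_mismatch_rate) {
  int n = seqs.size(), alen = (int)adapter.size();
  IntegerVector out(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int L = (int)s.size();
    int best_score = -1, best_o = 0;
    for (int o = std::min(alen, L); o >= min_overlap; --o) {
      // adapter suffix of length o vs read prefix of length o
      int mism = 0;
      for (int t = 0; t < o; ++t)
        if (s[t] != adapter[alen - o + t]) ++mism;
      if ((double)mism > max_mismatch_rate * o) continue;
      int score = o - 2 * mism;
      if (score > best_score) { best_score = score; best_o = o; }
    }
    out[r] = best_o;
  }
  return out;
}

// ---- mismatch-tolerant matching against a known mature set ------------------
//
// Ungapped containment: the shorter sequence must lie entirely within the
// longer; substitutions are counted over the overlap, total terminal overhang
// equals the length difference. Knowns must be supplied sorted by id so the
// first index wins lexicographic ties.

// [[Rcpp::export(name = ".match_known_cpp")]]
IntegerMatrix match_known_cpp(CharacterVector tags, CharacterVector knowns,
                              int max_sub, int slack) {
  int nt = tags.size(), nk = knowns.size();
  std::vector<std::string> ks(nk);
  for (int k = 0; k < nk; ++k) ks[k] = as<std::string>(knowns[k]);
  IntegerMatrix out(nt, 4); // idx (1-based, 0 = none), subs, off5, off3
  for (int t = 0; t < nt; ++t) {
    std::string ts = as<std::string>(tags[t]);
    int lt = (int)ts.size();
    int best_sub = max_sub + 1, best_ovh = slack + 1;
    int best_k = -1, best_o5 = 0, best_o3 = 0;
    for (int k = 0; k < nk; ++k) {
      int lk = (int)ks[k].size();
      int diff = lk - lt;
      int ovh = diff >= 0 ? diff : -diff;
      if (ovh > slack) continue;
      const std::string &shorter = diff >= 0 ? ts : ks[k];
      const std::string &longer = diff >= 0 ? ks[k] : ts;
      int ls = (int)shorter.size();
      for (int s = 0; s <= ovh; ++s) {
        int mism = 0;
        for (int i = 0; i < ls && mism <= max_sub; ++i)
          if (shorter[i] != longer[s + i]) ++mism;
        if (mism > max_sub) continue;
        // offsets from the tag's point of view: positive when the known
        // extends beyond the tag
        int o5 = diff >= 0 ? s : -s;
        int o3 = diff >= 0 ? (diff - s) : -(-diff - s);
        if (mism < best_sub ||
            (mism == best_sub && ovh < best_ovh)) {
          best_sub = mism; best_ovh = ovh;
          best_k = k; best_o5 = o5; best_o3 = o3;
        }
      }
    }
    if (best_k < 0) {
      out(t, 0) = 0;
    } else {
      out(t, 0) = best_k + 1;
      out(t, 1) = best_sub;
      out(t, 2) = best_o5;
      out(t, 3) = best_o3;
    }
  }
  return out;
}
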