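#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>

using namespace Rcpp;

// Key encoding: raw bytes of the int window. Only used for hashing/equality,
// never for ordering (ties are broken by comparing the int vectors directly).
static inline std::string window_key(const std::vector<int>& v, int from, int w) {
  return std::string(reinterpret_cast<const char*>(v.data() + from),
                     static_cast<size_t>(w) * sizeof(int));
}

// Greedy left-to-right non-overlapping selection from the ascending list of
// (possibly overlapping) match start positions. Equivalent to a scan that
// resumes at p + W after a match at p.
static void greedy_select(const std::vector<int>& pos, int w,
                          int& n, std::vector<int>& starts) {
  n = 0;
  starts.clear();
  int last_end = -1;  // 0-based inclusive end of last accepted match
  for (int p : pos) {
    if (p > last_end) {
      ++n;
      starts.push_back(p);
      last_end = p + w - 1;
    }
  }
}

// lexicographic comparison of int vectors (a < b)
static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  size_t m = std::min(a.size(), b.size());
  for (size_t i = 0; i < m; ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return a.size() < b.size();
}

struct Candidate {
  std::vector<int> body;
  int w = 0;
  int n = 0;
  long long savings = -1;
  std::vector<int> starts;  // 0-based
  bool found = false;
};

// Best (maximally compressive) subsequence of the current sequence.
// Savings S = W*N - (W + 1 + N) with N the greedy non-overlapping count.
// Ties: ascending length, then lexicographic by labels.
static Candidate best_candidate(const std::vector<int>& seq, int wmax) {
  Candidate best;
  int L = static_cast<int>(seq.size());
  for (int w = 2; w <= wmax; ++w) {
    if (L < 2 * w) break;  // need at least two non-overlapping copies
    std::unordered_map<std::string, std::vector<int>> occ;
    occ.reserve(static_cast<size_t>(L));
    for (int p = 0; p + w <= L; ++p) {
      occ[window_key(seq, p, w)].push_back(p);
    }
    for (auto& kv : occ) {
      if (kv.second.size() < 2) continue;
      int n;
      std::vector<int> starts;
      greedy_select(kv.second, w, n, starts);
      if (n < 2) continue;
      long long s = static_cast<long long>(w) * n - (w + 1 + n);
      if (s < 1) continue;
      if (s > best.savings) {
        best.found = true;
        best.savings = s;
        best.w = w;
        best.n = n;
        best.starts = starts;
        best.body.assign(seq.begin() + starts[0], seq.begin() + starts[0] + w);
      } else if (s == best.savings && best.found && w == best.w) {
        std::vector<int> body(seq.begin() + starts[0],
                              seq.begin() + starts[0] + w);
        if (lex_less(body, best.body)) {
          best.n = n;
          best.starts = starts;
          best.body = body;
        }
      }
      // s == best.savings with w > best.w: keep the shorter, earlier candidate
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_count_nonoverlapping")]]
List cpp_count_nonoverlapping(IntegerVector seq, IntegerVector sub) {
  int L = seq.size(), w = sub.size();
  std::vector<int> pos;
  for (int p = 0; p + w <= L; ++p) {
    bool ok = true;
    for (int i = 0; i < w; ++i) {
      if (seq[p + i] != sub[i]) { ok = false; break; }
    }
    if (ok) pos.push_back(p);
  }
  int n;
  std::vector<int> starts;
  greedy_select(pos, w, n, starts);
  IntegerVector st(starts.size());
  for (size_t i = 0; i < starts.size(); ++i) st[i] = starts[i] + 1;
  return List::create(_["n"] = n, _["starts"] = st);
}

// Greedy non-overlapping counts of several motifs in one sequence.
// [[Rcpp::export(name = ".cpp_count_many")]]
IntegerVector cpp_count_many(List motifs, IntegerVector seq) {
  int m = motifs.size();
  IntegerVector out(m);
  int L = seq.size();
  for (int k = 0; k < m; ++k) {
    IntegerVector sub = motifs[k];
    int w = sub.size();
    int n = 0, last_end = -1;
    for (int p = 0; p + w <= L; ++p) {
      if (p <= last_end) continue;
      bool ok = true;
      for (int i = 0; i < w; ++i) {
        if (seq[p + i] != sub[i]) { ok = false; break; }
      }
      if (ok) { ++n; last_end = p + w - 1; }
    }
    out[k] = n;
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_best_candidate")]]
List cpp_best_candidate(IntegerVector seq, int wmax) {
  std::vector<int> s(seq.begin(), seq.end());
  Candidate b = best_candidate(s, wmax);
  if (!b.found) return List::create();
  IntegerVector body(b.body.begin(), b.body.end());
  IntegerVector starts(b.starts.size());
  for (size_t i = 0; i < b.starts.size(); ++i) starts[i] = b.starts[i] + 1;
  return List::create(_["body"] = body, _["W"] = b.w, _["N"] = b.n,
                      _["savings"] = static_cast<double>(b.savings),
                      _["starts"] = starts);
}

// Full offline compressive-heuristic loop. Returns the compressed sequence
// and, per accepted rule: new symbol, body, W, N, savings, occurrence start
// positions in the iteration's sequence and in original coordinates.
// [[Rcpp::export(name = ".cpp_compress")]]
List cpp_compress(IntegerVector seq, int wmax, int alphabet) {
  std::vector<int> cur(seq.begin(), seq.end());
  std::vector<int> orig(cur.size());
  for (size_t i = 0; i < cur.size(); ++i) orig[i] = static_cast<int>(i);
  int next_symbol = alphabet + 1;
  List rules;
  for (;;) {
    Candidate b = best_candidate(cur, wmax);
    if (!b.found || b.savings < 1) break;
    IntegerVector body(b.body.begin(), b.body.end());
    IntegerVector starts(b.n), ostarts(b.n);
    for (int i = 0; i < b.n; ++i) {
      starts[i] = b.starts[i] + 1;
      ostarts[i] = orig[b.starts[i]] + 1;
    }
    rules.push_back(List::create(
        _["symbol"] = next_symbol, _["body"] = body, _["W"] = b.w,
        _["N"] = b.n, _["savings"] = static_cast<double>(b.savings),
        _["starts"] = starts, _["origStarts"] = ostarts));
    // replace the greedy occurrences by the new symbol
    std::vector<int> ncur, norig;
    ncur.reserve(cur.size());
    norig.reserve(cur.size());
    size_t si = 0;
    for (int p = 0; p < static_cast<int>(cur.size());) {
      if (si < b.starts.size() && p == b.starts[si]) {
        ncur.push_back(next_symbol);
        norig.push_back(orig[p]);
        p += b.w;
        ++si;
      } else {
        ncur.push_back(cur[p]);
        norig.push_back(orig[p]);
        ++p;
      }
    }
    cur.swap(ncur);
    orig.swap(norig);
    ++next_symbol;
  }
  return List::create(_["compressed"] = IntegerVector(cur.begin(), cur.end()),
                      _["rules"] = rules);
}

// All distinct n-grams of lengths minlen..maxlen with greedy non-overlapping
// counts. Returns parallel lists of grams and counts.
// [[Rcpp::export(name = ".cpp_ngram_counts")]]
List cpp_ngram_counts(IntegerVector seq, int minlen, int maxlen) {
  std::vector<int> s(seq.begin(), seq.end());
  int L = static_cast<int>(s.size());
  List grams;
  std::vector<int> counts;
  for (int w = minlen; w <= maxlen; ++w) {
    if (w > L) break;
    std::unordered_map<std::string, std::vector<int>> occ;
    for (int p = 0; p + w <= L; ++p) occ[window_key(s, p, w)].push_back(p);
    // deterministic output order: sort keys by int-lexicographic body
    std::vector<const std::string*> keys;
    keys.reserve(occ.size());
    for (auto& kv : occ) keys.push_back(&kv.first);
    std::sort(keys.begin(), keys.end(),
              [](const std::string* a, const std::string* b) {
                const int* pa = reinterpret_cast<const int*>(a->data());
                const int* pb = reinterpret_cast<const int*>(b->data());
                size_t na = a->size() / sizeof(int), nb = b->size() / sizeof(int);
                std::vector<int> va(pa, pa + na), vb(pb, pb + nb);
                return lex_less(va, vb);
              });
    for (auto* k : keys) {
      auto& pos = occ[*k];
      int n;
      std::vector<int> starts;
      greedy_select(pos, w, n, starts);
      const int* pk = reinterpret_cast<const int*>(k->data());
      grams.push_back(IntegerVector(pk, pk + w));
      counts.push_back(n);
    }
  }
  return List::create(_["grams"] = grams,
                      _["counts"] = IntegerVector(counts.begin(), counts.end()));
}
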