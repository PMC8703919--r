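#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

// Maximal exact matches of length >= k between q and s, forward strand.
// Seeds every k-mer of s in a rolling-hash index, scans q, verifies seed
// bytes, then extends left/right to maximality. 'N' never matches (not even
// another 'N'), so anchors are unambiguous sequence only. Per-diagonal
// bookkeeping reports each maximal run once.
//
// Returns 1-based q_start, s_start and length.
// [[Rcpp::export]]
DataFrame mem_anchors_cpp(std::string q, std::string s, int k) {
  const int nq = (int)q.size(), ns = (int)s.size();
  std::vector<int> out_q, out_s, out_len;
  if (nq >= k && ns >= k && k >= 1) {
    const uint64_t B = 1099511628211ULL;  // FNV prime as polynomial base
    uint64_t Bk = 1;                      // B^k (mod 2^64)
    for (int i = 0; i < k; ++i) Bk *= B;

    std::unordered_map<uint64_t, std::vector<int>> idx;
    idx.reserve((size_t)(ns - k + 1) * 2);

    // index subject k-mers, skipping windows containing N
    {
      uint64_t h = 0;
      int valid = 0;  // run length of non-N bases ending here
      for (int j = 0; j < ns; ++j) {
        unsigned char c = s[j];
        h = h * B + c;
        if (c == 'N') valid = 0; else ++valid;
        if (j >= k) h -= Bk * (unsigned char)s[j - k];
        if (j >= k - 1 && valid >= k) idx[h].push_back(j - k + 1);
      }
    }

    // per-diagonal exclusive end of the last reported MEM (q coordinate)
    std::unordered_map<int64_t, int> diag_end;
    diag_end.reserve(1024);

    uint64_t h = 0;
    int valid = 0;
    for (int i = 0; i < nq; ++i) {
      unsigned char c = q[i];
      h = h * B + c;
      if (c == 'N') valid = 0; else ++valid;
      if (i >= k) h -= Bk * (unsigned char)q[i - k];
      if (i < k - 1 || valid < k) continue;
      int qi = i - k + 1;  // window start in q
      auto it = idx.find(h);
      if (it == idx.end()) continue;
      for (int sj : it->second) {
        int64_t d = (int64_t)qi - sj;
        auto de = diag_end.find(d);
        if (de != diag_end.end() && qi < de->second) continue;  // inside reported MEM
        if (std::memcmp(q.data() + qi, s.data() + sj, k) != 0) continue;  // hash collision
        // extend left
        int a = qi, b = sj;
        while (a > 0 && b > 0 && q[a - 1] == s[b - 1] && q[a - 1] != 'N') { --a; --b; }
        // extend right
        int e = qi + k, f = sj + k;
        while (e < nq && f < ns && q[e] == s[f] && q[e] != 'N') { ++e; ++f; }
        out_q.push_back(a + 1);
        out_s.push_back(b + 1);
        out_len.push_back(e - a);
        diag_end[d] = e;
      }
    }
  }
  return DataFrame::create(_["q_start"] = out_q,
                           _["s_start"] = out_s,
                           _["length"] = out_len);
}

// Hamming-style site scan used by the mismatch-tolerant PCR mode: all start
// positions (1-based) where 'pat' matches 'tmpl' with <= max_mm mismatches
// and an exactly matching final base. N in either sequence counts as a
// mismatch.
// [[Rcpp::export]]
IntegerVector approx_sites_cpp(std::string tmpl, std::string pat, int max_mm) {
  const int n = (int)tmpl.size(), m = (int)pat.size();
  std::vector<int> hits;
  for (int i = 0; i + m <= n; ++i) {
    if (tmpl[i + m - 1] != pat[m - 1] || pat[m - 1] == 'N') continue;
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      char a = tmpl[i + j], b = pat[j];
      if (a != b || a == 'N') { if (++mm > max_mm) break; }
    }
    if (mm <= max_mm) hits.push_back(i + 1);
  }
  return wrap(hits);
}
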