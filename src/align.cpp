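// Alignment and k-mer kernels for allelepanel.
//
// All long/short read mapping goes through an anchored, banded edit-distance
// alignment: exact k-mer anchors give the diagonal, a band around the
// (linearly interpolated) diagonal bounds the DP.  Reads are aligned
// globally, reference ends are free (overlap alignment), so the same kernel
// serves read-to-template polishing, short-read pileup mapping and
// panel-vs-database comparison.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static const int BIG = 1 << 28;

static inline int base2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

static inline char idx2base(int i) {
  static const char b[5] = {'A', 'C', 'G', 'T', '-'};
  return b[i];
}

static inline int count_idx(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    case '-': return 4;
  }
  return -1;
}

// rolling 2-bit k-mer codes; code < 0 marks windows with non-ACGT bases
static void kmer_codes(const std::string& s, int k, std::vector<int64_t>& out) {
  int n = (int)s.size();
  out.assign(std::max(0, n - k + 1), -1);
  if (n < k) return;
  int64_t mask = (k >= 32) ? -1 : (((int64_t)1 << (2 * k)) - 1);
  int64_t code = 0;
  int run = 0;
  for (int i = 0; i < n; ++i) {
    int b = base2(s[i]);
    if (b < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | b) & mask;
    if (++run >= k) out[i - k + 1] = code;
  }
}

// [[Rcpp::export]]
int cpp_edit_distance(std::string a, std::string b) {
  int n = (int)a.size(), m = (int)b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    for (int j = 1; j <= m; ++j) {
      int c = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      c = std::min(c, prev[j] + 1);
      c = std::min(c, cur[j - 1] + 1);
      cur[j] = c;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// Semi-global: pattern fully aligned, free ends on text.  Returns the
// leftmost minimum-distance occurrence as (dist, start, end), 0-based
// half-open on text.
// [[Rcpp::export]]
List cpp_semiglobal(std::string pattern, std::string text) {
  int m = (int)pattern.size(), n = (int)text.size();
  if (m == 0) stop("empty pattern");
  std::vector<int> dp(n + 1), dn(n + 1);
  std::vector<int> sp(n + 1), sn(n + 1);
  for (int j = 0; j <= n; ++j) { dp[j] = 0; sp[j] = j; }
  for (int i = 1; i <= m; ++i) {
    dn[0] = i; sn[0] = 0;
    for (int j = 1; j <= n; ++j) {
      int dd = dp[j - 1] + (pattern[i - 1] == text[j - 1] ? 0 : 1);
      int du = dp[j] + 1;      // pattern base vs gap
      int dl = dn[j - 1] + 1;  // text base vs gap
      int best = dd, st = sp[j - 1];
      if (du < best) { best = du; st = sp[j]; }
      if (dl < best) { best = dl; st = sn[j - 1]; }
      dn[j] = best; sn[j] = st;
    }
    std::swap(dp, dn); std::swap(sp, sn);
  }
  int best = BIG, jend = 0;
  for (int j = 0; j <= n; ++j) if (dp[j] < best) { best = dp[j]; jend = j; }
  return List::create(_["dist"] = best, _["start"] = sp[jend], _["end"] = jend);
}

struct MapResult {
  bool mapped = false;
  int rstart = -1, rend = -1, dist = -1;
  std::string proj;
  std::vector<int> ins_pos;
  std::vector<std::string> ins_seq;
};

// anchored banded overlap alignment of `read` (global) onto `ref` (free ends)
static MapResult map_one(const std::string& read, const std::string& ref,
                         const std::unordered_map<int64_t, int>& index,
                         int k, int band, bool need_proj,
                         std::vector<uint8_t>& bp /* scratch */) {
  MapResult res;
  int m = (int)read.size(), n = (int)ref.size();
  if (m == 0 || n == 0) return res;

  std::vector<int64_t> codes;
  kmer_codes(read, k, codes);
  std::vector<std::pair<int, int>> anchors;  // (read pos, diag)
  for (int i = 0; i < (int)codes.size(); ++i) {
    if (codes[i] < 0) continue;
    auto it = index.find(codes[i]);
    if (it != index.end()) anchors.push_back({i, it->second - i});
  }
  if ((int)anchors.size() < 2) return res;

  auto med_diag = [&](int lo, int hi) {
    std::vector<int> d;
    for (auto& a : anchors) if (a.first >= lo && a.first < hi) d.push_back(a.second);
    if (d.empty()) for (auto& a : anchors) d.push_back(a.second);
    std::nth_element(d.begin(), d.begin() + d.size() / 2, d.end());
    return d[d.size() / 2];
  };
  double d0 = med_diag(0, m / 2), d1 = med_diag(m / 2, m);

  int w = 2 * band + 1;
  // lo[i]: leftmost ref column in band for read row i
  std::vector<int> lo(m + 1);
  for (int i = 0; i <= m; ++i) {
    double center = i + d0 + (d1 - d0) * ((double)i / std::max(1, m));
    int l = (int)center - band;
    if (l < 0) l = 0;
    if (l > n) l = n;
    lo[i] = l;
  }
  // rows must overlap: ensure monotone non-decreasing lo
  for (int i = 1; i <= m; ++i) if (lo[i] < lo[i - 1]) lo[i] = lo[i - 1];

  bp.assign((size_t)(m + 1) * w, 0);  // 0 stop, 1 diag, 2 up, 3 left
  // prev/cur carry a leading BIG sentinel at index 0: prev[k] is row i-1,
  // column lo[i-1] + (k-1), for k in 1..w; indexes beyond w+1 never read
  std::vector<int> prev(w + 2, BIG), cur(w + 2, BIG);
  for (int off = 0; off < w; ++off) {
    if (lo[0] + off <= n) prev[off + 1] = 0;  // free ref start
  }
  const char* refp = ref.c_str();
  for (int i = 1; i <= m; ++i) {
    int shift = lo[i] - lo[i - 1];  // >= 0 (lo is monotone)
    const char rc_ = read[i - 1];
    uint8_t* bprow = &bp[(size_t)i * w];
    const int* pv = prev.data();
    int* cu = cur.data();
    int jmax = std::min(w - 1, n - lo[i]);
    cu[0] = BIG;
    int start_off = 0;
    if (lo[i] == 0) {  // column j = 0: only a read insertion is possible
      int po = std::min(shift + 1, w + 1);
      int pu = pv[po];
      cu[1] = (pu < BIG) ? pu + 1 : BIG;
      bprow[0] = (cu[1] < BIG) ? 2 : 0;
      start_off = 1;
    }
    for (int off = start_off; off <= jmax; ++off) {
      int j = lo[i] + off;
      int po = off + shift + 1;       // prev-row index of column j
      int pd = (po <= w + 1) ? pv[po - 1] : BIG;  // (i-1, j-1)
      int pu = (po <= w) ? pv[po] : BIG;          // (i-1, j)
      int dd = pd + (rc_ == refp[j - 1] ? 0 : 1);
      int du = pu + 1;
      int dl = cu[off] + 1;           // (i, j-1); cu[0] is a BIG sentinel
      int best = dd; int op = 1;
      if (du < best) { best = du; op = 2; }
      if (dl < best) { best = dl; op = 3; }
      cu[off + 1] = best;
      bprow[off] = (best >= BIG) ? 0 : (uint8_t)op;
    }
    for (int off = jmax + 1; off < w; ++off) cu[off + 1] = BIG;
    std::swap(prev, cur);
  }
  // prev carries the +1 sentinel offset: prev[off + 1] is column lo[m] + off
  int best = BIG, boff = -1;
  for (int off = 0; off < w; ++off) {
    int j = lo[m] + off;
    if (j > n) break;
    if (prev[off + 1] < best) { best = prev[off + 1]; boff = off; }
  }
  if (best >= BIG) return res;
  res.mapped = true;
  res.dist = best;
  res.rend = lo[m] + boff;

  // traceback
  int i = m, j = res.rend;
  std::vector<uint8_t> ops;
  ops.reserve(m + 64);
  while (i > 0) {
    uint8_t op = bp[(size_t)i * w + (j - lo[i])];
    if (op == 0) break;  // row-0 free start shouldn't be hit with i>0
    ops.push_back(op);
    if (op == 1) { --i; --j; }
    else if (op == 2) { --i; }
    else { --j; }
  }
  res.rstart = j;
  if (!need_proj) return res;

  res.proj.assign(res.rend - res.rstart, '-');
  std::string pending;
  int ri = 0, rj = res.rstart;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == 1) {
      if (!pending.empty()) { res.ins_pos.push_back(rj); res.ins_seq.push_back(pending); pending.clear(); }
      res.proj[rj - res.rstart] = read[ri];
      ++ri; ++rj;
    } else if (*it == 2) {
      pending += read[ri];
      ++ri;
    } else {
      if (!pending.empty()) { res.ins_pos.push_back(rj); res.ins_seq.push_back(pending); pending.clear(); }
      ++rj;  // deletion: proj stays '-'
    }
  }
  if (!pending.empty()) { res.ins_pos.push_back(rj); res.ins_seq.push_back(pending); }
  return res;
}

static std::unordered_map<int64_t, int> build_index(const std::string& ref, int k) {
  std::unordered_map<int64_t, int> index;
  std::vector<int64_t> codes;
  kmer_codes(ref, k, codes);
  index.reserve(codes.size() * 2);
  for (int i = 0; i < (int)codes.size(); ++i)
    if (codes[i] >= 0) index.emplace(codes[i], i);  // first occurrence kept
  return index;
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, std::string ref, int k, int band,
                   bool keep_proj, bool keep_ins) {
  auto index = build_index(ref, k);
  int nr = reads.size();
  IntegerVector start(nr), end(nr), dist(nr);
  LogicalVector mapped(nr);
  CharacterVector proj(keep_proj ? nr : 0);
  List ins(keep_ins ? nr : 0);
  std::vector<uint8_t> scratch;
  for (int r = 0; r < nr; ++r) {
    std::string rd = as<std::string>(reads[r]);
    MapResult m = map_one(rd, ref, index, k, band, keep_proj || keep_ins, scratch);
    mapped[r] = m.mapped;
    start[r] = m.rstart; end[r] = m.rend; dist[r] = m.dist;
    if (keep_proj) proj[r] = m.mapped ? m.proj : std::string();
    if (keep_ins) {
      ins[r] = List::create(_["pos"] = wrap(m.ins_pos), _["seq"] = wrap(m.ins_seq));
    }
  }
  List out = List::create(_["mapped"] = mapped, _["start"] = start,
                          _["end"] = end, _["dist"] = dist);
  if (keep_proj) out["proj"] = proj;
  if (keep_ins) out["ins"] = ins;
  return out;
}

// distance of every read to every candidate; unmapped -> NA
// [[Rcpp::export]]
IntegerMatrix cpp_read_candidate_dist(CharacterVector reads, CharacterVector cands,
                                      int k, int band) {
  int nr = reads.size(), nc = cands.size();
  IntegerMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_INTEGER);
  std::vector<std::string> rds(nr);
  for (int r = 0; r < nr; ++r) rds[r] = as<std::string>(reads[r]);
  std::vector<uint8_t> scratch;
  for (int c = 0; c < nc; ++c) {
    std::string ref = as<std::string>(cands[c]);
    auto index = build_index(ref, k);
    for (int r = 0; r < nr; ++r) {
      MapResult m = map_one(rds[r], ref, index, k, band, false, scratch);
      if (m.mapped) out(r, c) = m.dist;
    }
  }
  return out;
}

// per-column base counts (rows A,C,G,T,-) from projections
// [[Rcpp::export]]
IntegerMatrix cpp_column_counts(IntegerVector starts, CharacterVector projs, int ref_len) {
  IntegerMatrix out(5, ref_len);
  for (int r = 0; r < projs.size(); ++r) {
    if (starts[r] < 0 || projs[r] == NA_STRING) continue;
    std::string p = as<std::string>(projs[r]);
    int s = starts[r];
    for (int i = 0; i < (int)p.size(); ++i) {
      int ci = count_idx(p[i]);
      if (ci >= 0 && s + i < ref_len) out(ci, s + i) += 1;
    }
  }
  return out;
}

// characters of each projection at given 0-based reference columns
// [[Rcpp::export]]
CharacterMatrix cpp_extract_columns(IntegerVector starts, CharacterVector projs,
                                    IntegerVector cols) {
  int nr = projs.size(), nc = cols.size();
  CharacterMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_STRING);
  for (int r = 0; r < nr; ++r) {
    if (starts[r] < 0 || projs[r] == NA_STRING) continue;
    std::string p = as<std::string>(projs[r]);
    int s = starts[r], e = s + (int)p.size();
    for (int c = 0; c < nc; ++c) {
      int j = cols[c];
      if (j >= s && j < e) out(r, c) = std::string(1, p[j - s]);
    }
  }
  return out;
}

// Majority-vote consensus from mapped reads.  Ties go to the template base.
// Insertions are called when more than half of the reads spanning a junction
// carry one; the plurality inserted sequence is used.  Ends with coverage
// below min_cov are trimmed.
// [[Rcpp::export]]
List cpp_consensus(IntegerVector starts, IntegerVector ends, CharacterVector projs,
                   List ins, std::string ref, double min_cov) {
  int n = (int)ref.size();
  IntegerMatrix counts = cpp_column_counts(starts, projs, n);
  std::vector<int> cov(n, 0), junc(n + 1, 0);
  for (int j = 0; j < n; ++j)
    for (int b = 0; b < 5; ++b) cov[j] += counts(b, j);
  // junction coverage via difference array: read spans junctions (start, end)
  {
    std::vector<int> diff(n + 2, 0);
    for (int r = 0; r < starts.size(); ++r) {
      if (starts[r] < 0) continue;
      int a = starts[r] + 1, b = ends[r] - 1;  // junctions strictly inside
      if (a <= b) { diff[a] += 1; diff[b + 1] -= 1; }
    }
    int acc = 0;
    for (int p = 0; p <= n; ++p) { acc += diff[p]; junc[p] = acc; }
  }
  // insertion tallies
  std::unordered_map<int, std::unordered_map<std::string, int>> instab;
  std::unordered_map<int, int> insn;
  for (int r = 0; r < ins.size(); ++r) {
    if (starts[r] < 0) continue;
    List li = ins[r];
    IntegerVector ip = li["pos"];
    CharacterVector is = li["seq"];
    for (int q = 0; q < ip.size(); ++q) {
      instab[ip[q]][as<std::string>(is[q])] += 1;
      insn[ip[q]] += 1;
    }
  }
  int t0 = 0, t1 = n - 1;
  while (t0 < n && cov[t0] < min_cov) ++t0;
  while (t1 >= 0 && cov[t1] < min_cov) --t1;
  std::string out;
  if (t0 > t1) return List::create(_["seq"] = out, _["start"] = 0, _["end"] = 0);
  out.reserve(t1 - t0 + 16);
  for (int j = t0; j <= t1; ++j) {
    if (j > t0) {
      auto itn = insn.find(j);
      if (itn != insn.end() && junc[j] > 0 && itn->second * 2 > junc[j]) {
        const auto& tab = instab[j];
        std::string bestseq; int bestc = -1;
        for (auto& kv : tab) {
          if (kv.second > bestc || (kv.second == bestc && kv.first < bestseq)) {
            bestc = kv.second; bestseq = kv.first;
          }
        }
        out += bestseq;
      }
    }
    int bestb = -1, bestc = -1;
    for (int b = 0; b < 5; ++b) {
      if (counts(b, j) > bestc) { bestc = counts(b, j); bestb = b; }
    }
    // tie toward template base
    int tb = count_idx(ref[j]);
    if (tb >= 0 && counts(tb, j) == bestc) bestb = tb;
    if (bestb != 4 && bestc > 0) out += idx2base(bestb);
    if (bestc == 0) out += ref[j];  // uncovered interior: keep template
  }
  return List::create(_["seq"] = out, _["start"] = t0, _["end"] = t1 + 1);
}

// k-mer classification support: for each subject sequence, how much of
// `query` is covered by shared k-mers, and the longest covered run
// (gaps <= max_gap bridged).
// [[Rcpp::export]]
DataFrame cpp_kmer_cover(std::string query, CharacterVector subjects, int k, int max_gap) {
  std::vector<int64_t> qc;
  kmer_codes(query, k, qc);
  int ns = subjects.size();
  IntegerVector matched(ns), total(ns), covered(ns), longest(ns);
  int tot = 0;
  for (auto c : qc) if (c >= 0) ++tot;
  for (int s = 0; s < ns; ++s) {
    std::string sub = as<std::string>(subjects[s]);
    std::vector<int64_t> sc;
    kmer_codes(sub, k, sc);
    std::unordered_set<int64_t> sset(sc.begin(), sc.end());
    sset.erase(-1);
    int nmatch = 0, cov = 0, best = 0;
    int run_start = -1, last = -10 * (max_gap + k);
    for (int i = 0; i < (int)qc.size(); ++i) {
      if (qc[i] < 0 || !sset.count(qc[i])) continue;
      ++nmatch;
      if (run_start >= 0 && i - last <= max_gap + k) {
        // extend current run
      } else {
        if (run_start >= 0) {
          int len = last + k - run_start;
          cov += len;
          if (len > best) best = len;
        }
        run_start = i;
      }
      last = i;
    }
    if (run_start >= 0) {
      int len = last + k - run_start;
      cov += len;
      if (len > best) best = len;
    }
    matched[s] = nmatch; total[s] = tot; covered[s] = cov; longest[s] = best;
  }
  return DataFrame::create(_["matched"] = matched, _["total"] = total,
                           _["covered"] = covered, _["longest_run"] = longest);
}

// fraction of each read's k-mers found in the target
// [[Rcpp::export]]
NumericVector cpp_kmer_containment(CharacterVector reads, std::string target, int k) {
  std::vector<int64_t> tc;
  kmer_codes(target, k, tc);
  std::unordered_set<int64_t> tset(tc.begin(), tc.end());
  tset.erase(-1);
  int nr = reads.size();
  NumericVector out(nr);
  for (int r = 0; r < nr; ++r) {
    std::vector<int64_t> rc;
    kmer_codes(as<std::string>(reads[r]), k, rc);
    int tot = 0, hit = 0;
    for (auto c : rc) {
      if (c < 0) continue;
      ++tot;
      if (tset.count(c)) ++hit;
    }
    out[r] = tot > 0 ? (double)hit / tot : 0.0;
  }
  return out;
}

// Per-base error process using R's RNG (deterministic under set.seed):
// insertion before each base with prob pins, deletion with prob pdel,
// substitution with prob pmis.
// [[Rcpp::export]]
CharacterVector cpp_simulate_reads(CharacterVector templates, double pmis,
                                   double pins, double pdel) {
  RNGScope scope;
  int nt = templates.size();
  CharacterVector out(nt);
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int t = 0; t < nt; ++t) {
    std::string tp = as<std::string>(templates[t]);
    std::string rd;
    rd.reserve(tp.size() + 64);
    for (size_t i = 0; i < tp.size(); ++i) {
      if (pins > 0 && unif_rand() < pins)
        rd += bases[std::min(3, (int)(unif_rand() * 4))];
      if (pdel > 0 && unif_rand() < pdel) continue;
      char c = tp[i];
      if (pmis > 0 && unif_rand() < pmis) {
        int b = base2(c);
        int nb = std::min(2, (int)(unif_rand() * 3));
        c = bases[(b + 1 + nb) % 4];
      }
      rd += c;
    }
    if (pins > 0 && unif_rand() < pins)
      rd += bases[std::min(3, (int)(unif_rand() * 4))];
    out[t] = rd;
  }
  return out;
}

// Observed strings of mapped reads over a template window [us, ue):
// projection characters with deletions stripped and read insertions at
// interior junctions spliced back in. Only reads covering the window with
// a flanking base on each side (or reaching the template boundary when
// the window touches it) report.
// [[Rcpp::export]]
CharacterVector cpp_window_obs(IntegerVector starts, IntegerVector ends,
                               CharacterVector projs, List ins,
                               int us, int ue, int n) {
  std::vector<std::string> out;
  for (int r = 0; r < projs.size(); ++r) {
    int st = starts[r], en = ends[r];
    if (st < 0) continue;
    bool left_ok = (us == 0) ? (st == 0) : (st <= us - 1);
    bool right_ok = (ue == n) ? (en == n) : (en >= ue + 1);
    if (!left_ok || !right_ok) continue;
    std::string p = as<std::string>(projs[r]);
    List li = ins[r];
    IntegerVector ip = li["pos"];
    CharacterVector is = li["seq"];
    std::string obs;
    // insertion positions are sorted; advance a cursor once per window
    int q = 0, nq = ip.size();
    while (q < nq && ip[q] <= us) ++q;
    for (int j = us; j < ue; ++j) {
      while (q < nq && ip[q] == j) { obs += as<std::string>(is[q]); ++q; }
      char c = p[j - st];
      if (c != '-') obs += c;
    }
    out.push_back(obs);
  }
  return wrap(out);
}

// Center-string vote over a set of observed window strings: among the
// unique observed strings plus the template, return the one minimizing the
// total edit distance to all observations (ties prefer the template, then
// the lexicographically smallest).
// [[Rcpp::export]]
List cpp_center_string(CharacterVector obs, std::string tpl) {
  int n = obs.size();
  std::vector<std::string> o(n);
  for (int i = 0; i < n; ++i) o[i] = as<std::string>(obs[i]);
  // fast path: when the template is already the plurality of exact
  // observations, it is the center string for all practical purposes
  {
    std::unordered_map<std::string, int> tally;
    for (auto& s : o) tally[s] += 1;
    int tc = tally.count(tpl) ? tally[tpl] : 0;
    int mx = 0;
    for (auto& kv : tally) mx = std::max(mx, kv.second);
    if (tc == mx && mx > 0) {
      return List::create(_["best"] = tpl, _["best_sum"] = 0.0,
                          _["template_sum"] = 0.0);
    }
  }
  std::vector<std::string> cand;
  cand.push_back(tpl);
  {
    std::unordered_set<std::string> seen;
    seen.insert(tpl);
    for (auto& s : o)
      if (seen.insert(s).second) cand.push_back(s);
  }
  auto ed = [](const std::string& a, const std::string& b) {
    int na = (int)a.size(), mb = (int)b.size();
    std::vector<int> prev(mb + 1), cur(mb + 1);
    for (int j = 0; j <= mb; ++j) prev[j] = j;
    for (int i = 1; i <= na; ++i) {
      cur[0] = i;
      for (int j = 1; j <= mb; ++j) {
        int c = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
        c = std::min(c, std::min(prev[j], cur[j - 1]) + 1);
        cur[j] = c;
      }
      std::swap(prev, cur);
    }
    return prev[mb];
  };
  long best_sum = -1, tpl_sum = 0;
  std::string best = tpl;
  for (size_t c = 0; c < cand.size(); ++c) {
    long s = 0;
    for (auto& x : o) s += ed(cand[c], x);
    if (c == 0) { tpl_sum = s; best_sum = s; best = tpl; }
    else if (s < best_sum || (s == best_sum && cand[c] < best && best != tpl)) {
      // strictly better, or tie among non-template candidates
      if (s < best_sum) { best_sum = s; best = cand[c]; }
    }
  }
  return List::create(_["best"] = best, _["best_sum"] = (double)best_sum,
                      _["template_sum"] = (double)tpl_sum);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) {
      switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      }
    }
    out[i] = r;
  }
  return out;
}
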