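// Seed-and-extend local nucleotide matcher.
//
// Exact word seeds (2-bit encoded, word size <= 32) are grouped per
// diagonal and extended ungapped in both directions with an X-drop
// criterion. Hits below the length or identity floors are discarded,
// hits contained in a higher-scoring hit on both axes are merged away,
// and output order is deterministic (score desc, then query start).
// The matcher is substitution-aware only: homologous regions that
// contain indels are reported as several collinear hits rather than
// one gapped alignment.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

const int MATCH = 1;
const int MISMATCH = -2;
const int XDROP = 20;

inline int code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char comp(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
  return r;
}

struct HitC {
  int qs, qe, ss, se;   // 0-based half-open, strand-local subject coords
  int matches, len, score;
  char strand;
};

// Index all clean words of s: word value -> positions.
void index_words(const std::string& s, int w,
                 std::unordered_map<uint64_t, std::vector<int> >& idx) {
  const int n = (int)s.size();
  if (n < w) return;
  uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  uint64_t val = 0;
  int run = 0;  // clean bases accumulated
  for (int i = 0; i < n; ++i) {
    int c = code(s[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run >= w) idx[val].push_back(i - w + 1);
  }
}

// Ungapped X-drop extension around an exact seed [qpos, qpos+w).
HitC extend_seed(const std::string& q, const std::string& s,
                 int qpos, int spos, int w, char strand) {
  int lq = (int)q.size(), ls = (int)s.size();
  // left
  int best = 0, score = 0, off = 0;
  int i = qpos - 1, j = spos - 1;
  while (i >= 0 && j >= 0) {
    score += (q[i] == s[j] && code(q[i]) >= 0) ? MATCH : MISMATCH;
    if (score > best) { best = score; off = qpos - i; }
    if (best - score > XDROP) break;
    --i; --j;
  }
  int left = off;
  // right
  best = 0; score = 0; off = 0;
  i = qpos + w; j = spos + w;
  while (i < lq && j < ls) {
    score += (q[i] == s[j] && code(q[i]) >= 0) ? MATCH : MISMATCH;
    if (score > best) { best = score; off = i - (qpos + w) + 1; }
    if (best - score > XDROP) break;
    ++i; ++j;
  }
  int right = off;
  HitC h;
  h.qs = qpos - left; h.qe = qpos + w + right;
  h.ss = spos - left; h.se = spos + w + right;
  h.len = h.qe - h.qs;
  int m = 0;
  for (int k = 0; k < h.len; ++k)
    if (q[h.qs + k] == s[h.ss + k] && code(q[h.qs + k]) >= 0) ++m;
  h.matches = m;
  h.score = m * MATCH + (h.len - m) * MISMATCH;
  h.strand = strand;
  return h;
}

void scan_strand(const std::string& q, const std::string& s, int w,
                 char strand, bool self_mode, std::vector<HitC>& out) {
  std::unordered_map<uint64_t, std::vector<int> > idx;
  index_words(s, w, idx);
  if (idx.empty() || (int)q.size() < w) return;

  // seeds grouped by diagonal (qpos - spos)
  std::unordered_map<int, std::vector<std::pair<int, int> > > diags;
  uint64_t mask = (w == 32) ? ~0ULL : ((1ULL << (2 * w)) - 1);
  uint64_t val = 0;
  int run = 0;
  for (int i = 0; i < (int)q.size(); ++i) {
    int c = code(q[i]);
    if (c < 0) { run = 0; val = 0; continue; }
    val = ((val << 2) | (uint64_t)c) & mask;
    if (++run < w) continue;
    int qpos = i - w + 1;
    std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(val);
    if (it == idx.end()) continue;
    for (size_t k = 0; k < it->second.size(); ++k) {
      int spos = it->second[k];
      int d = qpos - spos;
      if (self_mode && strand == '+' && d == 0) continue;  // trivial diagonal
      diags[d].push_back(std::make_pair(qpos, spos));
    }
  }

  for (std::unordered_map<int, std::vector<std::pair<int, int> > >::iterator
         dit = diags.begin(); dit != diags.end(); ++dit) {
    std::vector<std::pair<int, int> >& seeds = dit->second;
    std::sort(seeds.begin(), seeds.end());
    int covered_until = -1;
    for (size_t k = 0; k < seeds.size(); ++k) {
      if (seeds[k].first < covered_until) continue;
      HitC h = extend_seed(q, s, seeds[k].first, seeds[k].second, w, strand);
      covered_until = h.qe;
      out.push_back(h);
    }
  }
}

bool hit_order(const HitC& a, const HitC& b) {
  if (a.score != b.score) return a.score > b.score;
  if (a.qs != b.qs) return a.qs < b.qs;
  return a.ss < b.ss;
}

}  // namespace

// [[Rcpp::export(name = ".match_seqs_cpp")]]
DataFrame match_seqs_cpp(std::string query, std::string subject,
                         int word_size, int min_len, double min_identity,
                         bool self_mode, bool both_strands) {
  std::vector<HitC> raw;
  scan_strand(query, subject, word_size, '+', self_mode, raw);
  if (both_strands) {
    std::string src = revcomp(subject);
    scan_strand(query, src, word_size, '-', false, raw);
    // map strand-local subject coords back to forward coords
    int ls = (int)subject.size();
    for (size_t i = 0; i < raw.size(); ++i) {
      if (raw[i].strand == '-') {
        int ss = ls - raw[i].se, se = ls - raw[i].ss;
        raw[i].ss = ss; raw[i].se = se;
      }
    }
  }

  std::vector<HitC> kept;
  for (size_t i = 0; i < raw.size(); ++i) {
    const HitC& h = raw[i];
    if (h.len < min_len) continue;
    double ident = 100.0 * h.matches / h.len;
    if (ident < min_identity) continue;
    if (self_mode) {
      // one record per pair: canonical copy has the smaller start;
      // drop degenerate self-overlaps (palindrome center, same interval)
      if (h.qs > h.ss) continue;
      if (h.qs == h.ss) continue;
    }
    kept.push_back(h);
  }

  std::sort(kept.begin(), kept.end(), hit_order);

  // containment merge: drop a hit contained on both axes in a kept hit
  std::vector<bool> drop(kept.size(), false);
  for (size_t i = 0; i < kept.size(); ++i) {
    if (drop[i]) continue;
    for (size_t j = i + 1; j < kept.size(); ++j) {
      if (drop[j]) continue;
      if (kept[j].strand != kept[i].strand) continue;
      if (kept[j].qs >= kept[i].qs && kept[j].qe <= kept[i].qe &&
          kept[j].ss >= kept[i].ss && kept[j].se <= kept[i].se)
        drop[j] = true;
    }
  }

  std::vector<int> qs, qe, ss, se, len, matches, score;
  std::vector<std::string> strand;
  std::vector<double> ident;
  for (size_t i = 0; i < kept.size(); ++i) {
    if (drop[i]) continue;
    qs.push_back(kept[i].qs); qe.push_back(kept[i].qe);
    ss.push_back(kept[i].ss); se.push_back(kept[i].se);
    len.push_back(kept[i].len); matches.push_back(kept[i].matches);
    score.push_back(kept[i].score);
    strand.push_back(std::string(1, kept[i].strand));
    ident.push_back(100.0 * kept[i].matches / kept[i].len);
  }

  return DataFrame::create(
    Named("qstart") = qs, Named("qend") = qe,
    Named("sstart") = ss, Named("send") = se,
    Named("strand") = strand,
    Named("length") = len, Named("matches") = matches,
    Named("identity_pct") = ident, Named("score") = score,
    Named("stringsAsFactors") = false);
}

// [[Rcpp::export(name = ".smallest_rotation_cpp")]]
std::string smallest_rotation_cpp(std::string s) {
  // Booth's algorithm: index of the lexicographically least rotation
  int n = (int)s.size();
  if (n == 0) return s;
  std::string t = s + s;
  std::vector<int> f(2 * n, -1);
  int k = 0;
  for (int j = 1; j < 2 * n; ++j) {
    char sj = t[j];
    int i = f[j - k - 1];
    while (i != -1 && sj != t[k + i + 1]) {
      if (sj < t[k + i + 1]) k = j - i - 1;
      i = f[i];
    }
    if (sj != t[k + i + 1]) {
      if (sj < t[k]) k = j;
      f[j - k] = -1;
    } else {
      f[j - k] = i + 1;
    }
  }
  return t.substr(k, n);
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
std::string revcomp_cpp(std::string s) {
  return revcomp(s);
}
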