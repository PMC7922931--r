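// Core of the fragment recruiter: a positional q-gram index over the
// reference genome, a lossless q-gram candidate filter (two length-n strings
// with at most k mismatches share at least n - q + 1 - k*q position-consistent
// q-grams), and ungapped full-length scoring of surviving candidate windows.
//
// A base matches only itself and only when it is one of A/C/G/T: 'N' never
// matches, including against another 'N'. The same rule is used by the naive
// reference scan so the two routes are comparable position by position.

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline char complement(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = complement(s[i]);
  return out;
}

// maximum mismatch count tolerated by the q-gram lemma bound at this
// threshold; windows with more mismatches may be skipped safely
static inline int lemma_k(double identity_threshold, int n) {
  return (int)std::floor((1.0 - identity_threshold) * n + 1e-9);
}

struct QgramIndex {
  std::unordered_map<uint64_t, std::vector<int>> pos;
  int q;
};

static void build_index(const std::string& g, int q, QgramIndex& idx) {
  idx.q = q;
  const int L = (int)g.size();
  if (L < q) return;
  const uint64_t mask = (q >= 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
  uint64_t key = 0;
  int valid = 0;  // run of consecutive A/C/G/T bases ending at i
  for (int i = 0; i < L; ++i) {
    int c = base_code(g[i]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= q) idx.pos[key].push_back(i - q + 1);
  }
}

// count mismatches of read r against genome window starting at s,
// bailing out once `limit` is exceeded
static inline int window_mismatches(const std::string& g, int s,
                                    const std::string& r, int limit) {
  int mm = 0;
  const int n = (int)r.size();
  for (int j = 0; j < n; ++j) {
    char a = g[s + j], b = r[j];
    if (a != b || base_code(a) < 0) {
      if (++mm > limit) return mm;
    }
  }
  return mm;
}

// candidate window starts for one read orientation; a window start s gets one
// vote per read q-gram found in the genome at the position implied by s
static std::vector<int> candidate_starts(const QgramIndex& idx,
                                         const std::string& r,
                                         int L, int t) {
  const int n = (int)r.size(), q = idx.q;
  std::vector<int> out;
  if (t < 1) {  // filter carries no information: every window is a candidate
    for (int s = 0; s + n <= L; ++s) out.push_back(s);
    return out;
  }
  const uint64_t mask = (q >= 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);
  std::unordered_map<int, int> votes;
  uint64_t key = 0;
  int valid = 0;
  for (int j = 0; j < n; ++j) {
    int c = base_code(r[j]);
    if (c < 0) { valid = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)c) & mask;
    if (++valid >= q) {
      auto it = idx.pos.find(key);
      if (it == idx.pos.end()) continue;
      const int joff = j - q + 1;
      for (int p : it->second) {
        int s = p - joff;
        if (s >= 0 && s + n <= L) ++votes[s];
      }
    }
  }
  for (auto& kv : votes)
    if (kv.second >= t) out.push_back(kv.first);
  std::sort(out.begin(), out.end());
  return out;
}

struct Hit {
  int start;
  int matches;
  char strand;
};

// largest mismatch count whose identity still clears the strict threshold
static int max_accept_mismatches(double thr, int n) {
  int lmax = -1;
  for (int mm = 0; mm <= n; ++mm) {
    if ((double)(n - mm) / (double)n > thr) lmax = mm; else break;
  }
  return lmax;
}

static void recruit_one(const QgramIndex& idx, const std::string& g,
                        const std::string& r, char strand,
                        double thr, std::vector<Hit>& hits) {
  const int n = (int)r.size(), L = (int)g.size();
  if (n > L) return;
  const int k = lemma_k(thr, n);
  const int t = n - idx.q + 1 - k * idx.q;
  const int lmax = max_accept_mismatches(thr, n);
  if (lmax < 0) return;
  std::vector<int> cand = candidate_starts(idx, r, L, t);
  for (int s : cand) {
    int mm = window_mismatches(g, s, r, lmax);
    if (mm <= lmax) hits.push_back({s, n - mm, strand});
  }
}

static bool hit_before(const Hit& a, const Hit& b) {
  if (a.matches != b.matches) return a.matches > b.matches;  // identity desc
  if (a.start != b.start) return a.start < b.start;          // leftmost
  return a.strand == '+' && b.strand == '-';                 // forward first
}

// [[Rcpp::export]]
List cpp_recruit(std::string genome, CharacterVector read_seqs,
                 CharacterVector read_ids, int q, double identity_threshold,
                 int min_align_len, bool both_strands, bool best_per_read) {
  QgramIndex idx;
  build_index(genome, q, idx);
  const int L = (int)genome.size();

  std::vector<std::string> out_id;
  std::vector<int> out_start, out_end, out_matches, out_len;
  std::vector<std::string> out_strand;
  std::vector<double> out_ident;
  int skipped_short = 0;

  for (int i = 0; i < read_seqs.size(); ++i) {
    std::string r = as<std::string>(read_seqs[i]);
    const int n = (int)r.size();
    if (n < min_align_len) { ++skipped_short; continue; }
    if (n > L) continue;
    std::vector<Hit> hits;
    recruit_one(idx, genome, r, '+', identity_threshold, hits);
    if (both_strands)
      recruit_one(idx, genome, revcomp(r), '-', identity_threshold, hits);
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end(), hit_before);
    size_t keep = best_per_read ? 1 : hits.size();
    std::string id = as<std::string>(read_ids[i]);
    for (size_t h = 0; h < keep; ++h) {
      out_id.push_back(id);
      out_start.push_back(hits[h].start);
      out_end.push_back(hits[h].start + n);
      out_strand.push_back(std::string(1, hits[h].strand));
      out_matches.push_back(hits[h].matches);
      out_len.push_back(n);
      out_ident.push_back((double)hits[h].matches / (double)n);
    }
  }

  return List::create(
    _["read_id"] = wrap(out_id),
    _["start"] = wrap(out_start),
    _["end"] = wrap(out_end),
    _["strand"] = wrap(out_strand),
    _["matches"] = wrap(out_matches),
    _["align_len"] = wrap(out_len),
    _["identity"] = wrap(out_ident),
    _["skipped_short"] = skipped_short);
}

// Naive reference scan: every full-length window on one or both strands is
// scored by direct comparison, with no q-gram shortcut. Kept deliberately
// independent of the indexed path so the two can be cross-validated.
// [[Rcpp::export]]
List cpp_scan(std::string genome, std::string read, double identity_threshold,
              bool both_strands) {
  const int L = (int)genome.size(), n = (int)read.size();
  std::vector<Hit> hits;
  const int lmax = max_accept_mismatches(identity_threshold, n);
  if (lmax >= 0 && n <= L) {
    for (int s = 0; s + n <= L; ++s) {
      int mm = window_mismatches(genome, s, read, lmax);
      if (mm <= lmax) hits.push_back({s, n - mm, '+'});
    }
    if (both_strands) {
      std::string rc = revcomp(read);
      for (int s = 0; s + n <= L; ++s) {
        int mm = window_mismatches(genome, s, rc, lmax);
        if (mm <= lmax) hits.push_back({s, n - mm, '-'});
      }
    }
  }
  std::sort(hits.begin(), hits.end(), hit_before);
  const int m = (int)hits.size();
  IntegerVector start(m), end(m), matches(m);
  CharacterVector strand(m);
  NumericVector ident(m);
  for (int i = 0; i < m; ++i) {
    start[i] = hits[i].start;
    end[i] = hits[i].start + n;
    matches[i] = hits[i].matches;
    strand[i] = std::string(1, hits[i].strand);
    ident[i] = (double)hits[i].matches / (double)n;
  }
  return List::create(_["start"] = start, _["end"] = end,
                      _["strand"] = strand, _["matches"] = matches,
                      _["align_len"] = n, _["identity"] = ident);
}

// forward-strand candidate windows surviving the q-gram filter; exposed so
// the lossless-filter property can be checked against a direct mismatch scan
// [[Rcpp::export]]
IntegerVector cpp_qgram_candidates(std::string genome, std::string read,
                                   int q, double identity_threshold) {
  QgramIndex idx;
  build_index(genome, q, idx);
  const int n = (int)read.size();
  const int k = lemma_k(identity_threshold, n);
  const int t = n - q + 1 - k * q;
  std::vector<int> cand = candidate_starts(idx, read, (int)genome.size(), t);
  return wrap(cand);
}

// [[Rcpp::export]]
List cpp_qgram_index(std::string genome, int q) {
  QgramIndex idx;
  build_index(genome, q, idx);
  std::vector<std::pair<std::string, std::vector<int>>> entries;
  entries.reserve(idx.pos.size());
  static const char* bases = "ACGT";
  for (auto& kv : idx.pos) {
    std::string gram(q, 'A');
    uint64_t key = kv.first;
    for (int j = q - 1; j >= 0; --j) {
      gram[j] = bases[key & 3ULL];
      key >>= 2;
    }
    entries.push_back({gram, kv.second});
  }
  std::sort(entries.begin(), entries.end());
  List out(entries.size());
  CharacterVector nm(entries.size());
  for (size_t i = 0; i < entries.size(); ++i) {
    nm[i] = entries[i].first;
    std::sort(entries[i].second.begin(), entries[i].second.end());
    out[i] = wrap(entries[i].second);
  }
  out.attr("names") = nm;
  return out;
}
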