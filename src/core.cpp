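#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Quality trimming (sliding-window, Trimmomatic-style)
// ---------------------------------------------------------------------------

// Returns, per read, the number of 5' bases kept: the read is cut at the
// start of the first window (of `window` bases, stepping by 1) whose mean
// quality falls below `mean_q`. Reads with no failing window keep full length.
// [[Rcpp::export]]
IntegerVector cpp_quality_keep_len(CharacterVector qual, int window,
                                   double mean_q, int phred_offset) {
  const int n = qual.size();
  IntegerVector out(n);
  const double thresh = mean_q * window;
  for (int i = 0; i < n; ++i) {
    const char *q = CHAR(STRING_ELT(qual, i));
    int len = LENGTH(STRING_ELT(qual, i));
    if (len < window) { out[i] = len; continue; }
    double sum = 0.0;
    for (int j = 0; j < window; ++j) sum += q[j] - phred_offset;
    int cut = len;
    if (sum < thresh) cut = 0;
    for (int s = 1; cut == len && s + window <= len; ++s) {
      sum += (q[s + window - 1] - phred_offset) - (q[s - 1] - phred_offset);
      if (sum < thresh) cut = s;
    }
    out[i] = cut;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Bait scanning: ungapped sliding-window identity
// ---------------------------------------------------------------------------

// Best bait window per read. Baits must share a common length. Identity is
// matching positions / bait length; 'N' (or any non-ACGT) never matches.
// Tie-break at equal mismatch count: smaller read offset, then bait order.
// Returns a 3-column integer matrix: bait index (1-based, 0 = no hit),
// 0-based read offset, mismatch count.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_baits(CharacterVector reads, CharacterVector baits,
                             int max_mm) {
  const int n = reads.size(), nb = baits.size();
  int bl = nb > 0 ? LENGTH(STRING_ELT(baits, 0)) : 0;
  std::vector<const char *> bp(nb);
  for (int b = 0; b < nb; ++b) {
    if (LENGTH(STRING_ELT(baits, b)) != bl)
      stop("all baits must have the same length");
    bp[b] = CHAR(STRING_ELT(baits, b));
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int len = LENGTH(STRING_ELT(reads, i));
    int best_mm = max_mm + 1, best_off = -1, best_b = -1;
    for (int off = 0; off + bl <= len && best_mm > 0; ++off) {
      for (int b = 0; b < nb; ++b) {
        int limit = best_mm - 1;  // must strictly improve
        int mm = 0;
        const char *w = r + off;
        const char *bb = bp[b];
        for (int j = 0; j < bl; ++j) {
          char c = w[j];
          if (c != bb[j] || (c != 'A' && c != 'C' && c != 'G' && c != 'T')) {
            if (++mm > limit) break;
          }
        }
        if (mm < best_mm) { best_mm = mm; best_off = off; best_b = b;
          if (best_mm == 0) break; }
      }
    }
    if (best_b >= 0) {
      out(i, 0) = best_b + 1; out(i, 1) = best_off; out(i, 2) = best_mm;
    } else {
      out(i, 0) = 0; out(i, 1) = NA_INTEGER; out(i, 2) = NA_INTEGER;
    }
  }
  return out;
}

// Full-length mismatch count between equal-length string pairs.
// [[Rcpp::export]]
IntegerVector cpp_mismatch_count(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *x = CHAR(STRING_ELT(a, i));
    const char *y = CHAR(STRING_ELT(b, i));
    int lx = LENGTH(STRING_ELT(a, i)), ly = LENGTH(STRING_ELT(b, i));
    if (lx != ly) stop("strings must have equal length (pair %d)", i + 1);
    int mm = 0;
    for (int j = 0; j < lx; ++j) if (x[j] != y[j]) ++mm;
    out[i] = mm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Read-pair overlap merging
// ---------------------------------------------------------------------------

// Best suffix(s1)-prefix(s2rc) overlap per pair: lowest mismatch ratio wins,
// ties resolved toward the longer overlap. Returns matrix: overlap length
// (0 = none qualifying) and mismatch count.
// [[Rcpp::export]]
IntegerMatrix cpp_best_overlap(CharacterVector s1, CharacterVector s2rc,
                               int min_overlap, double max_mm_ratio) {
  const int n = s1.size();
  if (s2rc.size() != n) stop("mate vectors differ in length");
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) {
    const char *a = CHAR(STRING_ELT(s1, i));
    const char *b = CHAR(STRING_ELT(s2rc, i));
    int l1 = LENGTH(STRING_ELT(s1, i)), l2 = LENGTH(STRING_ELT(s2rc, i));
    int omax = std::min(l1, l2);
    int best_o = 0, best_mm = 0;
    double best_ratio = 2.0;
    for (int o = omax; o >= min_overlap; --o) {
      int allow = (int)(max_mm_ratio * o);
      const char *sa = a + (l1 - o);
      int mm = 0; bool ok = true;
      for (int j = 0; j < o; ++j) {
        if (sa[j] != b[j] && ++mm > allow) { ok = false; break; }
      }
      if (!ok) continue;
      double ratio = (double)mm / o;
      if (ratio < best_ratio - 1e-12) { best_ratio = ratio; best_o = o; best_mm = mm; }
    }
    out(i, 0) = best_o; out(i, 1) = best_mm;
  }
  return out;
}

// ---------------------------------------------------------------------------
// k-mer index + seeded ungapped alignment
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
};

static inline int base2bits(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

static std::string revcomp_str(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      default: c = 'N';
    }
  }
  return r;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector seqs, int k) {
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int c = 0; c < seqs.size(); ++c) {
    std::string s = as<std::string>(seqs[c]);
    idx->seqs.push_back(s);
    const int len = (int)s.size();
    if (len < k) continue;
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < len; ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k)
        idx->map[key].push_back({(int32_t)c, (int32_t)(p - k + 1)});
    }
  }
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) { return XPtr<KmerIndex>(xp)->k; }

// [[Rcpp::export]]
List cpp_index_lookup(SEXP xp, CharacterVector kmers) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != k) stop("query length must equal index k");
    uint64_t key = 0; bool valid = true;
    for (int j = 0; j < k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { valid = false; break; }
      key = (key << 2) | (uint64_t)b;
    }
    IntegerMatrix hits(0, 2);
    if (valid) {
      auto it = idx->map.find(key);
      if (it != idx->map.end()) {
        hits = IntegerMatrix((int)it->second.size(), 2);
        for (size_t h = 0; h < it->second.size(); ++h) {
          hits(h, 0) = it->second[h].first + 1;  // 1-based contig index
          hits(h, 1) = it->second[h].second;     // 0-based position
        }
      }
    }
    out[i] = hits;
  }
  return out;
}

struct Cand {
  int contig, pos, orient;  // orient: 0 = forward, 1 = flank revcomp
  bool operator<(const Cand &o) const {
    if (orient != o.orient) return orient < o.orient;
    if (contig != o.contig) return contig < o.contig;
    return pos < o.pos;
  }
  bool operator==(const Cand &o) const {
    return orient == o.orient && contig == o.contig && pos == o.pos;
  }
};

static int count_mm(const char *a, const char *b, int len, int limit) {
  int mm = 0;
  for (int j = 0; j < len; ++j)
    if (a[j] != b[j] && ++mm > limit) return mm;
  return mm;
}

// Align each flank against the indexed genome, ungapped, allowing up to
// floor(max_mm_frac * length) mismatches. Candidate placements come from
// exact k-mer seeds at every flank offset (both orientations); with
// exhaustive = true every placement is evaluated instead. Flanks shorter
// than k always take the exhaustive route. Among placements with the
// minimal mismatch count the first in (orientation, contig, position)
// order is reported along with n_best, the count of co-optimal placements.
// Columns: contig (1-based, 0 = unaligned), pos (0-based), strand
// (1 = forward, -1 = reverse), mm, n_best.
// [[Rcpp::export]]
IntegerMatrix cpp_align_flanks(SEXP xp, CharacterVector flanks,
                               double max_mm_frac, bool exhaustive) {
  XPtr<KmerIndex> idx(xp);
  const int k = idx->k;
  const int nc = (int)idx->seqs.size();
  const int n = flanks.size();
  IntegerMatrix out(n, 5);
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(flanks[i]);
    const int L = (int)fwd.size();
    std::string rev = revcomp_str(fwd);
    const std::string *ori[2] = {&fwd, &rev};
    const int allow = (int)(max_mm_frac * L);
    int best_mm = allow + 1, n_best = 0;
    int b_contig = -1, b_pos = -1, b_orient = 0;

    std::vector<Cand> cands;
    if (exhaustive || L < k) {
      for (int o = 0; o < 2; ++o)
        for (int c = 0; c < nc; ++c) {
          int clen = (int)idx->seqs[c].size();
          for (int p = 0; p + L <= clen; ++p) cands.push_back({c, p, o});
        }
    } else {
      for (int o = 0; o < 2; ++o) {
        const std::string &s = *ori[o];
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < L; ++p) {
          int b = base2bits(s[p]);
          if (b < 0) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)b) & mask;
          if (++run >= k) {
            auto it = idx->map.find(key);
            if (it != idx->map.end()) {
              int soff = p - k + 1;
              for (auto &h : it->second) {
                int start = h.second - soff;
                if (start >= 0 &&
                    start + L <= (int)idx->seqs[h.first].size())
                  cands.push_back({(int)h.first, start, o});
              }
            }
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
    }

    for (auto &cd : cands) {
      const char *g = idx->seqs[cd.contig].c_str() + cd.pos;
      int mm = count_mm(ori[cd.orient]->c_str(), g, L, allow);
      if (mm > allow) continue;
      if (mm < best_mm) {
        best_mm = mm; n_best = 1;
        b_contig = cd.contig; b_pos = cd.pos; b_orient = cd.orient;
      } else if (mm == best_mm) {
        ++n_best;
      }
    }
    if (n_best > 0) {
      out(i, 0) = b_contig + 1; out(i, 1) = b_pos;
      out(i, 2) = b_orient == 0 ? 1 : -1;
      out(i, 3) = best_mm; out(i, 4) = n_best;
    } else {
      out(i, 0) = 0; out(i, 1) = NA_INTEGER; out(i, 2) = NA_INTEGER;
      out(i, 3) = NA_INTEGER; out(i, 4) = 0;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Local homology filter (retrovirus-internal sequence screen)
// ---------------------------------------------------------------------------

// TRUE for any flank carrying a local ungapped match to any target with
// >= min_match matching bases inside some window of `win` bases. Candidate
// diagonals are seeded with exact k-mers (both flank orientations); each
// seeded diagonal is screened with a rolling window.
// [[Rcpp::export]]
LogicalVector cpp_local_match(CharacterVector flanks, CharacterVector targets,
                              int k, int win, int min_match) {
  const int nt = targets.size();
  std::vector<std::string> tg(nt);
  std::unordered_map<uint64_t, std::vector<std::pair<int32_t, int32_t>>> map;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    const std::string &s = tg[t];
    uint64_t key = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int b = base2bits(s[p]);
      if (b < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t)b) & mask;
      if (++run >= k) map[key].push_back({(int32_t)t, (int32_t)(p - k + 1)});
    }
  }

  const int n = flanks.size();
  LogicalVector out(n);
  std::vector<char> match_buf;
  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(flanks[i]);
    const int L = (int)fwd.size();
    bool hit = false;
    if (L >= win) {
      std::string rev = revcomp_str(fwd);
      const std::string *ori[2] = {&fwd, &rev};
      for (int o = 0; o < 2 && !hit; ++o) {
        const std::string &q = *ori[o];
        std::vector<std::pair<int32_t, int64_t>> diags;  // (target, diag)
        uint64_t key = 0; int run = 0;
        for (int p = 0; p < L; ++p) {
          int b = base2bits(q[p]);
          if (b < 0) { run = 0; key = 0; continue; }
          key = ((key << 2) | (uint64_t)b) & mask;
          if (++run >= k) {
            auto it = map.find(key);
            if (it != map.end())
              for (auto &h : it->second)
                diags.push_back({h.first, (int64_t)h.second - (p - k + 1)});
          }
        }
        std::sort(diags.begin(), diags.end());
        diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
        for (auto &d : diags) {
          const std::string &t = tg[d.first];
          // overlap of q[0,L) with t shifted by diag
          int64_t diag = d.second;
          int qs = diag < 0 ? (int)(-diag) : 0;
          int ts = diag < 0 ? 0 : (int)diag;
          int ol = std::min(L - qs, (int)t.size() - ts);
          if (ol < win) continue;
          match_buf.assign(ol, 0);
          for (int j = 0; j < ol; ++j)
            match_buf[j] = (q[qs + j] == t[ts + j]) ? 1 : 0;
          int sum = 0;
          for (int j = 0; j < win; ++j) sum += match_buf[j];
          if (sum >= min_match) { hit = true; break; }
          for (int j = win; j < ol; ++j) {
            sum += match_buf[j] - match_buf[j - win];
            if (sum >= min_match) { hit = true; break; }
          }
          if (hit) break;
        }
      }
    }
    out[i] = hit;
  }
  return out;
}
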