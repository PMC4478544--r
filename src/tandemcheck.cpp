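// Low-level kernels: 2-bit k-mer sets, a seed-and-extend banded aligner used
// for read mapping, homology search and panel depth, a base-level pileup, and
// the sequencing-error process.  All coordinates exported to R are 1-based
// inclusive.

#include <Rcpp.h>

#include <algorithm>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

inline int b2(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

const char B2C[5] = "ACGT";

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) {
    int b = b2(s[s.size() - 1 - i]);
    if (b >= 0) r[i] = B2C[3 - b];
  }
  return r;
}

// Rolling enumeration of k-mer codes; windows containing non-ACGT symbols are
// skipped.  pos (if given) records 1-based window starts.
void collect_kmers(const std::string& s, int k, bool canonical,
                   std::vector<uint64_t>& codes, std::vector<int>* pos) {
  if ((int)s.size() < k) return;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < s.size(); ++i) {
    int b = b2(s[i]);
    if (b < 0) { run = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << (uint64_t)shift);
    if (++run >= k) {
      codes.push_back(canonical ? std::min(fwd, rev) : fwd);
      if (pos) pos->push_back((int)i - k + 2);
    }
  }
}

}  // namespace

// Sorted unique canonical k-mer codes of a set of sequences, as doubles
// (exact for k <= 26).
// [[Rcpp::export]]
NumericVector tc_kmer_set(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    collect_kmers(s, k, true, codes, nullptr);
  }
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  NumericVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = (double)codes[i];
  return out;
}

// Canonical k-mer codes with their multiplicities (for the single-copy filter).
// [[Rcpp::export]]
List tc_kmer_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    collect_kmers(s, k, true, codes, nullptr);
  }
  std::sort(codes.begin(), codes.end());
  std::vector<uint64_t> uq;
  std::vector<int> cnt;
  for (size_t i = 0; i < codes.size();) {
    size_t j = i;
    while (j < codes.size() && codes[j] == codes[i]) ++j;
    uq.push_back(codes[i]);
    cnt.push_back((int)(j - i));
    i = j;
  }
  NumericVector oc(uq.size());
  IntegerVector on(cnt.size());
  for (size_t i = 0; i < uq.size(); ++i) { oc[i] = (double)uq[i]; on[i] = cnt[i]; }
  return List::create(_["codes"] = oc, _["counts"] = on);
}

// Window starts (1-based) of contig k-mers absent from a sorted member set.
// Tiled mode audits windows 1, k+1, 2k+1, ...; sliding mode every offset.
// With a copy filter, windows whose canonical k-mer occurs more than once in
// the assembly are skipped.
// [[Rcpp::export]]
IntegerVector tc_kmer_audit(std::string contig, int k, NumericVector members,
                            bool sliding, bool use_filter,
                            NumericVector filter_codes,
                            IntegerVector filter_counts) {
  if (k < 1 || k > 26) stop("k must be in [1, 26]");
  std::vector<uint64_t> codes;
  std::vector<int> pos;
  collect_kmers(contig, k, true, codes, &pos);
  std::vector<int> out;
  const double* mb = REAL(members);
  const size_t mn = members.size();
  for (size_t i = 0; i < codes.size(); ++i) {
    if (!sliding && ((pos[i] - 1) % k) != 0) continue;
    double code = (double)codes[i];
    if (use_filter) {
      const double* fb = REAL(filter_codes);
      size_t fn = filter_codes.size();
      const double* it = std::lower_bound(fb, fb + fn, code);
      if (it != fb + fn && *it == code &&
          filter_counts[(int)(it - fb)] > 1)
        continue;
    }
    if (!std::binary_search(mb, mb + mn, code)) out.push_back(pos[i]);
  }
  return wrap(out);
}

namespace {

struct Aln {
  bool ok = false;
  int ts = 0, te = 0, qs = 0, qe = 0;  // 1-based on target / query-as-aligned
  int edits = 0, matches = 0, alen = 0;
};

// Banded edit-distance alignment of query Q (rows, global unless clipped at a
// target edge) against target window T[ws, we) (free target prefix/suffix).
// cen is the expected column of query row 0; B the half band width.
Aln band_align(const std::string& Q, const std::string& T, int ws, int we,
               int cen, int B, bool free_qs, bool free_qe) {
  const int m = (int)Q.size();
  const int n = we - ws;
  const int W = 2 * B + 1;
  const uint16_t INF = 0x3fff;
  static std::vector<uint16_t> D;
  D.assign((size_t)(m + 1) * W, INF);
  auto off = [&](int i, int j) { return j - (i + cen - B); };
  auto inband = [&](int i, int j) {
    if (i < 0 || i > m || j < 0 || j > n) return false;
    int o = off(i, j);
    return o >= 0 && o < W;
  };
  auto at = [&](int i, int j) -> uint16_t& {
    return D[(size_t)i * W + off(i, j)];
  };
  for (int j = std::max(0, cen - B); j <= std::min(n, cen + B); ++j)
    at(0, j) = 0;  // free target prefix
  // forward pass on raw row pointers; in band storage the diagonal
  // neighbour (i-1, j-1) sits at prev[o], (i-1, j) at prev[o+1] and
  // (i, j-1) at cur[o-1]
  const char* Tw = T.data() + ws;
  for (int i = 1; i <= m; ++i) {
    const uint16_t* prev = D.data() + (size_t)(i - 1) * W;
    uint16_t* cur = D.data() + (size_t)i * W;
    const int base = i + cen - B;  // target col at offset 0
    int lo = std::max(0, base), hi = std::min(n, base + 2 * B);
    if (lo > hi) continue;
    const char qc = Q[i - 1];
    for (int j = lo; j <= hi; ++j) {
      const int o = j - base;
      int best = INF;
      if (j == 0) best = free_qs ? 0 : std::min<int>(INF, i);
      if (j > 0) {
        int v = prev[o];  // (i-1, j-1)
        v += (qc == Tw[j - 1] ? 0 : 1);
        if (v < best) best = v;
        if (o > 0) {
          int l = cur[o - 1] + 1;  // (i, j-1)
          if (l < best) best = l;
        }
      }
      if (o + 1 < W) {
        int u = prev[o + 1] + 1;  // (i-1, j)
        if (u < best) best = u;
      }
      cur[o] = (uint16_t)std::min<int>(best, INF);
    }
  }
  int bi = -1, bj = -1, bc = INF;
  {
    int lo = std::max(0, m + cen - B), hi = std::min(n, m + cen + B);
    for (int j = lo; j <= hi; ++j)
      if (inband(m, j) && at(m, j) < bc) { bc = at(m, j); bi = m; bj = j; }
  }
  if (free_qe) {
    for (int i = 0; i <= m; ++i)
      if (inband(i, n) && at(i, n) < bc) { bc = at(i, n); bi = i; bj = n; }
  }
  Aln res;
  if (bi < 0 || bc >= INF) return res;
  int i = bi, j = bj, matches = 0, alen = 0;
  while (true) {
    if (i == 0) break;
    if (free_qs && j == 0 && at(i, j) == 0) break;
    uint16_t cur = at(i, j);
    if (j > 0 && inband(i - 1, j - 1) && at(i - 1, j - 1) < INF &&
        at(i - 1, j - 1) + (Q[i - 1] == T[ws + j - 1] ? 0 : 1) == cur) {
      if (Q[i - 1] == T[ws + j - 1]) ++matches;
      --i; --j; ++alen;
      continue;
    }
    if (inband(i - 1, j) && at(i - 1, j) < INF && at(i - 1, j) + 1 == cur) {
      --i; ++alen;
      continue;
    }
    if (j > 0 && inband(i, j - 1) && at(i, j - 1) < INF &&
        at(i, j - 1) + 1 == cur) {
      --j; ++alen;
      continue;
    }
    --i; ++alen;  // vertical against the j == 0 boundary
  }
  if (bi <= i || bj <= j) return res;  // empty alignment
  res.ok = true;
  res.qs = i + 1;
  res.qe = bi;
  res.ts = ws + j + 1;
  res.te = ws + bj;
  res.edits = bc;
  res.matches = matches;
  res.alen = alen;
  return res;
}

struct SeedHit {
  int t, diag, qpos;
};

}  // namespace

// Seed-and-extend search of every query (both strands) against an indexed set
// of targets.  Returns all candidate alignments passing max_edit_frac; the
// caller filters/ranks.  Query coordinates are reported on the original
// (plus-strand) query frame; target coordinates on the forward target.
// [[Rcpp::export]]
DataFrame tc_search(CharacterVector targets, CharacterVector queries,
                    int seed_len = 13, int stride = 4, int cluster_gap = 40,
                    int min_seed_hits = 2, int band_min = 16,
                    int band_pad = 16, double max_edit_frac = 0.35,
                    int max_clusters = 64) {
  if (seed_len < 4 || seed_len > 15) stop("seed_len must be in [4, 15]");
  const int nt = targets.size();
  std::vector<std::string> tg(nt);
  for (int i = 0; i < nt; ++i) tg[i] = as<std::string>(targets[i]);

  // flat sorted seed index: (code, packed target<<32 | pos0)
  std::vector<std::pair<uint64_t, uint64_t>> idx;
  {
    std::vector<uint64_t> codes;
    std::vector<int> pos;
    for (int t = 0; t < nt; ++t) {
      codes.clear(); pos.clear();
      collect_kmers(tg[t], seed_len, false, codes, &pos);
      for (size_t i = 0; i < codes.size(); ++i)
        idx.emplace_back(codes[i],
                         ((uint64_t)t << 32) | (uint64_t)(pos[i] - 1));
    }
    std::sort(idx.begin(), idx.end());
  }
  auto lookup = [&](uint64_t code, std::vector<std::pair<int, int>>& out) {
    auto lo = std::lower_bound(
        idx.begin(), idx.end(), std::make_pair(code, (uint64_t)0));
    for (auto it = lo; it != idx.end() && it->first == code; ++it)
      out.emplace_back((int)(it->second >> 32), (int)(it->second & 0xffffffffu));
  };

  std::vector<int> o_q, o_t, o_ts, o_te, o_qs, o_qe, o_str, o_ed, o_mt,
      o_al, o_vt;

  std::vector<uint64_t> qcodes;
  std::vector<int> qpos;
  std::vector<SeedHit> hits;
  std::vector<std::pair<int, int>> lk;

  for (R_xlen_t qi = 0; qi < queries.size(); ++qi) {
    std::string q0 = as<std::string>(queries[qi]);
    const int m = (int)q0.size();
    if (m < seed_len) continue;
    std::vector<uint64_t> seen;  // dedupe (strand, t, ts)
    for (int strand = 0; strand < 2; ++strand) {
      std::string q = strand == 0 ? q0 : revcomp(q0);
      qcodes.clear(); qpos.clear();
      collect_kmers(q, seed_len, false, qcodes, &qpos);
      hits.clear();
      for (size_t i = 0; i < qcodes.size(); ++i) {
        if (((qpos[i] - 1) % stride) != 0) continue;
        lk.clear();
        lookup(qcodes[i], lk);
        for (auto& tp : lk)
          hits.push_back({tp.first, tp.second - (qpos[i] - 1), qpos[i] - 1});
      }
      if (hits.empty()) continue;
      std::sort(hits.begin(), hits.end(), [](const SeedHit& a, const SeedHit& b) {
        return a.t != b.t ? a.t < b.t : a.diag < b.diag;
      });
      struct Cl { int t, d0, d1, votes; };
      std::vector<Cl> cls;
      for (size_t i = 0; i < hits.size(); ++i) {
        if (!cls.empty() && cls.back().t == hits[i].t &&
            hits[i].diag - cls.back().d1 <= cluster_gap) {
          cls.back().d1 = hits[i].diag;
          cls.back().votes++;
        } else {
          cls.push_back({hits[i].t, hits[i].diag, hits[i].diag, 1});
        }
      }
      std::stable_sort(cls.begin(), cls.end(),
                       [](const Cl& a, const Cl& b) { return a.votes > b.votes; });
      int eval = 0;
      for (auto& c : cls) {
        if (c.votes < min_seed_hits) continue;
        if (eval >= max_clusters) break;
        ++eval;
        const std::string& T = tg[c.t];
        const int tlen = (int)T.size();
        int ws = std::max(0, c.d0 - band_pad);
        int we = std::min(tlen, c.d1 + m + band_pad);
        if (we <= ws) continue;
        bool fqs = (c.d0 - band_pad < 0);
        bool fqe = (c.d1 + m + band_pad > tlen);
        int cen = (c.d0 + c.d1) / 2 - ws;
        int B = std::max(band_min, (c.d1 - c.d0) / 2 + band_pad);
        Aln a = band_align(q, T, ws, we, cen, B, fqs, fqe);
        if (!a.ok) continue;
        int qalen = a.qe - a.qs + 1;
        if (qalen < seed_len) continue;
        if (a.edits > max_edit_frac * qalen) continue;
        uint64_t key = ((uint64_t)strand << 63) | ((uint64_t)c.t << 32) |
                       (uint64_t)a.ts;
        if (std::find(seen.begin(), seen.end(), key) != seen.end()) continue;
        seen.push_back(key);
        int qs = a.qs, qe = a.qe;
        if (strand == 1) { qs = m - a.qe + 1; qe = m - a.qs + 1; }
        o_q.push_back((int)qi + 1);
        o_t.push_back(c.t + 1);
        o_ts.push_back(a.ts);
        o_te.push_back(a.te);
        o_qs.push_back(qs);
        o_qe.push_back(qe);
        o_str.push_back(strand == 0 ? 1 : -1);
        o_ed.push_back(a.edits);
        o_mt.push_back(a.matches);
        o_al.push_back(a.alen);
        o_vt.push_back(c.votes);
      }
    }
  }
  return DataFrame::create(
      _["query"] = o_q, _["target"] = o_t, _["t_start"] = o_ts,
      _["t_end"] = o_te, _["q_start"] = o_qs, _["q_end"] = o_qe,
      _["strand"] = o_str, _["edits"] = o_ed, _["matches"] = o_mt,
      _["aln_len"] = o_al, _["votes"] = o_vt);
}

// Weighted base counts (4 x contig length, rows A,C,G,T) from alignments.
// Equal-length segments are compared column-wise; unequal segments go through
// a small full DP so indel-containing alignments still contribute matched
// columns.
// [[Rcpp::export]]
List tc_pileup(CharacterVector targets, CharacterVector queries,
               IntegerVector qi, IntegerVector ti, IntegerVector ts,
               IntegerVector te, IntegerVector qs, IntegerVector qe,
               IntegerVector strand, NumericVector w) {
  const int nt = targets.size();
  std::vector<std::string> tg(nt);
  List out(nt);
  std::vector<NumericMatrix> mats;
  for (int t = 0; t < nt; ++t) {
    tg[t] = as<std::string>(targets[t]);
    mats.emplace_back(4, (int)tg[t].size());
  }
  for (R_xlen_t a = 0; a < qi.size(); ++a) {
    std::string q = as<std::string>(queries[qi[a] - 1]);
    std::string seg = q.substr(qs[a] - 1, qe[a] - qs[a] + 1);
    if (strand[a] < 0) seg = revcomp(seg);
    const std::string& T = tg[ti[a] - 1];
    int t0 = ts[a] - 1, t1 = te[a] - 1;
    NumericMatrix& M = mats[ti[a] - 1];
    double wt = w[a];
    int tl = t1 - t0 + 1, ql = (int)seg.size();
    if (tl == ql) {
      for (int i = 0; i < tl; ++i) {
        int b = b2(seg[i]);
        if (b >= 0) M(b, t0 + i) += wt;
      }
    } else {
      // full edit-distance DP with traceback on the segment pair
      std::vector<int> D((size_t)(ql + 1) * (tl + 1));
      auto at = [&](int i, int j) -> int& { return D[(size_t)i * (tl + 1) + j]; };
      for (int i = 0; i <= ql; ++i) at(i, 0) = i;
      for (int j = 0; j <= tl; ++j) at(0, j) = j;
      for (int i = 1; i <= ql; ++i)
        for (int j = 1; j <= tl; ++j)
          at(i, j) = std::min({at(i - 1, j - 1) + (seg[i - 1] == T[t0 + j - 1] ? 0 : 1),
                               at(i - 1, j) + 1, at(i, j - 1) + 1});
      int i = ql, j = tl;
      while (i > 0 && j > 0) {
        if (at(i, j) == at(i - 1, j - 1) + (seg[i - 1] == T[t0 + j - 1] ? 0 : 1)) {
          int b = b2(seg[i - 1]);
          if (b >= 0) M(b, t0 + j - 1) += wt;
          --i; --j;
        } else if (at(i, j) == at(i - 1, j) + 1) {
          --i;
        } else {
          --j;
        }
      }
    }
  }
  for (int t = 0; t < nt; ++t) out[t] = mats[t];
  return out;
}

// Sequencing-error process: per-base deletion, substitution and insertion,
// driven by the R RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
CharacterVector tc_apply_errors(CharacterVector seqs, double sub, double ins,
                                double del) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string r;
    r.reserve(s.size() + 8);
    for (size_t j = 0; j < s.size(); ++j) {
      if (del > 0 && unif_rand() < del) {
        // deleted
      } else {
        char c = s[j];
        if (sub > 0 && unif_rand() < sub) {
          int b = b2(c);
          int nb = (int)(unif_rand() * 3);
          if (nb > 2) nb = 2;
          c = B2C[b < 0 ? nb : (nb + b + 1) % 4];
        }
        r.push_back(c);
      }
      if (ins > 0 && unif_rand() < ins) {
        int nb = (int)(unif_rand() * 4);
        if (nb > 3) nb = 3;
        r.push_back(B2C[nb]);
      }
    }
    out[i] = r;
  }
  return out;
}
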