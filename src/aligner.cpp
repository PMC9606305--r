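// Seed-chain-extend pairwise genome aligner.
//
// Anchors are exact k-mer matches (unique in both sequences for
// unique-anchor mode, all occurrences up to a cap for maxmatch mode),
// merged into maximal runs, chained per (reference contig, strand) by a
// gap-bounded dynamic program, and closed between adjacent anchors with a
// small global alignment (match +1, mismatch -1, gap -2). Chain ends are
// extended gaplessly with an X-drop rule. N bases never count as matches
// or as substitutions.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <array>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return 4; // N or other ambiguity
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
    case 'A': c = 'T'; break;
    case 'C': c = 'G'; break;
    case 'G': c = 'C'; break;
    case 'T': c = 'A'; break;
    default:  c = 'N'; break;
    }
  }
  return r;
}

struct ColCounts {
  long matches = 0;   // identical A/C/G/T columns
  long mism = 0;      // substitution columns, both sides A/C/G/T
  long cols = 0;      // all columns incl. gaps and N columns
};

// Global alignment of R[r0,r1) vs Q[q0,q1) with traceback-based column
// classification. Appends reference positions of match columns to mpos.
static void close_gap(const std::string& R, int r0, int r1,
                      const std::string& Q, int q0, int q1,
                      ColCounts& cc, std::vector<int>* mpos) {
  const int n = r1 - r0, m = q1 - q0;
  if (n <= 0 && m <= 0) return;
  if (n <= 0) { cc.cols += m; return; }
  if (m <= 0) { cc.cols += n; return; }
  if ((double)n * (double)m > 16e6) { // defensive; chaining bounds gaps
    cc.cols += n + m;
    return;
  }
  const int W = m + 1;
  std::vector<int> S((size_t)(n + 1) * W);
  std::vector<unsigned char> T((size_t)(n + 1) * W);
  for (int j = 0; j <= m; ++j) { S[j] = -2 * j; T[j] = 2; }
  for (int i = 1; i <= n; ++i) {
    S[(size_t)i * W] = -2 * i;
    T[(size_t)i * W] = 1;
    const int a = base_code(R[r0 + i - 1]);
    for (int j = 1; j <= m; ++j) {
      const int b = base_code(Q[q0 + j - 1]);
      const int sub = (a < 4 && b < 4 && a == b) ? 1 : -1;
      int best = S[(size_t)(i - 1) * W + (j - 1)] + sub;
      unsigned char tb = 0;
      const int up = S[(size_t)(i - 1) * W + j] - 2;
      if (up > best) { best = up; tb = 1; }
      const int lf = S[(size_t)i * W + (j - 1)] - 2;
      if (lf > best) { best = lf; tb = 2; }
      S[(size_t)i * W + j] = best;
      T[(size_t)i * W + j] = tb;
    }
  }
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char tb = T[(size_t)i * W + j];
    cc.cols += 1;
    if (tb == 0) {
      const int a = base_code(R[r0 + i - 1]);
      const int b = base_code(Q[q0 + j - 1]);
      if (a < 4 && b < 4) {
        if (a == b) {
          cc.matches += 1;
          if (mpos) mpos->push_back(r0 + i - 1);
        } else {
          cc.mism += 1;
        }
      }
      --i; --j;
    } else if (tb == 1) {
      --i;
    } else {
      --j;
    }
  }
}

// Gapless X-drop extension from (rpos, qpos) in direction dir (+1/-1).
// Returns number of columns taken; counts and match positions appended.
static int extend_gapless(const std::string& R, const std::string& Q,
                          int rpos, int qpos, int dir, int max_ext,
                          int xdrop, ColCounts& cc, std::vector<int>* mpos) {
  const int rl = (int)R.size(), ql = (int)Q.size();
  int best = 0, best_t = -1, score = 0;
  for (int t = 0; t < max_ext; ++t) {
    const int i = rpos + dir * t, j = qpos + dir * t;
    if (i < 0 || j < 0 || i >= rl || j >= ql) break;
    const int a = base_code(R[i]), b = base_code(Q[j]);
    score += (a < 4 && b < 4 && a == b) ? 1 : -1;
    if (score > best) { best = score; best_t = t; }
    if (score <= best - xdrop) break;
  }
  if (best_t < 0 || best <= 0) return 0;
  for (int t = 0; t <= best_t; ++t) {
    const int i = rpos + dir * t, j = qpos + dir * t;
    const int a = base_code(R[i]), b = base_code(Q[j]);
    cc.cols += 1;
    if (a < 4 && b < 4) {
      if (a == b) {
        cc.matches += 1;
        if (mpos) mpos->push_back(i);
      } else {
        cc.mism += 1;
      }
    }
  }
  return best_t + 1;
}

struct Anchor { int r, q, len; };

// [[Rcpp::export]]
List align_sets_cpp(CharacterVector ref_names, CharacterVector ref_seqs,
                    CharacterVector qry_names, CharacterVector qry_seqs,
                    int k, bool unique_mode, int max_occ, int max_gap,
                    int min_chain, bool keep_match_pos) {
  const int nref = ref_seqs.size(), nqry = qry_seqs.size();
  std::vector<std::string> refs(nref);
  for (int i = 0; i < nref; ++i) refs[i] = as<std::string>(ref_seqs[i]);

  const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;

  // sorted k-mer index over all reference contigs:
  // (value, contig<<32 | pos), binary-searched at query time
  std::vector<std::pair<uint64_t, uint64_t>> idx;
  {
    size_t cap = 0;
    for (int r = 0; r < nref; ++r) cap += refs[r].size();
    idx.reserve(cap);
    for (int r = 0; r < nref; ++r) {
      const std::string& s = refs[r];
      uint64_t val = 0; int run = 0;
      for (size_t p = 0; p < s.size(); ++p) {
        const int c = base_code(s[p]);
        if (c >= 4) { run = 0; val = 0; continue; }
        val = ((val << 2) | (uint64_t)c) & mask;
        if (++run >= k) {
          idx.emplace_back(val,
                           ((uint64_t)r << 32) | (uint64_t)(p - k + 1));
        }
      }
    }
    std::sort(idx.begin(), idx.end());
  }

  // output rows
  std::vector<std::string> o_ref, o_qry, o_strand;
  std::vector<int> o_rs, o_re, o_qs, o_qe;
  std::vector<double> o_match, o_mism, o_cols;
  std::vector<std::vector<int>> mpos_store;

  for (int qi = 0; qi < nqry; ++qi) {
    const std::string qfwd = as<std::string>(qry_seqs[qi]);
    const int qlen = (int)qfwd.size();
    for (int si = 0; si < 2; ++si) {
      const char strand = (si == 0) ? '+' : '-';
      const std::string qs = (si == 0) ? qfwd : revcomp(qfwd);

      // sorted (value, qpos) list merged against the reference index
      std::vector<std::pair<uint64_t, uint32_t>> qv;
      {
        qv.reserve(qs.size());
        uint64_t val = 0; int run = 0;
        for (size_t p = 0; p < qs.size(); ++p) {
          const int c = base_code(qs[p]);
          if (c >= 4) { run = 0; val = 0; continue; }
          val = ((val << 2) | (uint64_t)c) & mask;
          if (++run >= k) qv.emplace_back(val, (uint32_t)(p - k + 1));
        }
        std::sort(qv.begin(), qv.end());
      }

      std::vector<std::vector<std::array<int, 2>>> hits(nref);
      {
        size_t qi2 = 0, ri = 0;
        const size_t nq = qv.size(), nr = idx.size();
        while (qi2 < nq && ri < nr) {
          const uint64_t qval = qv[qi2].first, rval = idx[ri].first;
          if (qval < rval) { ++qi2; continue; }
          if (rval < qval) { ++ri; continue; }
          size_t qe = qi2, re = ri;
          while (qe < nq && qv[qe].first == qval) ++qe;
          while (re < nr && idx[re].first == qval) ++re;
          const long qn = qe - qi2, rn = re - ri;
          const bool take = unique_mode ? (qn == 1 && rn == 1)
                                        : (rn <= max_occ && qn <= max_occ);
          if (take) {
            for (size_t q2 = qi2; q2 < qe; ++q2) {
              for (size_t r2 = ri; r2 < re; ++r2) {
                const uint64_t e = idx[r2].second;
                hits[(int)(e >> 32)].push_back(
                  {(int)(e & 0xffffffffULL), (int)qv[q2].second});
              }
            }
          }
          qi2 = qe; ri = re;
        }
      }

      for (int r = 0; r < nref; ++r) {
        auto& hv = hits[r];
        if (hv.empty()) continue;
        const std::string& R = refs[r];

        // merge collinear contiguous hits into maximal anchors
        std::sort(hv.begin(), hv.end(),
                  [](const std::array<int, 2>& a, const std::array<int, 2>& b) {
                    const long da = (long)a[0] - a[1], db = (long)b[0] - b[1];
                    if (da != db) return da < db;
                    return a[0] < b[0];
                  });
        std::vector<Anchor> an;
        for (size_t h = 0; h < hv.size(); ++h) {
          const long d = (long)hv[h][0] - hv[h][1];
          if (!an.empty()) {
            Anchor& last = an.back();
            if ((long)last.r - last.q == d &&
                hv[h][0] == last.r + last.len - k + 1) {
              last.len += 1;
              continue;
            }
          }
          an.push_back({hv[h][0], hv[h][1], k});
        }

        // chain DP, limited lookback
        std::sort(an.begin(), an.end(), [](const Anchor& a, const Anchor& b) {
          if (a.r != b.r) return a.r < b.r;
          return a.q < b.q;
        });
        const int na = (int)an.size();
        std::vector<double> score(na);
        std::vector<int> parent(na, -1);
        const int lookback = 64;
        for (int i = 0; i < na; ++i) {
          score[i] = an[i].len;
          for (int j = i - 1; j >= 0 && j >= i - lookback; --j) {
            const int gr = an[i].r - (an[j].r + an[j].len);
            const int gq = an[i].q - (an[j].q + an[j].len);
            if (gr < -(k - 1) || gq < -(k - 1)) continue;
            if (gr > max_gap || gq > max_gap) continue;
            const int t = std::max(0, std::max(-gr, -gq));
            if (an[i].len - t <= 0) continue;
            const double cost =
              0.01 * std::min(std::max(gr, 0), std::max(gq, 0)) +
              0.5 * std::abs(gr - gq);
            const double cand = score[j] + (an[i].len - t) - cost;
            if (cand > score[i]) { score[i] = cand; parent[i] = j; }
          }
        }

        // extract chains best-first
        std::vector<int> order(na);
        for (int i = 0; i < na; ++i) order[i] = i;
        std::sort(order.begin(), order.end(),
                  [&](int a, int b) { return score[a] > score[b]; });
        std::vector<char> used(na, 0);
        for (const int end : order) {
          if (used[end]) continue;
          std::vector<int> chain;
          int cur = end;
          double base = 0.0;
          while (cur >= 0 && !used[cur]) {
            chain.push_back(cur);
            used[cur] = 1;
            const int par = parent[cur];
            if (par >= 0 && used[par]) { base = score[par]; break; }
            cur = par;
          }
          if (score[end] - base < min_chain) continue;
          std::reverse(chain.begin(), chain.end());

          // build block
          ColCounts cc;
          std::vector<int> mp;
          std::vector<int>* mpp = keep_match_pos ? &mp : nullptr;
          int r0 = an[chain[0]].r, q0 = an[chain[0]].q;
          int cr = r0, cq = q0;
          bool first = true;
          for (const int ci : chain) {
            Anchor a = an[ci];
            if (!first) {
              const int t = std::max(0, std::max(cr - a.r, cq - a.q));
              a.r += t; a.q += t; a.len -= t;
              if (a.len <= 0) continue;
              if (a.r > cr || a.q > cq)
                close_gap(R, cr, a.r, qs, cq, a.q, cc, mpp);
            }
            cc.matches += a.len;
            cc.cols += a.len;
            if (mpp) for (int p = a.r; p < a.r + a.len; ++p) mpp->push_back(p);
            cr = a.r + a.len;
            cq = a.q + a.len;
            first = false;
          }
          const int back =
            extend_gapless(R, qs, r0 - 1, q0 - 1, -1, 2000, 20, cc, mpp);
          r0 -= back; q0 -= back;
          const int fwd =
            extend_gapless(R, qs, cr, cq, +1, 2000, 20, cc, mpp);
          cr += fwd; cq += fwd;

          int bqs = q0, bqe = cq;
          if (strand == '-') { bqs = qlen - cq; bqe = qlen - q0; }
          o_ref.push_back(as<std::string>(ref_names[r]));
          o_qry.push_back(as<std::string>(qry_names[qi]));
          o_strand.push_back(std::string(1, strand));
          o_rs.push_back(r0); o_re.push_back(cr);
          o_qs.push_back(bqs); o_qe.push_back(bqe);
          o_match.push_back((double)cc.matches);
          o_mism.push_back((double)cc.mism);
          o_cols.push_back((double)cc.cols);
          if (keep_match_pos) {
            std::sort(mp.begin(), mp.end());
            mp.erase(std::unique(mp.begin(), mp.end()), mp.end());
            mpos_store.push_back(std::move(mp));
          }
        }
      }
    }
  }

  List out = List::create(
    _["ref_contig"] = wrap(o_ref), _["qry_contig"] = wrap(o_qry),
    _["ref_start"] = wrap(o_rs), _["ref_end"] = wrap(o_re),
    _["qry_start"] = wrap(o_qs), _["qry_end"] = wrap(o_qe),
    _["strand"] = wrap(o_strand), _["matches"] = wrap(o_match),
    _["mismatches"] = wrap(o_mism), _["aligned_length"] = wrap(o_cols));
  if (keep_match_pos) {
    List ml(mpos_store.size());
    for (size_t i = 0; i < mpos_store.size(); ++i) {
      ml[i] = IntegerVector(mpos_store[i].begin(), mpos_store[i].end());
    }
    out["match_pos"] = ml;
  }
  return out;
}
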