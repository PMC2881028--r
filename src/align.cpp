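#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Nucleotide local alignment with affine gaps (Gotoh recursion).
// A gap of length g costs gap_open + g * gap_extend. 'N' (or any
// non-ACGT character) never matches anything, including itself.

static const double NEG_INF = -1e18;

struct AlnParams {
  double match, mismatch, gap_open, gap_extend;
};

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

static inline double pair_score(int a, int b, const AlnParams& p) {
  if (a > 3 || b > 3) return p.mismatch;
  return (a == b) ? p.match : p.mismatch;
}

struct BestCell {
  double score;
  int qi, sj; // 1-based end coordinates; 0 when no positive-scoring cell
};

// Forward score-only pass of local affine DP. Columns j with mask[j-1]
// set are excluded from any alignment. Returns the best cell.
static BestCell sw_best(const std::vector<int>& q, const std::vector<int>& s,
                        const AlnParams& p, const std::vector<char>* mask) {
  const int m = (int)q.size(), n = (int)s.size();
  std::vector<double> H(n + 1, 0.0);       // H[i][j], rolling by row
  std::vector<double> F(n + 1, NEG_INF);   // vertical gap state per column
  BestCell best = {0.0, 0, 0};
  const double go = p.gap_open + p.gap_extend;
  for (int i = 1; i <= m; ++i) {
    double Hdiag = H[0]; // H[i-1][0] == 0
    H[0] = 0.0;
    double Erow = NEG_INF; // E[i][j]: gap in query (horizontal)
    for (int j = 1; j <= n; ++j) {
      const bool masked = mask && (*mask)[j - 1];
      double Hup = H[j]; // H[i-1][j]
      double h;
      if (masked) {
        h = NEG_INF;
        Erow = NEG_INF;
        F[j] = NEG_INF;
      } else {
        Erow = std::max(H[j - 1] - go, Erow - p.gap_extend);
        F[j] = std::max(Hup - go, F[j] - p.gap_extend);
        h = Hdiag + pair_score(q[i - 1], s[j - 1], p);
        h = std::max(h, Erow);
        h = std::max(h, F[j]);
        h = std::max(h, 0.0);
      }
      Hdiag = Hup;
      H[j] = masked ? 0.0 : h;
      if (!masked && h > best.score) {
        best.score = h;
        best.qi = i;
        best.sj = j;
      }
    }
  }
  return best;
}

struct Hit {
  double score;
  int qs, qe, ss, se; // 1-based inclusive
};

// Locate the start of an optimal local alignment ending at (qi, sj) by
// running the same DP on the reversed prefixes.
static Hit sw_locate(const std::vector<int>& q, const std::vector<int>& s,
                     const AlnParams& p, const BestCell& best,
                     const std::vector<char>* mask) {
  Hit h;
  h.score = best.score;
  h.qe = best.qi;
  h.se = best.sj;
  std::vector<int> qr(q.begin(), q.begin() + best.qi);
  std::vector<int> sr(s.begin(), s.begin() + best.sj);
  std::reverse(qr.begin(), qr.end());
  std::reverse(sr.begin(), sr.end());
  std::vector<char> mr;
  const std::vector<char>* mrp = NULL;
  if (mask) {
    mr.assign(mask->begin(), mask->begin() + best.sj);
    std::reverse(mr.begin(), mr.end());
    mrp = &mr;
  }
  BestCell b2 = sw_best(qr, sr, p, mrp);
  h.qs = best.qi - b2.qi + 1;
  h.ss = best.sj - b2.sj + 1;
  return h;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
DataFrame sw_align_cpp(std::string query, std::string subject,
                       double match, double mismatch,
                       double gap_open, double gap_extend,
                       double min_score, int max_hits) {
  AlnParams p = {match, mismatch, gap_open, gap_extend};
  std::vector<int> q = encode(query), s = encode(subject);
  std::vector<char> mask(s.size(), 0);
  std::vector<double> scores;
  std::vector<int> qs, qe, ss, se;
  for (int k = 0; k < max_hits; ++k) {
    BestCell best = sw_best(q, s, p, &mask);
    if (best.score < min_score || best.qi == 0) break;
    Hit h = sw_locate(q, s, p, best, &mask);
    scores.push_back(h.score);
    qs.push_back(h.qs);
    qe.push_back(h.qe);
    ss.push_back(h.ss);
    se.push_back(h.se);
    for (int j = h.ss - 1; j < h.se; ++j) mask[j] = 1;
  }
  return DataFrame::create(_["score"] = scores,
                           _["q_start"] = qs, _["q_end"] = qe,
                           _["s_start"] = ss, _["s_end"] = se);
}

// ---- seed-and-extend over an indexed subject set ----

// [[Rcpp::export(name = ".seed_extend_cpp")]]
DataFrame seed_extend_cpp(CharacterVector queries, CharacterVector subjects,
                          double match, double mismatch,
                          double gap_open, double gap_extend,
                          int word_size, double min_score, int pad) {
  AlnParams p = {match, mismatch, gap_open, gap_extend};
  const int nsub = subjects.size();
  std::vector<std::vector<int> > subs(nsub);
  for (int i = 0; i < nsub; ++i) subs[i] = encode(std::string(subjects[i]));

  // k-mer index: packed 2-bit word -> list of (subject, position)
  typedef std::pair<int, int> Loc;
  std::unordered_map<uint64_t, std::vector<Loc> > index;
  const uint64_t kmask = (word_size >= 32) ? ~0ULL
    : ((1ULL << (2 * word_size)) - 1);
  for (int si = 0; si < nsub; ++si) {
    const std::vector<int>& s = subs[si];
    uint64_t w = 0;
    int run = 0;
    for (size_t j = 0; j < s.size(); ++j) {
      if (s[j] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)s[j]) & kmask;
      if (++run >= word_size)
        index[w].push_back(Loc(si, (int)j - word_size + 1)); // 0-based start
    }
  }

  std::vector<int> out_q, out_s, out_qs, out_qe, out_ss, out_se;
  std::vector<double> out_score;

  for (int qi = 0; qi < queries.size(); ++qi) {
    std::string qstr = as<std::string>(queries[qi]);
    std::vector<int> q = encode(qstr);
    const int qlen = (int)q.size();
    if (qlen < word_size) continue;
    // accepted subject intervals per subject (to skip redundant seeds)
    std::unordered_map<int, std::vector<std::pair<int, int> > > accepted;
    std::unordered_set<uint64_t> tried; // (subject, diag bucket, locus bucket)
    uint64_t w = 0;
    int run = 0;
    for (int i = 0; i < qlen; ++i) {
      if (q[i] > 3) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)q[i]) & kmask;
      if (++run < word_size) continue;
      const int qpos = i - word_size + 1; // 0-based
      std::unordered_map<uint64_t, std::vector<Loc> >::const_iterator it =
        index.find(w);
      if (it == index.end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        const int si = it->second[h].first;
        const int spos = it->second[h].second;
        // skip seeds inside an already accepted alignment on this subject
        bool covered = false;
        std::vector<std::pair<int, int> >& acc = accepted[si];
        for (size_t a = 0; a < acc.size(); ++a)
          if (spos >= acc[a].first && spos + word_size - 1 <= acc[a].second) {
            covered = true;
            break;
          }
        if (covered) continue;
        const int diag = spos - qpos;
        uint64_t key = ((uint64_t)(uint32_t)si << 40) ^
          ((uint64_t)(uint32_t)((diag + (1 << 24)) / word_size) << 16) ^
          (uint64_t)(uint32_t)(spos / 2048);
        if (!tried.insert(key).second) continue;
        // extension window on the subject
        const std::vector<int>& s = subs[si];
        int ws = spos - qlen - pad;
        if (ws < 0) ws = 0;
        int we = spos + word_size - 1 + qlen + pad;
        if (we > (int)s.size() - 1) we = (int)s.size() - 1;
        std::vector<int> win(s.begin() + ws, s.begin() + we + 1);
        BestCell best = sw_best(q, win, p, NULL);
        if (best.score < min_score || best.qi == 0) continue;
        Hit hit = sw_locate(q, win, p, best, NULL);
        int abs_ss = ws + hit.ss;      // 1-based
        int abs_se = ws + hit.se;
        // dedupe identical hits reached from different seeds
        bool dup = false;
        for (size_t a = 0; a < acc.size(); ++a)
          if (acc[a].first == abs_ss - 1 && acc[a].second == abs_se - 1) {
            dup = true;
            break;
          }
        if (dup) continue;
        acc.push_back(std::make_pair(abs_ss - 1, abs_se - 1));
        out_q.push_back(qi + 1);
        out_s.push_back(si + 1);
        out_score.push_back(hit.score);
        out_qs.push_back(hit.qs);
        out_qe.push_back(hit.qe);
        out_ss.push_back(abs_ss);
        out_se.push_back(abs_se);
      }
    }
  }
  return DataFrame::create(_["query"] = out_q, _["subject"] = out_s,
                           _["score"] = out_score,
                           _["q_start"] = out_qs, _["q_end"] = out_qe,
                           _["s_start"] = out_ss, _["s_end"] = out_se);
}
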