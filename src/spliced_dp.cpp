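// Two-state spliced alignment of a cDNA against genomic sequence under the
// GT-AG splice-site rule.
//
// State E[i][j]: best score of an alignment of cdna[1..j] against a suffix of
// genomic[1..i] that currently sits in exon state (fitting alignment: the
// genomic prefix before the gene is free, E[i][0] = 0).
// An intron is a genomic jump from a donor d (genomic[d..d+1] == "GT") to an
// acceptor a (genomic[a-1..a] == "AG"), d <= a, with
// min_intron <= a - d + 1 <= max_intron, costing a flat intron_penalty and
// consuming no cDNA. The jump is implemented as a sliding-window maximum over
// donor candidates per cDNA column (monotone deque), so the whole DP is
// O(n * m) time and O(n * m) int32 memory for the score matrix, which the
// traceback re-reads.

#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <vector>

using namespace Rcpp;

static const int NEG = INT32_MIN / 4;

struct Donor {
  int d;
  int val;
};

// [[Rcpp::export(name = ".spliced_dp")]]
List spliced_dp(std::string genomic, std::string cdna, int match, int mismatch,
                int gap, int intron_penalty, int min_intron, int max_intron) {
  const int n = (int)genomic.size();
  const int m = (int)cdna.size();
  if (n < 1 || m < 1) stop("empty sequence");
  const double cells = (double)(n + 1) * (double)(m + 1);
  if (cells * 4.0 > 3.5e9) stop("DP matrix too large; use anchored mode");

  std::vector<int32_t> E((size_t)(n + 1) * (m + 1));
  auto idx = [n](int i, int j) { return (size_t)j * (n + 1) + i; };
  // 1-based sequence accessors
  auto gb = [&genomic](int i) { return genomic[i - 1]; };
  auto cb = [&cdna](int j) { return cdna[j - 1]; };
  auto sc = [&](int i, int j) {
    char a = gb(i), b = cb(j);
    if (a == 'N' || b == 'N') return mismatch;
    return a == b ? match : mismatch;
  };

  for (int i = 0; i <= n; ++i) E[idx(i, 0)] = 0;
  for (int j = 1; j <= m; ++j) E[idx(0, j)] = (int32_t)j * gap;

  std::deque<Donor> dq;
  for (int j = 1; j <= m; ++j) {
    dq.clear();
    for (int i = 1; i <= n; ++i) {
      int d = i - min_intron + 1;
      if (d >= 1 && d + 1 <= n && gb(d) == 'G' && gb(d + 1) == 'T') {
        int val = E[idx(d - 1, j)];
        // strict comparison keeps the leftmost donor among equals at front
        while (!dq.empty() && dq.back().val < val) dq.pop_back();
        dq.push_back({d, val});
      }
      while (!dq.empty() && dq.front().d < i - max_intron + 1) dq.pop_front();

      int best = E[idx(i - 1, j - 1)] + sc(i, j);
      int cand = E[idx(i - 1, j)] + gap;
      if (cand > best) best = cand;
      cand = E[idx(i, j - 1)] + gap;
      if (cand > best) best = cand;
      if (i >= 2 && gb(i - 1) == 'A' && gb(i) == 'G' && !dq.empty()) {
        cand = dq.front().val + intron_penalty;
        if (cand > best) best = cand;
      }
      E[idx(i, j)] = best;
    }
  }

  // fitting end: best score over genomic end positions, leftmost on ties
  int best_i = 0;
  int32_t best_score = E[idx(0, m)];
  for (int i = 1; i <= n; ++i) {
    if (E[idx(i, m)] > best_score) {
      best_score = E[idx(i, m)];
      best_i = i;
    }
  }

  // traceback; move priority: diagonal, genomic gap, cDNA gap, intron close
  // (leftmost donor) -- exon moves before intron moves
  std::vector<int> ex_gs, ex_ge, ex_cs, ex_ce, in_gs, in_ge;
  int i = best_i, j = m;
  int mismatches = 0, gaps = 0;
  int cur_ge = -1, cur_ce = -1;  // open exon run (genomic/cDNA ends)
  auto close_run = [&](int gs, int cs) {
    if (cur_ge >= 0) {
      ex_gs.push_back(gs);
      ex_ge.push_back(cur_ge);
      ex_cs.push_back(cs);
      ex_ce.push_back(cur_ce);
      cur_ge = -1;
      cur_ce = -1;
    }
  };
  while (j > 0) {
    int32_t cur = E[idx(i, j)];
    if (i >= 1 && cur == E[idx(i - 1, j - 1)] + sc(i, j)) {
      if (cur_ge < 0) {
        cur_ge = i;
        cur_ce = j;
      }
      if (sc(i, j) != match) ++mismatches;
      --i;
      --j;
    } else if (i >= 1 && cur == E[idx(i - 1, j)] + gap) {
      if (cur_ge < 0) {
        cur_ge = i;
        cur_ce = j;  // genomic base aligned to a cDNA gap
      }
      ++gaps;
      --i;
    } else if (cur == E[idx(i, j - 1)] + gap) {
      ++gaps;
      --j;
    } else if (i >= 2 && gb(i - 1) == 'A' && gb(i) == 'G') {
      int lo = i - max_intron + 1;
      if (lo < 1) lo = 1;
      int hi = i - min_intron + 1;
      bool found = false;
      for (int d = lo; d <= hi; ++d) {
        if (gb(d) == 'G' && gb(d + 1) == 'T' &&
            cur == E[idx(d - 1, j)] + intron_penalty) {
          close_run(i + 1, j + 1);
          in_gs.push_back(d);
          in_ge.push_back(i);
          i = d - 1;
          found = true;
          break;
        }
      }
      if (!found) stop("internal error: spliced DP traceback failed");
    } else {
      stop("internal error: spliced DP traceback failed");
    }
  }
  close_run(i + 1, j + 1);

  // runs were collected right-to-left; reverse into left-to-right order
  std::reverse(ex_gs.begin(), ex_gs.end());
  std::reverse(ex_ge.begin(), ex_ge.end());
  std::reverse(ex_cs.begin(), ex_cs.end());
  std::reverse(ex_ce.begin(), ex_ce.end());
  std::reverse(in_gs.begin(), in_gs.end());
  std::reverse(in_ge.begin(), in_ge.end());

  return List::create(
      Named("score") = (int)best_score, Named("end") = best_i,
      Named("exon_gstart") = wrap(ex_gs), Named("exon_gend") = wrap(ex_ge),
      Named("exon_cstart") = wrap(ex_cs), Named("exon_cend") = wrap(ex_ce),
      Named("intron_start") = wrap(in_gs), Named("intron_end") = wrap(in_ge),
      Named("mismatches") = mismatches, Named("gaps") = gaps);
}
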