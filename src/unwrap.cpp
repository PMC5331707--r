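#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Quality-guided region-growing 2D phase unwrapping.
//
// Pixels are visited in descending quality order starting from a seed; each
// newly visited pixel is shifted by the integer multiple of 2*pi that brings
// it within pi of the mean of its already-unwrapped 4-neighbors. On fields
// whose true inter-pixel phase steps stay below pi this recovers the
// underlying phase up to a single global 2*pi constant (the seed keeps its
// wrapped value). Mask pixels not 4-connected to the seed are left NA.

struct Cand {
  double q;
  int idx;
  long order; // FIFO tie-break for equal quality -> deterministic
};
struct CandLess {
  bool operator()(const Cand& a, const Cand& b) const {
    if (a.q != b.q) return a.q < b.q;
    return a.order > b.order;
  }
};

// [[Rcpp::export(name = ".unwrap_region_grow")]]
List unwrap_region_grow(NumericMatrix wrapped, LogicalMatrix mask,
                        NumericMatrix quality, int seed_row, int seed_col) {
  const int nr = wrapped.nrow(), nc = wrapped.ncol();
  const double TWO_PI = 2.0 * M_PI;
  if (seed_row < 0 || seed_row >= nr || seed_col < 0 || seed_col >= nc)
    stop("seed point outside image");
  if (!mask(seed_row, seed_col)) stop("seed point outside mask");

  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  LogicalMatrix visited(nr, nc);
  std::vector<bool> queued((size_t)nr * nc, false);

  std::priority_queue<Cand, std::vector<Cand>, CandLess> pq;
  long order = 0;
  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  int sidx = seed_col * nr + seed_row;
  out(seed_row, seed_col) = wrapped(seed_row, seed_col);
  visited(seed_row, seed_col) = true;

  auto push_neighbors = [&](int r, int c) {
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], cc = c + dc[d];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || visited(rr, cc)) continue;
      int idx = cc * nr + rr;
      if (queued[idx]) continue;
      queued[idx] = true;
      pq.push(Cand{quality(rr, cc), idx, order++});
    }
  };
  push_neighbors(seed_row, seed_col);
  (void)sidx;

  while (!pq.empty()) {
    Cand c = pq.top();
    pq.pop();
    int cc = c.idx / nr, r = c.idx % nr;
    if (visited(r, cc)) continue;
    // mean of unwrapped 4-neighbors
    double s = 0.0;
    int n = 0;
    for (int d = 0; d < 4; ++d) {
      int rr = r + dr[d], c2 = cc + dc[d];
      if (rr < 0 || rr >= nr || c2 < 0 || c2 >= nc) continue;
      if (visited(rr, c2)) {
        s += out(rr, c2);
        ++n;
      }
    }
    double ref = s / n; // n >= 1: candidates only enter via a visited neighbor
    double w = wrapped(r, cc);
    double m = std::round((ref - w) / TWO_PI);
    out(r, cc) = w + TWO_PI * m;
    visited(r, cc) = true;
    push_neighbors(r, cc);
  }

  return List::create(_["unwrapped"] = out, _["visited"] = visited);
}
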