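#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Expanding-ring scan over an occupancy grid for the k nearest occupied
// cells around a 0-based (row, col) origin.
//
// Shells are Chebyshev rings scanned row-major (rows ascending, columns
// ascending within a row); within the growing candidate set, ties in
// Euclidean distance resolve to the earliest cell in scan order.  A cell
// in shell r has Euclidean distance >= r from the origin, so once k
// candidates (counted with multiplicity) are known the scan can stop as
// soon as r reaches the current k-th best distance.  nob bounds the
// Euclidean search radius; pass R_PosInf for an unbounded search.
//
// Returns a list with an m x 2 integer matrix of 0-based (row, col)
// cells (multiplicity expanded, m <= k) and their distances.
// [[Rcpp::export]]
List cpp_nearest_cells(const IntegerMatrix& grid, int orow, int ocol,
                       int k, double nob) {
  const int nr = grid.nrow(), nc = grid.ncol();
  if (orow < 0 || orow >= nr || ocol < 0 || ocol >= nc)
    stop("origin outside grid");
  if (k < 1) stop("k must be >= 1");

  struct Cand { double d; int row, col, count; };
  std::vector<Cand> cand;
  long long found = 0;  // multiplicity-weighted candidate count

  const int rmax_grid = std::max(std::max(orow, nr - 1 - orow),
                                 std::max(ocol, nc - 1 - ocol));
  int rlimit = rmax_grid;
  if (R_finite(nob)) rlimit = std::min(rlimit, (int)std::floor(nob));

  // current k-th smallest distance among candidates (with multiplicity)
  auto kth_dist = [&]() -> double {
    if (found < k) return R_PosInf;
    long long acc = 0;
    // cand is kept sorted by (d, scan order)
    for (const Cand& c : cand) {
      acc += c.count;
      if (acc >= k) return c.d;
    }
    return R_PosInf;
  };

  auto visit = [&](int i, int j) {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return;
    int cnt = grid(i, j);
    if (cnt <= 0) return;
    double d = std::sqrt((double)(i - orow) * (i - orow) +
                         (double)(j - ocol) * (j - ocol));
    if (R_finite(nob) && d > nob) return;
    // insert keeping (d, scan-order) order: scan order is monotone in
    // discovery, so a stable insertion before the first strictly
    // greater distance preserves it
    Cand c{d, i, j, cnt};
    auto pos = std::upper_bound(cand.begin(), cand.end(), c,
                                [](const Cand& a, const Cand& b) {
                                  return a.d < b.d;
                                });
    cand.insert(pos, c);
    found += cnt;
  };

  for (int r = 0; r <= rlimit; ++r) {
    if (found >= k && (double)r >= kth_dist()) break;
    if (r == 0) {
      visit(orow, ocol);
      continue;
    }
    const int r0 = orow - r, r1 = orow + r;
    for (int i = r0; i <= r1; ++i) {
      if (i < 0 || i >= nr) continue;
      if (i == r0 || i == r1) {
        for (int j = ocol - r; j <= ocol + r; ++j) visit(i, j);
      } else {
        visit(i, ocol - r);
        visit(i, ocol + r);
      }
    }
  }

  // expand multiplicity up to k entries
  std::vector<int> rows, cols;
  std::vector<double> dists;
  for (const Cand& c : cand) {
    for (int m = 0; m < c.count && (int)rows.size() < k; ++m) {
      rows.push_back(c.row);
      cols.push_back(c.col);
      dists.push_back(c.d);
    }
    if ((int)rows.size() >= k) break;
  }
  const int m = rows.size();
  IntegerMatrix cells(m, 2);
  NumericVector dd(m);
  for (int i = 0; i < m; ++i) {
    cells(i, 0) = rows[i];
    cells(i, 1) = cols[i];
    dd[i] = dists[i];
  }
  return List::create(_["cells"] = cells, _["dists"] = dd);
}

// In-place occupancy update: decrement cells in `old_cells`, increment
// cells in `new_cells` (both m x 2, 0-based row/col).  The caller owns
// `grid` exclusively; mutation avoids re-allocating large grids every
// frame of a trial.
// [[Rcpp::export]]
void cpp_shift_cells(IntegerMatrix grid, const IntegerMatrix& old_cells,
                     const IntegerMatrix& new_cells) {
  const int nr = grid.nrow(), nc = grid.ncol();
  for (int i = 0; i < old_cells.nrow(); ++i) {
    int r = old_cells(i, 0), c = old_cells(i, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc) stop("cell outside grid");
    grid(r, c) -= 1;
    if (grid(r, c) < 0) stop("occupancy underflow");
  }
  for (int i = 0; i < new_cells.nrow(); ++i) {
    int r = new_cells(i, 0), c = new_cells(i, 1);
    if (r < 0 || r >= nr || c < 0 || c >= nc) stop("cell outside grid");
    grid(r, c) += 1;
  }
}
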