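#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const double BIG = 1e20;

// 1D lower-envelope distance transform (Felzenszwalb & Huttenlocher).
// Exact for integer inputs: all arithmetic stays on integers representable
// in doubles, so squared distances are exact.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

//' Exact squared Euclidean distance transform
//'
//' For every pixel, the squared Euclidean distance (in pixel units) to the
//' nearest \code{TRUE} pixel of \code{seed}. Squared distances between pixel
//' centres are integers, so the result is exact and safe to compare with
//' squared radii without tolerance.
//'
//' @param seed logical matrix of seed pixels.
//' @return numeric matrix of squared distances; \code{Inf} where \code{seed}
//'   has no \code{TRUE} pixel at all.
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix edt_sq(LogicalMatrix seed) {
  int nr = seed.nrow(), nc = seed.ncol();
  NumericMatrix out(nr, nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int j = 0; j < nc; j++) {
    for (int i = 0; i < nr; i++) f[i] = seed(i, j) ? 0.0 : BIG;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; i++) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; j++) out(i, j) = d[j] >= BIG ? R_PosInf : d[j];
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> di, dj;
  if (connectivity == 8) {
    int di8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
    int dj8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
    di.assign(di8, di8 + 8);
    dj.assign(dj8, dj8 + 8);
  } else {
    int di4[] = {-1, 0, 0, 1};
    int dj4[] = {0, -1, 1, 0};
    di.assign(di4, di4 + 4);
    dj.assign(dj4, dj4 + 4);
  }
  // row-major scan: labels are assigned in raster order of first pixel
  for (int i = 0; i < nr; i++) {
    for (int j = 0; j < nc; j++) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      next++;
      std::queue<std::pair<int, int> > q;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (size_t k = 0; k < di.size(); k++) {
          int ii = p.first + di[k], jj = p.second + dj[k];
          if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(std::make_pair(ii, jj));
          }
        }
      }
    }
  }
  return lab;
}

static inline bool inlab(const IntegerMatrix& lab, int i, int j, int id) {
  if (i < 0 || j < 0 || i >= lab.nrow() || j >= lab.ncol()) return false;
  return lab(i, j) == id;
}

// Moore-neighbour outer-contour tracing. Returns the polygonal length of the
// closed path through boundary pixel centres (steps of 1 or sqrt(2)),
// terminating when the (pixel, backtrack) state repeats its initial value.
// Isolated pixels get perimeter 4 (their unit-square outline); dominoes and
// other sub-3x3 shapes degenerate, but such specks are normally removed by
// area filters before circularity matters.
// [[Rcpp::export]]
NumericVector contour_perimeters(IntegerMatrix lab, int nlab) {
  NumericVector per(nlab);
  if (nlab == 0) return per;
  int nr = lab.nrow(), nc = lab.ncol();
  // clockwise Moore neighbourhood starting East
  const int mi[] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int mj[] = {1, 1, 0, -1, -1, -1, 0, 1};
  std::vector<int> si(nlab, -1), sj(nlab, -1);
  for (int i = 0; i < nr; i++)
    for (int j = 0; j < nc; j++) {
      int id = lab(i, j);
      if (id > 0 && si[id - 1] < 0) {
        si[id - 1] = i;
        sj[id - 1] = j;
      }
    }
  for (int id = 1; id <= nlab; id++) {
    int i0 = si[id - 1], j0 = sj[id - 1];
    if (i0 < 0) {
      per[id - 1] = NA_REAL;
      continue;
    }
    bool iso = true;
    for (int k = 0; k < 8 && iso; k++)
      if (inlab(lab, i0 + mi[k], j0 + mj[k], id)) iso = false;
    if (iso) {
      per[id - 1] = 4.0;
      continue;
    }
    // start at the first pixel in raster order; its W neighbour is outside
    // the component by construction, so it is a valid backtrack pixel
    int ci = i0, cj = j0;       // current contour pixel
    int bi = i0, bj = j0 - 1;   // backtrack (outside) pixel
    const int b0i = bi, b0j = bj;
    double len = 0.0;
    bool started = false;
    long guard = 0;
    const long maxit = 8L * (long)nr * nc + 64;
    while (guard++ < maxit) {
      if (started && ci == i0 && cj == j0 && bi == b0i && bj == b0j) break;
      started = true;
      // direction index from c to b
      int dirb = -1;
      for (int k = 0; k < 8; k++)
        if (ci + mi[k] == bi && cj + mj[k] == bj) {
          dirb = k;
          break;
        }
      int found = -1, prev = dirb;
      for (int k = 1; k <= 8; k++) {
        int d = (dirb + k) % 8;
        if (inlab(lab, ci + mi[d], cj + mj[d], id)) {
          found = d;
          break;
        }
        prev = d;
      }
      if (found < 0) break;  // cannot happen for non-isolated components
      len += (mi[found] != 0 && mj[found] != 0) ? M_SQRT2 : 1.0;
      bi = ci + mi[prev];
      bj = cj + mj[prev];
      ci += mi[found];
      cj += mj[found];
    }
    per[id - 1] = len;
  }
  return per;
}
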