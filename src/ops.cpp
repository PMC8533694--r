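#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Replicate-edge clamp
static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Square (Chebyshev) box mean filter with replicate padding.
// [[Rcpp::export]]
NumericMatrix box_mean_cpp(NumericMatrix x, int r) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  double w = (2.0 * r + 1.0) * (2.0 * r + 1.0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = clampi(j + dj, 0, nc - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = clampi(i + di, 0, nr - 1);
          s += x(ii, jj);
        }
      }
      out(i, j) = s / w;
    }
  }
  return out;
}

// Square box median filter with replicate padding. Window size is always
// odd ((2r+1)^2) so the median is the middle order statistic.
// [[Rcpp::export]]
NumericMatrix box_median_cpp(NumericMatrix x, int r) {
  int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  int side = 2 * r + 1;
  int n = side * side;
  std::vector<double> buf(n);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int k = 0;
      for (int dj = -r; dj <= r; ++dj) {
        int jj = clampi(j + dj, 0, nc - 1);
        for (int di = -r; di <= r; ++di) {
          int ii = clampi(i + di, 0, nr - 1);
          buf[k++] = x(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      out(i, j) = buf[n / 2];
    }
  }
  return out;
}

// Connected-component labeling of a logical mask, 4- or 8-adjacency.
// Labels are assigned 1..N in raster (column-major) order of first pixel.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix m, int connectivity) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<int> stack;
  const int d4i[4] = {-1, 1, 0, 0};
  const int d4j[4] = {0, 0, -1, 1};
  const int d8i[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int d8j[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int *di = connectivity == 4 ? d4i : d8i;
  const int *dj = connectivity == 4 ? d4j : d8j;
  int nd = connectivity == 4 ? 4 : 8;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int k = 0; k < nd; ++k) {
          int qi = pi + di[k], qj = pj + dj[k];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (m(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Chain-code perimeter of each labeled component (labels 1..n_labels),
// in pixel units: Moore boundary tracing of the outer contour, straight
// steps counted 1, diagonal steps sqrt(2). Single-pixel components get
// the unit-square outline length 4.
// [[Rcpp::export]]
NumericVector perimeter_cpp(IntegerMatrix lab, int n_labels) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(n_labels);
  // first pixel of each label in column-major scan = a boundary pixel
  std::vector<int> start_i(n_labels, -1), start_j(n_labels, -1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = lab(i, j);
      if (l > 0 && start_i[l - 1] < 0) { start_i[l - 1] = i; start_j[l - 1] = j; }
    }
  // Moore neighbourhood in clockwise order starting from W when the image
  // is viewed with rows increasing downward: W, NW, N, NE, E, SE, S, SW
  const int mi[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int mj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const double slen[8] = {1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2, 1.0, M_SQRT2};
  for (int l = 0; l < n_labels; ++l) {
    int si = start_i[l], sj = start_j[l];
    if (si < 0) { per[l] = NA_REAL; continue; }
    // isolated pixel?
    bool alone = true;
    for (int k = 0; k < 8 && alone; ++k) {
      int qi = si + mi[k], qj = sj + mj[k];
      if (qi >= 0 && qi < nr && qj >= 0 && qj < nc && lab(qi, qj) == l + 1)
        alone = false;
    }
    if (alone) { per[l] = 4.0; continue; }
    // Moore tracing; backtrack starts at N of start (previous pixel in the
    // column-major scan, guaranteed background or out of bounds)
    double p = 0.0;
    int ci = si, cj = sj;
    int bdir = 2; // direction from current to backtrack pixel: N
    int first_next_i = -1, first_next_j = -1;
    long guard = 0, maxit = 8L * (long)nr * (long)nc + 64;
    while (true) {
      if (++guard > maxit) { per[l] = NA_REAL; break; }
      // scan clockwise starting just after the backtrack direction
      int found = -1;
      for (int s = 1; s <= 8; ++s) {
        int k = (bdir + s) % 8;
        int qi = ci + mi[k], qj = cj + mj[k];
        if (qi >= 0 && qi < nr && qj >= 0 && qj < nc && lab(qi, qj) == l + 1) {
          found = k;
          break;
        }
      }
      if (found < 0) break; // cannot happen for non-isolated pixels
      int ni = ci + mi[found], nj = cj + mj[found];
      // Jacob's stopping criterion: back at start, about to repeat the
      // first move
      if (ci == si && cj == sj && first_next_i >= 0 &&
          ni == first_next_i && nj == first_next_j && guard > 1)
        break;
      if (first_next_i < 0) { first_next_i = ni; first_next_j = nj; }
      p += slen[found];
      // new backtrack direction: from the new pixel towards the old one
      bdir = (found + 4) % 8;
      ci = ni; cj = nj;
    }
    if (!NumericVector::is_na(per[l])) per[l] = p;
  }
  return per;
}
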