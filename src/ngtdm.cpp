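#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

// Accumulated gray-tone difference table: s(i) and occurrence counts,
// indexed by bin - 1. n is the number of pixels that entered the matrix.
struct Table {
  std::vector<double> s;
  std::vector<int> cnt;
  int n = 0;

  void reset() {
    std::fill(s.begin(), s.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    n = 0;
  }
};

// Accumulate the NGTDM over a 2-D patch stored column-major (nr x nc).
// valid[k] == 0 marks padding cells (outside the image); their bin values
// are never read. strict == true restricts to pixels whose full (2d+1)^2
// neighborhood lies inside the valid region; otherwise any pixel with at
// least one valid neighbor is eligible.
void accumulate(const int* bins, const char* valid, int nr, int nc,
                int d, bool strict, Table& t) {
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid[r + c * nr]) continue;
      double sum = 0.0;
      int nn = 0;
      bool full = true;
      for (int dc = -d; dc <= d; ++dc) {
        for (int dr = -d; dr <= d; ++dr) {
          if (dr == 0 && dc == 0) continue;
          int rr = r + dr, cc = c + dc;
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc || !valid[rr + cc * nr]) {
            full = false;
            continue;
          }
          sum += bins[rr + cc * nr];
          ++nn;
        }
      }
      if (strict ? !full : nn == 0) continue;
      int i = bins[r + c * nr];
      if (i < 1) stop("bin indices must be positive integers");
      if ((int)t.s.size() < i) {
        t.s.resize(i, 0.0);
        t.cnt.resize(i, 0);
      }
      double A = sum / nn;
      t.s[i - 1] += std::fabs((double)i - A);
      t.cnt[i - 1] += 1;
      ++t.n;
    }
  }
}

// coarseness, contrast, busyness from an accumulated table.
// Conventions: contrast = 0 when a single gray level is present;
// busyness = 0 when its denominator vanishes (textureless limit).
void features_from(const Table& t, double eps, double* out) {
  const int B = (int)t.s.size();
  const double n = (double)t.n;
  double ps = 0.0, stot = 0.0, m1 = 0.0, m2 = 0.0;
  int ng = 0;
  std::vector<double> ip;  // i * p(i) for levels present
  ip.reserve(B);
  for (int k = 0; k < B; ++k) {
    if (t.cnt[k] == 0) continue;
    double p = t.cnt[k] / n;
    double i = k + 1.0;
    ps += p * t.s[k];
    stot += t.s[k];
    m1 += p * i;
    m2 += p * i * i;
    ip.push_back(i * p);
    ++ng;
  }
  out[0] = 1.0 / (eps + ps);  // coarseness
  out[1] = (ng > 1)
    ? (2.0 * (m2 - m1 * m1) / ((double)ng * (ng - 1.0))) * (stot / n)
    : 0.0;                    // contrast
  double den = 0.0;
  for (size_t a = 0; a < ip.size(); ++a)
    for (size_t b = 0; b < ip.size(); ++b)
      den += std::fabs(ip[a] - ip[b]);
  out[2] = (den > 0.0) ? ps / den : 0.0;  // busyness
}

void fill_buffers(const IntegerMatrix& bins, const LogicalMatrix& valid,
                  std::vector<int>& bb, std::vector<char>& vb) {
  const int nr = bins.nrow(), nc = bins.ncol();
  if (valid.nrow() != nr || valid.ncol() != nc)
    stop("patch and validity grids must have identical dimensions");
  bb.assign(nr * nc, 0);
  vb.assign(nr * nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int k = r + c * nr;
      int v = valid(r, c);
      if (v == NA_LOGICAL) stop("validity grid must not contain NA");
      if (v) {
        if (bins(r, c) == NA_INTEGER) stop("valid cells must carry bin values");
        bb[k] = bins(r, c);
        vb[k] = 1;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
List cpp_ngtdm(IntegerMatrix bins, LogicalMatrix valid, int d, bool strict) {
  std::vector<int> bb;
  std::vector<char> vb;
  fill_buffers(bins, valid, bb, vb);
  Table t;
  accumulate(bb.data(), vb.data(), bins.nrow(), bins.ncol(), d, strict, t);
  return List::create(
    _["s"] = NumericVector(t.s.begin(), t.s.end()),
    _["counts"] = IntegerVector(t.cnt.begin(), t.cnt.end()),
    _["n_considered"] = t.n);
}

// [[Rcpp::export]]
NumericVector cpp_patch_features(IntegerMatrix bins, LogicalMatrix valid,
                                 int d, bool strict, double eps) {
  std::vector<int> bb;
  std::vector<char> vb;
  fill_buffers(bins, valid, bb, vb);
  Table t;
  accumulate(bb.data(), vb.data(), bins.nrow(), bins.ncol(), d, strict, t);
  NumericVector out(3);
  out.names() = CharacterVector::create("coarseness", "contrast", "busyness");
  if (t.n == 0) {
    out[0] = out[1] = out[2] = NA_REAL;
    return out;
  }
  double f[3];
  features_from(t, eps, f);
  out[0] = f[0];
  out[1] = f[1];
  out[2] = f[2];
  return out;
}

// Per-voxel texture over a binned 3-D volume. For every center voxel a
// size^3 cube is taken; features are computed on 2-D planes orthogonal to
// each of the three axes (the central plane only, or all `size` slices) and
// averaged over defined slices, then over defined orientations. A voxel with
// no defined plane yields an NA row.
//
// vol: column-major 3-D bin array; dims: its extents; centers: m x 3, 1-based.
// [[Rcpp::export]]
NumericMatrix cpp_lesion_features(IntegerVector vol, IntegerVector dims,
                                  IntegerMatrix centers, int size, int d,
                                  bool strict, double eps, bool central_only) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  if ((R_xlen_t)n1 * n2 * n3 != vol.size()) stop("dims do not match volume length");
  if (size < 3 || size % 2 == 0) stop("size must be an odd integer >= 3");
  const int h = size / 2;
  const int m = centers.nrow();
  const int* v = INTEGER(vol);
  const int ext[3] = {n1, n2, n3};

  NumericMatrix out(m, 3);
  colnames(out) = CharacterVector::create("coarseness", "contrast", "busyness");

  std::vector<int> pb(size * size);
  std::vector<char> pv(size * size);
  Table t;

  for (int row = 0; row < m; ++row) {
    int c0[3] = {centers(row, 0) - 1, centers(row, 1) - 1, centers(row, 2) - 1};
    for (int ax = 0; ax < 3; ++ax) {
      if (c0[ax] < 0 || c0[ax] >= ext[ax]) stop("center voxel outside the image");
    }
    double acc[3] = {0, 0, 0};
    int n_orient = 0;
    for (int ax = 0; ax < 3; ++ax) {
      const int u = (ax == 0) ? 1 : 0;          // first in-plane axis
      const int w = (ax == 2) ? 1 : 2;          // second in-plane axis
      double oacc[3] = {0, 0, 0};
      int n_slice = 0;
      const int t0 = central_only ? 0 : -h;
      const int t1 = central_only ? 0 : h;
      for (int off = t0; off <= t1; ++off) {
        const int f = c0[ax] + off;
        if (f < 0 || f >= ext[ax]) continue;
        // build the size x size patch for this slice
        std::fill(pb.begin(), pb.end(), 0);
        std::fill(pv.begin(), pv.end(), 0);
        for (int b = 0; b < size; ++b) {
          const int gw = c0[w] - h + b;
          if (gw < 0 || gw >= ext[w]) continue;
          for (int a = 0; a < size; ++a) {
            const int gu = c0[u] - h + a;
            if (gu < 0 || gu >= ext[u]) continue;
            int g[3];
            g[ax] = f;
            g[u] = gu;
            g[w] = gw;
            const R_xlen_t idx = g[0] + (R_xlen_t)n1 * (g[1] + (R_xlen_t)n2 * g[2]);
            const int k = a + b * size;
            pb[k] = v[idx];
            pv[k] = 1;
          }
        }
        t.reset();
        t.s.clear();
        t.cnt.clear();
        accumulate(pb.data(), pv.data(), size, size, d, strict, t);
        if (t.n == 0) continue;
        double f3[3];
        features_from(t, eps, f3);
        oacc[0] += f3[0];
        oacc[1] += f3[1];
        oacc[2] += f3[2];
        ++n_slice;
      }
      if (n_slice > 0) {
        acc[0] += oacc[0] / n_slice;
        acc[1] += oacc[1] / n_slice;
        acc[2] += oacc[2] / n_slice;
        ++n_orient;
      }
    }
    if (n_orient == 0) {
      out(row, 0) = out(row, 1) = out(row, 2) = NA_REAL;
    } else {
      out(row, 0) = acc[0] / n_orient;
      out(row, 1) = acc[1] / n_orient;
      out(row, 2) = acc[2] / n_orient;
    }
  }
  return out;
}
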