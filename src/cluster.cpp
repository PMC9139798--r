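#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pooled-variance two-sample t statistic per column of Z (observations in
// rows). Columns where the pooled variance is zero get t = 0; columns
// containing NA get NA.
// [[Rcpp::export]]
NumericVector tmap_pooled_cpp(const NumericMatrix& Z,
                              const IntegerVector& idxA,
                              const IntegerVector& idxB) {
  const int V = Z.ncol();
  const int nA = idxA.size(), nB = idxB.size();
  if (nA < 2 || nB < 2) stop("need at least 2 observations per group");
  NumericVector t(V);
  const double inv = 1.0 / nA + 1.0 / nB;
  const double df = nA + nB - 2.0;
  for (int v = 0; v < V; ++v) {
    double sA = 0, ssA = 0, sB = 0, ssB = 0;
    bool bad = false;
    for (int i = 0; i < nA; ++i) {
      double x = Z(idxA[i] - 1, v);
      if (ISNAN(x)) { bad = true; break; }
      sA += x; ssA += x * x;
    }
    if (!bad) for (int i = 0; i < nB; ++i) {
      double x = Z(idxB[i] - 1, v);
      if (ISNAN(x)) { bad = true; break; }
      sB += x; ssB += x * x;
    }
    if (bad) { t[v] = NA_REAL; continue; }
    double mA = sA / nA, mB = sB / nB;
    double sp2 = ((ssA - nA * mA * mA) + (ssB - nB * mB * mB)) / df;
    if (sp2 <= 0) { t[v] = 0.0; continue; }
    t[v] = (mA - mB) / std::sqrt(sp2 * inv);
  }
  return t;
}

static void neighbor_offsets(const IntegerVector& dims, int conn,
                             std::vector<int>& di, std::vector<int>& dj,
                             std::vector<int>& dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if ((conn == 6 && nz > 1) || (conn == 18 && nz > 2)) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Label connected components among `vox` (1-based linear indices into a
// grid of dimensions `dims`) under 6/18/26-connectivity. Returns 1-based
// component labels parallel to `vox`, in order of first visit.
// [[Rcpp::export]]
IntegerVector label_clusters_cpp(const IntegerVector& vox,
                                 const IntegerVector& dims, int conn) {
  if (conn != 6 && conn != 18 && conn != 26) stop("connectivity must be 6, 18 or 26");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t G = (R_xlen_t)nx * ny * nz;
  const int n = vox.size();
  std::vector<int> pos(G, -1);
  for (int i = 0; i < n; ++i) pos[vox[i] - 1] = i;
  std::vector<int> di, dj, dk;
  neighbor_offsets(dims, conn, di, dj, dk);
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != 0) continue;
    lab[i] = ++next;
    stack.clear(); stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int lin = vox[cur] - 1;
      int x = lin % nx, rem = lin / nx, y = rem % ny, z = rem / ny;
      for (size_t o = 0; o < di.size(); ++o) {
        int xx = x + di[o], yy = y + dj[o], zz = z + dk[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int p = pos[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        if (p >= 0 && lab[p] == 0) { lab[p] = next; stack.push_back(p); }
      }
    }
  }
  return lab;
}

// Largest connected suprathreshold component among the voxels listed in
// `vox` whose statistic passes `keep` (precomputed boolean per voxel).
static int max_component(const std::vector<char>& keep,
                         const IntegerVector& vox, std::vector<int>& pos,
                         std::vector<int>& stamp, int& cur_stamp,
                         const IntegerVector& dims,
                         const std::vector<int>& di, const std::vector<int>& dj,
                         const std::vector<int>& dk) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = vox.size();
  ++cur_stamp;
  int best = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!keep[i] || stamp[i] == cur_stamp) continue;
    int size = 0;
    stamp[i] = cur_stamp;
    stack.clear(); stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int lin = vox[cur] - 1;
      int x = lin % nx, rem = lin / nx, y = rem % ny, z = rem / ny;
      for (size_t o = 0; o < di.size(); ++o) {
        int xx = x + di[o], yy = y + dj[o], zz = z + dk[o];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        int p = pos[(R_xlen_t)xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz)];
        if (p >= 0 && keep[p] && stamp[p] != cur_stamp) {
          stamp[p] = cur_stamp; stack.push_back(p);
        }
      }
    }
    if (size > best) best = size;
  }
  return best;
}

// Permutation null of the maximum suprathreshold cluster size, pooled over
// both tails. Z: observations (pair-level z-values) x voxels; permA: one
// row per permutation, 1-based row indices assigned to group A; voxgrid:
// 1-based grid linear index of each Z column; tthr: positive t threshold.
// [[Rcpp::export]]
IntegerVector cluster_perm_null_cpp(const NumericMatrix& Z,
                                    const IntegerMatrix& permA,
                                    const IntegerVector& dims,
                                    const IntegerVector& voxgrid,
                                    double tthr, int conn) {
  if (conn != 6 && conn != 18 && conn != 26) stop("connectivity must be 6, 18 or 26");
  const int V = Z.ncol(), n = Z.nrow();
  const int nA = permA.ncol(), nB = n - nA;
  if (nB < 2 || nA < 2) stop("need at least 2 observations per group");
  const int nPerm = permA.nrow();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t G = (R_xlen_t)nx * ny * nz;

  // column totals (NA columns are excluded from clustering entirely)
  std::vector<double> sTot(V), ssTot(V);
  std::vector<char> ok(V, 1);
  for (int v = 0; v < V; ++v) {
    double s = 0, ss = 0;
    for (int i = 0; i < n; ++i) {
      double x = Z(i, v);
      if (ISNAN(x)) { ok[v] = 0; break; }
      s += x; ss += x * x;
    }
    sTot[v] = s; ssTot[v] = ss;
  }

  std::vector<int> pos(G, -1);
  for (int v = 0; v < V; ++v) pos[voxgrid[v] - 1] = v;
  std::vector<int> di, dj, dk;
  neighbor_offsets(dims, conn, di, dj, dk);
  std::vector<int> stamp(V, 0);
  int cur_stamp = 0;

  const double inv = 1.0 / nA + 1.0 / nB;
  const double df = n - 2.0;
  IntegerVector out(nPerm);
  std::vector<char> hi(V), lo(V);
  for (int p = 0; p < nPerm; ++p) {
    for (int v = 0; v < V; ++v) { hi[v] = 0; lo[v] = 0; }
    for (int v = 0; v < V; ++v) {
      if (!ok[v]) continue;
      double sA = 0, ssA = 0;
      for (int i = 0; i < nA; ++i) {
        double x = Z(permA(p, i) - 1, v);
        sA += x; ssA += x * x;
      }
      double sB = sTot[v] - sA, ssB = ssTot[v] - ssA;
      double mA = sA / nA, mB = sB / nB;
      double sp2 = ((ssA - nA * mA * mA) + (ssB - nB * mB * mB)) / df;
      if (sp2 <= 0) continue;
      double t = (mA - mB) / std::sqrt(sp2 * inv);
      if (t > tthr) hi[v] = 1;
      else if (t < -tthr) lo[v] = 1;
    }
    int mhi = max_component(hi, voxgrid, pos, stamp, cur_stamp, dims, di, dj, dk);
    int mlo = max_component(lo, voxgrid, pos, stamp, cur_stamp, dims, di, dj, dk);
    out[p] = mhi > mlo ? mhi : mlo;
  }
  return out;
}

// Pairwise voxelwise Pearson correlations for one run: `mats` is a list of
// equally shaped voxel x time matrices, one per subject. Returns a voxel x
// pair matrix in lexicographic (i < j) pair order. Zero-variance time
// courses give NA for every pair involving them.
// [[Rcpp::export]]
NumericMatrix pairwise_isc_cpp(const List& mats) {
  const int n = mats.size();
  if (n < 2) stop("at least 2 subjects are required");
  NumericMatrix first = mats[0];
  const int V = first.nrow(), T = first.ncol();
  // center rows and scale to unit norm (column-major passes throughout)
  std::vector<NumericMatrix> Z;
  std::vector<std::vector<char>> zerovar(n);
  Z.reserve(n);
  std::vector<double> mu(V), ss(V);
  for (int s = 0; s < n; ++s) {
    NumericMatrix m = mats[s];
    if (m.nrow() != V || m.ncol() != T)
      stop("subjects have mismatched voxel counts or run lengths");
    NumericMatrix z(V, T);
    std::fill(mu.begin(), mu.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const double* p = &m(0, t);
      for (int v = 0; v < V; ++v) mu[v] += p[v];
    }
    for (int v = 0; v < V; ++v) mu[v] /= T;
    std::fill(ss.begin(), ss.end(), 0.0);
    for (int t = 0; t < T; ++t) {
      const double* p = &m(0, t);
      double* q = &z(0, t);
      for (int v = 0; v < V; ++v) {
        double d = p[v] - mu[v];
        q[v] = d; ss[v] += d * d;
      }
    }
    zerovar[s].assign(V, 0);
    for (int v = 0; v < V; ++v) {
      if (ss[v] == 0) { zerovar[s][v] = 1; ss[v] = 1.0; }
      ss[v] = 1.0 / std::sqrt(ss[v]);
    }
    for (int t = 0; t < T; ++t) {
      double* q = &z(0, t);
      for (int v = 0; v < V; ++v) q[v] *= ss[v];
    }
    Z.push_back(z);
  }
  const int P = n * (n - 1) / 2;
  NumericMatrix out(V, P);
  std::vector<double> acc(V);
  int p = 0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j, ++p) {
      const NumericMatrix &a = Z[i], &b = Z[j];
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int t = 0; t < T; ++t) {
        const double *pa = &a(0, t), *pb = &b(0, t);
        for (int v = 0; v < V; ++v) acc[v] += pa[v] * pb[v];
      }
      double* po = &out(0, p);
      for (int v = 0; v < V; ++v) {
        if (zerovar[i][v] || zerovar[j][v]) po[v] = NA_REAL;
        else po[v] = acc[v] > 1.0 ? 1.0 : (acc[v] < -1.0 ? -1.0 : acc[v]);
      }
    }
  return out;
}

// Stationary unit-variance Gaussian AR(1) sample paths, one per row,
// drawn from R's RNG stream (seeded from R as usual).
// [[Rcpp::export]]
NumericMatrix ar1_matrix_cpp(int n_series, int n_time, double phi) {
  NumericMatrix x(n_series, n_time);
  double* c0 = &x(0, 0);
  for (int v = 0; v < n_series; ++v) c0[v] = norm_rand();
  if (n_time == 1) return x;
  const double sd = (phi != 0.0) ? std::sqrt(1.0 - phi * phi) : 1.0;
  for (int t = 1; t < n_time; ++t) {
    const double* prev = &x(0, t - 1);
    double* cur = &x(0, t);
    for (int v = 0; v < n_series; ++v)
      cur[v] = phi * prev[v] + sd * norm_rand();
  }
  return x;
}

// In-place row standardization to sample mean 0, variance 1 (divisor N-1);
// constant rows are left centered at zero.
// [[Rcpp::export]]
NumericMatrix standardize_rows_cpp(NumericMatrix x) {
  const int V = x.nrow(), T = x.ncol();
  std::vector<double> mu(V, 0.0), ss(V, 0.0);
  for (int t = 0; t < T; ++t) {
    const double* p = &x(0, t);
    for (int v = 0; v < V; ++v) mu[v] += p[v];
  }
  for (int v = 0; v < V; ++v) mu[v] /= T;
  for (int t = 0; t < T; ++t) {
    double* p = &x(0, t);
    for (int v = 0; v < V; ++v) {
      p[v] -= mu[v];
      ss[v] += p[v] * p[v];
    }
  }
  for (int v = 0; v < V; ++v) {
    double sd = std::sqrt(ss[v] / (T - 1));
    ss[v] = (sd == 0) ? 1.0 : 1.0 / sd;
  }
  for (int t = 0; t < T; ++t) {
    double* p = &x(0, t);
    for (int v = 0; v < V; ++v) p[v] *= ss[v];
  }
  return x;
}

// Separable convolution of the first three (spatial) dimensions of a 3D
// or 4D column-major array with a 1D kernel, zero padding at the faces.
// [[Rcpp::export]]
NumericVector smooth_sep_cpp(const NumericVector& a, const IntegerVector& dims,
                             const NumericVector& w) {
  const int nd = dims.size();
  if (nd != 3 && nd != 4) stop("expected 3 or 4 dimensions");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nt = (nd == 4) ? dims[3] : 1;
  const R_xlen_t nxyz = (R_xlen_t)nx * ny * nz;
  const int half = (w.size() - 1) / 2;
  NumericVector cur = clone(a);
  NumericVector nxt(a.size());
  const int sizes[3] = {nx, ny, nz};
  const R_xlen_t strides[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  for (int axis = 0; axis < 3; ++axis) {
    const int d = sizes[axis];
    const R_xlen_t s = strides[axis];
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (int t = 0; t < nt; ++t) {
      const R_xlen_t base_t = (R_xlen_t)t * nxyz;
      for (int j = -half; j <= half; ++j) {
        if (j >= d || -j >= d) continue;
        const double wj = w[j + half];
        // output index i along axis receives input index i + j
        const int lo = (j < 0) ? -j : 0;
        const int hi = (j > 0) ? d - j : d;
        if (axis == 0) {
          for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y) {
              const R_xlen_t row = base_t + strides[2] * z + strides[1] * y;
              const double* in = &cur[row + j];
              double* out = &nxt[row];
              for (int x = lo; x < hi; ++x) out[x] += wj * in[x];
            }
        } else if (axis == 1) {
          for (int z = 0; z < nz; ++z)
            for (int y = lo; y < hi; ++y) {
              const R_xlen_t row_in = base_t + strides[2] * z + strides[1] * (y + j);
              const R_xlen_t row_out = base_t + strides[2] * z + strides[1] * y;
              const double* in = &cur[row_in];
              double* out = &nxt[row_out];
              for (int x = 0; x < nx; ++x) out[x] += wj * in[x];
            }
        } else {
          for (int z = lo; z < hi; ++z)
            for (int y = 0; y < ny; ++y) {
              const R_xlen_t row_in = base_t + strides[2] * (z + j) + strides[1] * y;
              const R_xlen_t row_out = base_t + strides[2] * z + strides[1] * y;
              const double* in = &cur[row_in];
              double* out = &nxt[row_out];
              for (int x = 0; x < nx; ++x) out[x] += wj * in[x];
            }
        }
      }
    }
    std::swap(cur, nxt);
  }
  cur.attr("dim") = dims;
  return cur;
}
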