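#include <Rcpp.h>
#include <queue>
#include <limits>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = (nz, ny, nx), column-major,
// so z is the fastest-varying axis. All voxel indices here are 0-based.

static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n - 2;
  i %= period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// Correlation of each axis-aligned line with a centered kernel,
// reflected ("mirror") boundary handling. axis: 0=z, 1=y, 2=x.
// [[Rcpp::export]]
NumericVector conv3d_axis_cpp(NumericVector x, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n[3] = {nz, ny, nx};
  const R_xlen_t st[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  const int r = ((int)kernel.size() - 1) / 2;
  NumericVector out(x.size());
  const int a = axis, b = (axis + 1) % 3, c = (axis + 2) % 3;
  const int na = n[a], nb = n[b], nc = n[c];
  const R_xlen_t sa = st[a], sb = st[b], sc = st[c];
  std::vector<double> line(na);
  for (int ic = 0; ic < nc; ic++) {
    for (int ib = 0; ib < nb; ib++) {
      const R_xlen_t base = ib * sb + ic * sc;
      for (int ia = 0; ia < na; ia++) line[ia] = x[base + ia * sa];
      for (int ia = 0; ia < na; ia++) {
        double acc = 0.0;
        for (int t = -r; t <= r; t++)
          acc += kernel[t + r] * line[reflect_idx(ia + t, na)];
        out[base + ia * sa] = acc;
      }
    }
  }
  return out;
}

// Eigenvalues (descending) of per-voxel symmetric 3x3 matrices given as
// the six unique components. Analytic (trigonometric) solver.
// [[Rcpp::export]]
List eig3_sym_cpp(NumericVector a11, NumericVector a12, NumericVector a13,
                  NumericVector a22, NumericVector a23, NumericVector a33) {
  const R_xlen_t m = a11.size();
  NumericVector e1(m), e2(m), e3(m);
  for (R_xlen_t i = 0; i < m; i++) {
    const double p1 = a12[i] * a12[i] + a13[i] * a13[i] + a23[i] * a23[i];
    const double q = (a11[i] + a22[i] + a33[i]) / 3.0;
    if (p1 < 1e-300) {
      double d[3] = {a11[i], a22[i], a33[i]};
      std::sort(d, d + 3);
      e1[i] = d[2]; e2[i] = d[1]; e3[i] = d[0];
      continue;
    }
    const double b11 = a11[i] - q, b22 = a22[i] - q, b33 = a33[i] - q;
    const double p2 = b11 * b11 + b22 * b22 + b33 * b33 + 2.0 * p1;
    const double p = std::sqrt(p2 / 6.0);
    // det(B)/2 with B = (A - qI)/p
    const double ip = 1.0 / p;
    const double c11 = b11 * ip, c22 = b22 * ip, c33 = b33 * ip;
    const double c12 = a12[i] * ip, c13 = a13[i] * ip, c23 = a23[i] * ip;
    double detB = c11 * (c22 * c33 - c23 * c23)
                - c12 * (c12 * c33 - c23 * c13)
                + c13 * (c12 * c23 - c22 * c13);
    double rr = detB / 2.0;
    if (rr < -1.0) rr = -1.0; else if (rr > 1.0) rr = 1.0;
    const double phi = std::acos(rr) / 3.0;
    const double l1 = q + 2.0 * p * std::cos(phi);
    const double l3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
    const double l2 = 3.0 * q - l1 - l3;
    e1[i] = l1; e2[i] = l2; e3[i] = l3;
  }
  return List::create(_["e1"] = e1, _["e2"] = e2, _["e3"] = e3);
}

// ---- squared Euclidean distance transform (Felzenszwalb & Huttenlocher) ----

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s;
    for (;;) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    const double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxels) from every voxel to the nearest
// TRUE voxel of `fg`. Voxels inside fg get 0. All-false input -> Inf.
// [[Rcpp::export]]
NumericVector edt3d_sq_cpp(LogicalVector fg, IntegerVector dims) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n[3] = {nz, ny, nx};
  const R_xlen_t st[3] = {1, (R_xlen_t)nz, (R_xlen_t)nz * ny};
  // large finite sentinel instead of Inf: keeps the lower-envelope
  // arithmetic well defined on lines mixing reached and unreached voxels
  const double BIG = 1e18;
  NumericVector d(fg.size());
  for (R_xlen_t i = 0; i < fg.size(); i++) d[i] = fg[i] ? 0.0 : BIG;
  const int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int axis = 0; axis < 3; axis++) {
    const int a = axis, b = (axis + 1) % 3, c = (axis + 2) % 3;
    const int na = n[a], nb = n[b], nc = n[c];
    const R_xlen_t sa = st[a], sb = st[b], sc = st[c];
    for (int ic = 0; ic < nc; ic++) {
      for (int ib = 0; ib < nb; ib++) {
        const R_xlen_t base = ib * sb + ic * sc;
        bool allbig = true;
        for (int ia = 0; ia < na; ia++) {
          f[ia] = d[base + ia * sa];
          if (f[ia] < BIG) allbig = false;
        }
        if (allbig) continue;
        dt1d(f, out, na, v, z);
        for (int ia = 0; ia < na; ia++) d[base + ia * sa] = out[ia];
      }
    }
  }
  const double INF = std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < d.size(); i++)
    if (d[i] >= 1e17) d[i] = INF;
  return d;
}

// ---- 3D connected components ----

// Labels foreground voxels (fg != 0) with ids 1..K in discovery order
// (BFS). connectivity: 6, 18 or 26.
// [[Rcpp::export]]
IntegerVector label3d_cpp(LogicalVector fg, IntegerVector dims, int connectivity) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  std::vector<int> dz, dy, dx;
  for (int az = -1; az <= 1; az++)
    for (int ay = -1; ay <= 1; ay++)
      for (int ax = -1; ax <= 1; ax++) {
        const int l1 = std::abs(az) + std::abs(ay) + std::abs(ax);
        if (l1 == 0) continue;
        if (connectivity == 6 && l1 > 1) continue;
        if (connectivity == 18 && l1 > 2) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
      }
  const int nn = (int)dz.size();
  IntegerVector lab(fg.size(), 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        const R_xlen_t i = z * sz + y * sy + x * sx;
        if (!fg[i] || lab[i] != 0) continue;
        next++;
        lab[i] = next;
        q.push(i);
        while (!q.empty()) {
          const R_xlen_t cur = q.front(); q.pop();
          const int cz = (int)(cur % nz);
          const int cy = (int)((cur / nz) % ny);
          const int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int t = 0; t < nn; t++) {
            const int pz = cz + dz[t], py = cy + dy[t], px = cx + dx[t];
            if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
              continue;
            const R_xlen_t j = pz * sz + py * sy + px * sx;
            if (fg[j] && lab[j] == 0) { lab[j] = next; q.push(j); }
          }
        }
      }
  return lab;
}

// ---- greedy detection support ----

// Global argmax with tie handling: among all voxels whose value is within
// `tol` of the maximum, return the one with the smallest (z, y, x)
// lexicographic index. Returns list(value, index = 0-based c(z, y, x)).
// [[Rcpp::export]]
List argmax_lex_cpp(NumericVector v, IntegerVector dims, double tol) {
  const int nz = dims[0], ny = dims[1];
  double best = -std::numeric_limits<double>::infinity();
  for (R_xlen_t i = 0; i < v.size(); i++)
    if (v[i] > best) best = v[i];
  const double cut = best - tol;
  int bz = -1, by = -1, bx = -1;
  for (R_xlen_t i = 0; i < v.size(); i++) {
    if (v[i] < cut) continue;
    const int z = (int)(i % nz);
    const int y = (int)((i / nz) % ny);
    const int x = (int)(i / ((R_xlen_t)nz * ny));
    if (bz < 0 || z < bz || (z == bz && (y < by || (y == by && x < bx)))) {
      bz = z; by = y; bx = x;
    }
  }
  return List::create(_["value"] = best,
                      _["index"] = IntegerVector::create(bz, by, bx));
}

// Zero P over the ball `zoff` centered at `center` and subtract the
// corresponding contribution from the running correlation `corr`
// (corr[c] = sum_o w[o] * P[c + o] with zero padding). Modifies P and
// corr in place; the caller must own both arrays.
// [[Rcpp::export]]
void zero_ball_update_cpp(NumericVector P, NumericVector corr,
                          IntegerVector dims, IntegerVector center,
                          IntegerMatrix zoff, IntegerMatrix toff,
                          double w) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  const int cz = center[0], cy = center[1], cx = center[2];
  const int nzf = zoff.nrow(), ntf = toff.nrow();
  for (int i = 0; i < nzf; i++) {
    const int vz = cz + zoff(i, 0), vy = cy + zoff(i, 1), vx = cx + zoff(i, 2);
    if (vz < 0 || vz >= nz || vy < 0 || vy >= ny || vx < 0 || vx >= nx)
      continue;
    const R_xlen_t vi = vz + vy * sy + vx * sx;
    const double p = P[vi];
    if (p == 0.0) continue;
    P[vi] = 0.0;
    const double pw = p * w;
    for (int t = 0; t < ntf; t++) {
      const int qz = vz - toff(t, 0), qy = vy - toff(t, 1), qx = vx - toff(t, 2);
      if (qz < 0 || qz >= nz || qy < 0 || qy >= ny || qx < 0 || qx >= nx)
        continue;
      corr[qz + qy * sy + qx * sx] -= pw;
    }
  }
}

// Sum of P over `off` voxel offsets around `center`, with the number of
// in-bounds offsets (for truncated-window renormalization).
// [[Rcpp::export]]
List ball_sum_cpp(NumericVector P, IntegerVector dims, IntegerVector center,
                  IntegerMatrix off) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  const int cz = center[0], cy = center[1], cx = center[2];
  double s = 0.0;
  int cnt = 0;
  for (int i = 0; i < off.nrow(); i++) {
    const int vz = cz + off(i, 0), vy = cy + off(i, 1), vx = cx + off(i, 2);
    if (vz < 0 || vz >= nz || vy < 0 || vy >= ny || vx < 0 || vx >= nx)
      continue;
    s += P[vz + vy * sy + vx * sx];
    cnt++;
  }
  return List::create(_["sum"] = s, _["n_inside"] = cnt);
}

// Brute-force k-nearest-neighbour squared distances from each row of Q
// to the rows of X. exclude[i] (0-based index into X, or -1) marks one
// point to skip for query i (used for leave-self-out queries).
// [[Rcpp::export]]
NumericMatrix knn_sq_cpp(NumericMatrix Q, NumericMatrix X, int k,
                         IntegerVector exclude) {
  const int m = Q.nrow(), n = X.nrow();
  NumericMatrix out(m, k);
  std::vector<double> best(k);
  for (int i = 0; i < m; i++) {
    for (int t = 0; t < k; t++) best[t] = std::numeric_limits<double>::infinity();
    const double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    const int ex = exclude[i];
    for (int j = 0; j < n; j++) {
      if (j == ex) continue;
      const double d0 = X(j, 0) - qx, d1 = X(j, 1) - qy, d2 = X(j, 2) - qz;
      const double d = d0 * d0 + d1 * d1 + d2 * d2;
      if (d < best[k - 1]) {
        int t = k - 1;
        while (t > 0 && best[t - 1] > d) { best[t] = best[t - 1]; t--; }
        best[t] = d;
      }
    }
    for (int t = 0; t < k; t++) out(i, t) = best[t];
  }
  return out;
}
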