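#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Large-but-finite stand-in for "no feature in this row" in the distance
// transform.  Kept well below sqrt(DBL_MAX) so squared sums stay exact
// enough; real squared distances in mm^2 never approach it.
static const double DT_INF = 1e12;

// 1-D squared distance transform (lower envelope of parabolas), sample
// positions at i*step.  In-place on f (length n).
static void dt1d(std::vector<double> &f, int n, double step,
                 std::vector<int> &v, std::vector<double> &z,
                 std::vector<double> &d) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; q++) {
    double xq = q * step, s = 0.0;
    for (;;) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) k--; else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
    } else {
      k++;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * step;
    while (z[k + 1] < xq) k++;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
  for (int q = 0; q < n; q++) f[q] = d[q];
}

// Exact Euclidean distance transform of a 3-D mask with anisotropic
// spacing (mm).  Returns, for every voxel, the distance from its center to
// the nearest background voxel center; the grid boundary counts as
// background at half a voxel outside the first/last slice.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, IntegerVector dim,
                        NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; i++) g[i] = mask[i] ? DT_INF : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), d(nmax), row(nmax);

  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; i++) row[i] = g[base + i];
      dt1d(row, nx, spacing[0], v, z, d);
      for (int i = 0; i < nx; i++) g[base + i] = row[i];
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; j++) row[j] = g[base + (R_xlen_t)j * nx];
      dt1d(row, ny, spacing[1], v, z, d);
      for (int j = 0; j < ny; j++) g[base + (R_xlen_t)j * nx] = row[j];
    }
  // z pass
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; k++) row[k] = g[base + (R_xlen_t)k * nx * ny];
      dt1d(row, nz, spacing[2], v, z, d);
      for (int k = 0; k < nz; k++) g[base + (R_xlen_t)k * nx * ny] = row[k];
    }

  // clip against the grid boundary (background half a voxel outside)
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        R_xlen_t id = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
        double db = std::min(std::min((i + 0.5) * spacing[0],
                                      (nx - i - 0.5) * spacing[0]),
                    std::min(std::min((j + 0.5) * spacing[1],
                                      (ny - j - 0.5) * spacing[1]),
                    std::min((k + 0.5) * spacing[2],
                             (nz - k - 0.5) * spacing[2])));
        out[id] = std::min(std::sqrt(g[id]), db);
      }
  return out;
}

// Multi-source shortest-path distance (26-neighborhood, metric edge
// lengths in mm) restricted to mask voxels.  sources are 1-based linear
// indices.  Returns dist (Inf where unreachable / background) and pred
// (1-based predecessor linear index; NA for sources and unreached).
// [[Rcpp::export]]
List geodesic_cpp(LogicalVector mask, IntegerVector dim,
                  NumericVector spacing, IntegerVector sources) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> dist(n, R_PosInf);
  std::vector<R_xlen_t> pred(n, -1);

  // 26-neighborhood offsets and weights
  std::vector<int> ox, oy, oz;
  std::vector<double> w;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
        double a = dx * spacing[0], b = dy * spacing[1], c = dz * spacing[2];
        w.push_back(std::sqrt(a * a + b * b + c * c));
      }

  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int s = 0; s < sources.size(); s++) {
    R_xlen_t id = (R_xlen_t)sources[s] - 1;
    if (id < 0 || id >= n || !mask[id])
      stop("source voxel %d is not inside the mask", (int)sources[s]);
    dist[id] = 0.0;
    pq.push(QE(0.0, id));
  }

  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double du = top.first;
    R_xlen_t u = top.second;
    if (du > dist[u]) continue;
    int ui = (int)(u % nx), uj = (int)((u / nx) % ny), uk = (int)(u / ((R_xlen_t)nx * ny));
    for (size_t e = 0; e < w.size(); e++) {
      int vi = ui + ox[e], vj = uj + oy[e], vk = uk + oz[e];
      if (vi < 0 || vi >= nx || vj < 0 || vj >= ny || vk < 0 || vk >= nz)
        continue;
      R_xlen_t vid = (R_xlen_t)vk * nx * ny + (R_xlen_t)vj * nx + vi;
      if (!mask[vid]) continue;
      double nd = du + w[e];
      if (nd < dist[vid]) {
        dist[vid] = nd;
        pred[vid] = u;
        pq.push(QE(nd, vid));
      }
    }
  }

  NumericVector dout(n);
  IntegerVector pout(n);
  for (R_xlen_t i = 0; i < n; i++) {
    dout[i] = dist[i];
    pout[i] = (pred[i] < 0) ? NA_INTEGER : (int)(pred[i] + 1);
  }
  return List::create(_["dist"] = dout, _["pred"] = pout);
}

// For each query point (rows of q, mm coordinates) find the index of the
// nearest reference point (rows of r).  Ties broken in favor of the lower
// row index, so callers pass references ordered by linear voxel index.
// [[Rcpp::export]]
IntegerVector nearest_ref_cpp(NumericMatrix q, NumericMatrix r) {
  const int nq = q.nrow(), nr = r.nrow();
  if (nr == 0) stop("no reference points");
  IntegerVector out(nq);
  for (int i = 0; i < nq; i++) {
    double best = R_PosInf;
    int bj = 0;
    double qx = q(i, 0), qy = q(i, 1), qz = q(i, 2);
    for (int j = 0; j < nr; j++) {
      double dx = qx - r(j, 0), dy = qy - r(j, 1), dz = qz - r(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}
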