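#include <Rcpp.h>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-neighbourhood offsets
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY4[4] = {-1, 1, 0, 0};
static const int DX4[4] = {0, 0, -1, 1};

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n, -1) {}
  int find(int a) {
    int r = a;
    while (parent[r] != r) r = parent[r];
    while (parent[a] != r) { int nx = parent[a]; parent[a] = r; a = nx; }
    return r;
  }
};

// Prominence-based peak detection (0-dimensional persistence).
//
// Pixels inside `mask` are processed in decreasing intensity order; connected
// components of super-level sets are tracked with union-find. When two
// components merge at level v, the one with the lower peak dies with
// prominence = peak - v; it is reported as a seed iff prominence >= tol.
// Components that survive to the end are reported iff
// peak - (component minimum) >= tol. Plateaus are resolved by reporting the
// integer-rounded centroid of the connected equal-valued plateau around the
// peak pixel (ties toward smaller (y, x)).
//
// Returns a list with 1-based matrix coordinates y, x plus peak value and
// prominence, ordered by decreasing peak value (ties: smaller (y, x)).
// [[Rcpp::export]]
List prominence_peaks_cpp(NumericMatrix img, LogicalMatrix mask, double tol) {
  const int nr = img.nrow(), nc = img.ncol(), n = nr * nc;
  std::vector<int> px;
  px.reserve(n);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (mask(i, j)) px.push_back(j * nr + i);
  const double* v = REAL(img);
  // value desc, then y asc, then x asc
  std::stable_sort(px.begin(), px.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    int ya = a % nr, xa = a / nr, yb = b % nr, xb = b / nr;
    if (ya != yb) return ya < yb;
    return xa < xb;
  });

  UF uf(n);
  std::vector<int> peak_of(n, -1);     // root -> peak pixel id
  std::vector<double> minval(n, 0.0);  // root -> lowest level seen
  std::vector<char> processed(n, 0);
  std::vector<int> acc_peak;
  std::vector<double> acc_prom;

  for (size_t k = 0; k < px.size(); ++k) {
    int p = px[k];
    int py = p % nr, pxx = p / nr;
    // distinct processed neighbour roots
    int roots[8];
    int nroots = 0;
    for (int d = 0; d < 8; ++d) {
      int ny = py + DY8[d], nx = pxx + DX8[d];
      if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
      int q = nx * nr + ny;
      if (!processed[q]) continue;
      int r = uf.find(q);
      bool seen = false;
      for (int t = 0; t < nroots; ++t) if (roots[t] == r) { seen = true; break; }
      if (!seen) roots[nroots++] = r;
    }
    processed[p] = 1;
    if (nroots == 0) {
      uf.parent[p] = p;
      peak_of[p] = p;
      minval[p] = v[p];
      continue;
    }
    // primary root: highest peak value; tie -> smaller (y, x) of peak pixel
    int prim = roots[0];
    for (int t = 1; t < nroots; ++t) {
      int r = roots[t];
      double pv = v[peak_of[r]], pb = v[peak_of[prim]];
      if (pv > pb) { prim = r; continue; }
      if (pv == pb) {
        int a = peak_of[r], b = peak_of[prim];
        int ya = a % nr, xa = a / nr, yb = b % nr, xb = b / nr;
        if (ya < yb || (ya == yb && xa < xb)) prim = r;
      }
    }
    for (int t = 0; t < nroots; ++t) {
      int r = roots[t];
      if (r == prim) continue;
      double prom = v[peak_of[r]] - v[p];
      if (prom >= tol) {
        acc_peak.push_back(peak_of[r]);
        acc_prom.push_back(prom);
      }
      uf.parent[uf.find(r)] = uf.find(prim);
    }
    int rp = uf.find(prim);
    uf.parent[p] = rp;
    minval[rp] = v[p];
  }
  // surviving components
  for (size_t k = 0; k < px.size(); ++k) {
    int p = px[k];
    if (uf.parent[p] == p) {
      double prom = v[peak_of[p]] - minval[p];
      if (prom >= tol) {
        acc_peak.push_back(peak_of[p]);
        acc_prom.push_back(prom);
      }
    }
  }

  // plateau centroids
  int m = acc_peak.size();
  IntegerVector outy(m), outx(m);
  NumericVector outv(m), outp(m);
  std::vector<int> stack;
  std::vector<int> plateau;
  std::vector<char> visited(n, 0);
  for (int s = 0; s < m; ++s) {
    int p = acc_peak[s];
    double pv = v[p];
    plateau.clear();
    stack.clear();
    stack.push_back(p);
    visited[p] = 1;
    while (!stack.empty()) {
      int q = stack.back(); stack.pop_back();
      plateau.push_back(q);
      int qy = q % nr, qx = q / nr;
      for (int d = 0; d < 8; ++d) {
        int ny = qy + DY8[d], nx = qx + DX8[d];
        if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
        int t = nx * nr + ny;
        if (!visited[t] && mask(ny, nx) && v[t] == pv) {
          visited[t] = 1;
          stack.push_back(t);
        }
      }
    }
    for (size_t t = 0; t < plateau.size(); ++t) visited[plateau[t]] = 0;
    double my = 0, mx = 0;
    for (size_t t = 0; t < plateau.size(); ++t) {
      my += plateau[t] % nr;
      mx += plateau[t] / nr;
    }
    my /= plateau.size();
    mx /= plateau.size();
    // round half toward smaller coordinate
    int cy = (int)std::ceil(my - 0.5), cx = (int)std::ceil(mx - 0.5);
    // snap to the nearest plateau member if the rounded centroid left it
    bool inside = false;
    for (size_t t = 0; t < plateau.size(); ++t) {
      int q = plateau[t];
      if (q % nr == cy && q / nr == cx) { inside = true; break; }
    }
    if (!inside) {
      double best = 1e300;
      int bq = plateau[0];
      for (size_t t = 0; t < plateau.size(); ++t) {
        int q = plateau[t];
        int qy = q % nr, qx = q / nr;
        double d2 = (qy - my) * (qy - my) + (qx - mx) * (qx - mx);
        if (d2 < best - 1e-12 ||
            (std::abs(d2 - best) <= 1e-12 &&
             (qy < bq % nr || (qy == bq % nr && qx < bq / nr)))) {
          best = d2;
          bq = q;
        }
      }
      cy = bq % nr;
      cx = bq / nr;
    }
    outy[s] = cy + 1;
    outx[s] = cx + 1;
    outv[s] = pv;
    outp[s] = acc_prom[s];
  }
  return List::create(_["y"] = outy, _["x"] = outx,
                      _["value"] = outv, _["prominence"] = outp);
}

struct WSNode {
  double elev;
  double dist;
  int y, x;
  int label;
  unsigned long order;
};
struct WSCmp {
  bool operator()(const WSNode& a, const WSNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    if (a.dist != b.dist) return a.dist > b.dist;
    if (a.y != b.y) return a.y > b.y;
    if (a.x != b.x) return a.x > b.x;
    return a.order > b.order;
  }
};

// Marker-controlled watershed by priority flooding, restricted to `mask`.
// Primary priority is the elevation surface; ties are broken by Euclidean
// distance to the claiming seed, so that on constant elevation the partition
// is the Euclidean nearest-seed (Voronoi) assignment within the mask.
// Seeds are given as 1-based (y, x) matrix coordinates and produce labels
// 1..n_seeds in input order. Mask pixels unreachable from any seed stay 0.
// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix elev, LogicalMatrix mask,
                                   IntegerVector seed_y, IntegerVector seed_x) {
  const int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix labels(nr, nc);
  const int ns = seed_y.size();
  if (ns == 0) return labels;
  std::priority_queue<WSNode, std::vector<WSNode>, WSCmp> pq;
  unsigned long order = 0;
  for (int s = 0; s < ns; ++s) {
    int y = seed_y[s] - 1, x = seed_x[s] - 1;
    if (y < 0 || y >= nr || x < 0 || x >= nc || !mask(y, x))
      stop("seed outside image or mask");
    pq.push(WSNode{elev(y, x), 0.0, y, x, s + 1, order++});
  }
  while (!pq.empty()) {
    WSNode nd = pq.top();
    pq.pop();
    if (labels(nd.y, nd.x) != 0) continue;
    labels(nd.y, nd.x) = nd.label;
    int sy = seed_y[nd.label - 1] - 1, sx = seed_x[nd.label - 1] - 1;
    for (int d = 0; d < 4; ++d) {
      int ny = nd.y + DY4[d], nx = nd.x + DX4[d];
      if (ny < 0 || ny >= nr || nx < 0 || nx >= nc) continue;
      if (!mask(ny, nx) || labels(ny, nx) != 0) continue;
      double dy = ny - sy, dx = nx - sx;
      pq.push(WSNode{elev(ny, nx), std::sqrt(dy * dy + dx * dx),
                     ny, nx, nd.label, order++});
    }
  }
  return labels;
}
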