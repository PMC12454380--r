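// Geometry kernels for point-cloud processing: farthest-point sampling,
// brute-force kNN, fixed-radius grouping, grid-accelerated DBSCAN,
// segment-wise max (with argmax, for pooling gradients), and ball-pivoting
// surface reconstruction.
#include <Rcpp.h>
#include <unordered_map>
#include <set>
#include <array>
#include <map>
#include <vector>
#include <cmath>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

static inline double sq(double x) { return x * x; }

static inline double dist2(const NumericMatrix& a, int i,
                           const NumericMatrix& b, int j) {
  return sq(a(i, 0) - b(j, 0)) + sq(a(i, 1) - b(j, 1)) + sq(a(i, 2) - b(j, 2));
}

// Farthest-point sampling. Deterministic, permutation-invariant start:
// the point farthest from the centroid (first index on exact ties).
// [[Rcpp::export]]
IntegerVector fps_cpp(NumericMatrix pts, int m) {
  int n = pts.nrow();
  if (m > n) stop("fps: m exceeds point count");
  double cx = 0, cy = 0, cz = 0;
  for (int i = 0; i < n; ++i) { cx += pts(i,0); cy += pts(i,1); cz += pts(i,2); }
  cx /= n; cy /= n; cz /= n;
  int start = 0; double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = sq(pts(i,0)-cx) + sq(pts(i,1)-cy) + sq(pts(i,2)-cz);
    if (d > best) { best = d; start = i; }
  }
  IntegerVector out(m);
  std::vector<double> mind(n, R_PosInf);
  int cur = start;
  for (int s = 0; s < m; ++s) {
    out[s] = cur + 1;
    double far_d = -1.0; int far_i = 0;
    for (int i = 0; i < n; ++i) {
      double d = dist2(pts, i, pts, cur);
      if (d < mind[i]) mind[i] = d;
      if (mind[i] > far_d) { far_d = mind[i]; far_i = i; }
    }
    cur = far_i;
  }
  return out;
}

// k nearest neighbours of each query point among ref points (brute force).
// self = TRUE when query and ref are the same matrix: neighbour j == i is
// skipped. Returns 1-based indices and distances, ascending.
// [[Rcpp::export]]
List knn_cpp(NumericMatrix query, NumericMatrix ref, int k, bool self = false) {
  int nq = query.nrow(), nr = ref.nrow();
  int avail = self ? nr - 1 : nr;
  if (k > avail) stop("knn: k exceeds available neighbour count");
  IntegerMatrix idx(nq, k);
  NumericMatrix dst(nq, k);
  std::vector<std::pair<double,int> > cand;
  for (int i = 0; i < nq; ++i) {
    cand.clear();
    cand.reserve(nr);
    for (int j = 0; j < nr; ++j) {
      if (self && j == i) continue;
      cand.push_back(std::make_pair(dist2(query, i, ref, j), j));
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int s = 0; s < k; ++s) {
      idx(i, s) = cand[s].second + 1;
      dst(i, s) = std::sqrt(cand[s].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}

// Fixed-radius grouping: for each centroid take up to nsample nearest points
// within radius (sorted by distance); pad by repeating the nearest member.
// A centroid with no point in radius falls back to its global nearest point.
// [[Rcpp::export]]
IntegerMatrix ball_group_cpp(NumericMatrix centroids, NumericMatrix pts,
                             double radius, int nsample) {
  int m = centroids.nrow(), n = pts.nrow();
  double r2 = radius * radius;
  IntegerMatrix out(m, nsample);
  std::vector<std::pair<double,int> > inr;
  for (int i = 0; i < m; ++i) {
    inr.clear();
    double bestd = R_PosInf; int bestj = 0;
    for (int j = 0; j < n; ++j) {
      double d = dist2(centroids, i, pts, j);
      if (d <= r2) inr.push_back(std::make_pair(d, j));
      if (d < bestd) { bestd = d; bestj = j; }
    }
    if (inr.empty()) inr.push_back(std::make_pair(bestd, bestj));
    std::sort(inr.begin(), inr.end());
    int take = std::min((int)inr.size(), nsample);
    for (int s = 0; s < nsample; ++s)
      out(i, s) = inr[s < take ? s : 0].second + 1;
  }
  return out;
}

// ---- spatial hash grid ----------------------------------------------------
struct HashGrid {
  double cell;
  double ox, oy, oz;
  std::unordered_map<int64_t, std::vector<int> > cells;
  const NumericMatrix* P;

  static int64_t key(int ix, int iy, int iz) {
    return ((int64_t)(ix + 1048576) << 42) |
           ((int64_t)(iy + 1048576) << 21) |
           (int64_t)(iz + 1048576);
  }
  void build(const NumericMatrix& pts, double cell_) {
    P = &pts; cell = cell_;
    ox = oy = oz = 0.0;
    int n = pts.nrow();
    cells.reserve(n);
    for (int i = 0; i < n; ++i) {
      int ix = (int)std::floor(pts(i,0) / cell);
      int iy = (int)std::floor(pts(i,1) / cell);
      int iz = (int)std::floor(pts(i,2) / cell);
      cells[key(ix, iy, iz)].push_back(i);
    }
  }
  // collect indices with dist <= rad of (x,y,z)
  void query(double x, double y, double z, double rad,
             std::vector<int>& out) const {
    out.clear();
    double r2 = rad * rad;
    int x0 = (int)std::floor((x - rad) / cell), x1 = (int)std::floor((x + rad) / cell);
    int y0 = (int)std::floor((y - rad) / cell), y1 = (int)std::floor((y + rad) / cell);
    int z0 = (int)std::floor((z - rad) / cell), z1 = (int)std::floor((z + rad) / cell);
    for (int ix = x0; ix <= x1; ++ix)
      for (int iy = y0; iy <= y1; ++iy)
        for (int iz = z0; iz <= z1; ++iz) {
          std::unordered_map<int64_t, std::vector<int> >::const_iterator it =
            cells.find(key(ix, iy, iz));
          if (it == cells.end()) continue;
          for (size_t s = 0; s < it->second.size(); ++s) {
            int j = it->second[s];
            double d = sq((*P)(j,0)-x) + sq((*P)(j,1)-y) + sq((*P)(j,2)-z);
            if (d <= r2) out.push_back(j);
          }
        }
  }
};

// Classic DBSCAN (<= eps neighbourhood, core point if |N(p)| >= minpts
// counting the point itself). Cluster ids 0..K-1 in discovery order,
// noise = -1.
// [[Rcpp::export]]
IntegerVector dbscan_cpp(NumericMatrix pts, double eps, int minpts) {
  int n = pts.nrow();
  IntegerVector labels(n, -2);  // -2 = unvisited
  if (n == 0 || eps <= 0) { std::fill(labels.begin(), labels.end(), -1); return labels; }
  HashGrid grid;
  grid.build(pts, eps);
  std::vector<int> nb, nb2;
  int k = 0;
  std::vector<int> seeds;
  for (int i = 0; i < n; ++i) {
    if (labels[i] != -2) continue;
    grid.query(pts(i,0), pts(i,1), pts(i,2), eps, nb);
    if ((int)nb.size() < minpts) { labels[i] = -1; continue; }
    labels[i] = k;
    seeds.assign(nb.begin(), nb.end());
    for (size_t s = 0; s < seeds.size(); ++s) {
      int j = seeds[s];
      if (labels[j] == -1) labels[j] = k;          // border point
      if (labels[j] != -2) continue;
      labels[j] = k;
      grid.query(pts(j,0), pts(j,1), pts(j,2), eps, nb2);
      if ((int)nb2.size() >= minpts)
        seeds.insert(seeds.end(), nb2.begin(), nb2.end());
    }
    ++k;
  }
  return labels;
}

// Segment-wise max with argmax (1-based row index into x), for max pooling.
// seg is 1-based with values in 1..G; every group must be non-empty.
// [[Rcpp::export]]
List seg_max_cpp(NumericMatrix x, IntegerVector seg, int G) {
  int n = x.nrow(), C = x.ncol();
  NumericMatrix mx(G, C);
  IntegerMatrix arg(G, C);
  std::fill(mx.begin(), mx.end(), R_NegInf);
  for (int i = 0; i < n; ++i) {
    int g = seg[i] - 1;
    for (int c = 0; c < C; ++c) {
      double v = x(i, c);
      if (v > mx(g, c)) { mx(g, c) = v; arg(g, c) = i + 1; }
    }
  }
  return List::create(_["max"] = mx, _["argmax"] = arg);
}

// ---- ball-pivoting surface reconstruction ---------------------------------
namespace bpa {

struct V3 {
  double x, y, z;
  V3(double x_=0, double y_=0, double z_=0) : x(x_), y(y_), z(z_) {}
};
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 operator*(const V3& a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

struct FrontEdge { int a, b, o; V3 c; };

struct State {
  const NumericMatrix* P;
  const NumericMatrix* N;
  bool hasN;
  double r;
  HashGrid grid;
  std::map<std::pair<int,int>, int> edgeUse;
  std::set<std::vector<int> > tris;
  std::vector<FrontEdge> front;
  std::vector<bool> used;
  std::vector<std::array<int,3> > out;

  V3 p(int i) const { return V3((*P)(i,0), (*P)(i,1), (*P)(i,2)); }
  V3 nv(int i) const { return V3((*N)(i,0), (*N)(i,1), (*N)(i,2)); }

  // ball center touching p1,p2,p3 at radius r, on side `sgn` of triangle normal
  bool ballCenter(int i, int j, int k, int sgn, V3& c) const {
    V3 p1 = p(i), e1 = p(j) - p1, e2 = p(k) - p1;
    double a11 = dot(e1, e1), a22 = dot(e2, e2), a12 = dot(e1, e2);
    double det = a11 * a22 - a12 * a12;
    if (det <= 1e-14 * a11 * a22 || a11 == 0 || a22 == 0) return false;
    // solve [a11 a12; a12 a22] [al; be] = [a11/2; a22/2]
    double al = (0.5 * a11 * a22 - 0.5 * a12 * a22) / det;
    double be = (0.5 * a22 * a11 - 0.5 * a12 * a11) / det;
    V3 c0 = p1 + e1 * al + e2 * be;
    double R2 = dot(c0 - p1, c0 - p1);
    double h2 = r * r - R2;
    if (h2 <= 0) return false;
    V3 nrm = cross(e1, e2);
    double nn = norm(nrm);
    if (nn == 0) return false;
    c = c0 + nrm * (sgn * std::sqrt(h2) / nn);
    return true;
  }

  bool ballEmpty(const V3& c, std::vector<int>& scratch) const {
    grid.query(c.x, c.y, c.z, r * (1.0 - 1e-9), scratch);
    for (size_t s = 0; s < scratch.size(); ++s) {
      double d = norm(p(scratch[s]) - c);
      if (d < r - 1e-7 * r) return false;
    }
    return true;
  }

  void addTriangle(int a, int b, int x, const V3& c) {
    std::vector<int> t; t.push_back(a); t.push_back(b); t.push_back(x);
    std::sort(t.begin(), t.end());
    if (!tris.insert(t).second) return;
    std::array<int,3> tri = {{a, b, x}};
    out.push_back(tri);
    used[a] = used[b] = used[x] = true;
    bumpEdge(a, b); bumpEdge(b, x); bumpEdge(a, x);
    FrontEdge e1 = {a, x, b, c}; front.push_back(e1);
    FrontEdge e2 = {x, b, a, c}; front.push_back(e2);
  }
  void bumpEdge(int i, int j) {
    edgeUse[std::make_pair(std::min(i,j), std::max(i,j))]++;
  }
  int edgeCount(int i, int j) {
    std::map<std::pair<int,int>, int>::iterator it =
      edgeUse.find(std::make_pair(std::min(i,j), std::max(i,j)));
    return it == edgeUse.end() ? 0 : it->second;
  }
};

} // namespace bpa

// Ball-pivoting reconstruction at a single radius. `normals` may have zero
// rows; when present it selects the ball side for seed triangles. Returns a
// 1-based ntri x 3 vertex-index matrix.
// [[Rcpp::export]]
IntegerMatrix bpa_cpp(NumericMatrix pts, NumericMatrix normals, double r,
                      int max_candidates = 64) {
  using namespace bpa;
  int n = pts.nrow();
  // symbolic perturbation: a deterministic sub-tolerance jitter breaks the
  // cocircular degeneracies of gridded inputs (which otherwise admit two
  // conflicting, overlapping triangulations of each lattice square); the
  // caller measures triangle areas on the unperturbed coordinates.
  NumericMatrix ppts(clone(pts));
  for (int i = 0; i < n; ++i) {
    uint64_t h = (uint64_t)(i + 1) * 0x9E3779B97F4A7C15ULL;
    for (int c = 0; c < 3; ++c) {
      h ^= h >> 33; h *= 0xFF51AFD7ED558CCDULL; h ^= h >> 33;
      double u = (double)(h & 0xFFFFFFFFULL) / 4294967295.0 - 0.5;
      ppts(i, c) += 1e-4 * r * u;
    }
  }
  State st;
  st.P = &ppts; st.N = &normals; st.hasN = normals.nrow() == n; st.r = r;
  st.used.assign(n, false);
  if (n >= 3) st.grid.build(ppts, r);
  std::vector<int> scratch, cand;
  std::vector<std::pair<double,int> > near;

  size_t maxTri = (size_t)std::max(40, 8 * n);

  for (int seed = 0; seed < n && st.out.size() < maxTri; ++seed) {
    if (st.used[seed]) continue;
    // gather nearest candidates within 2r
    st.grid.query(ppts(seed,0), ppts(seed,1), ppts(seed,2), 2.0 * r, cand);
    near.clear();
    for (size_t s = 0; s < cand.size(); ++s) {
      if (cand[s] == seed) continue;
      near.push_back(std::make_pair(norm(st.p(cand[s]) - st.p(seed)), cand[s]));
    }
    std::sort(near.begin(), near.end());
    if ((int)near.size() > max_candidates) near.resize(max_candidates);
    bool seeded = false;
    for (size_t a = 0; a < near.size() && !seeded; ++a) {
      for (size_t b = a + 1; b < near.size() && !seeded; ++b) {
        int j = near[a].second, k = near[b].second;
        int sgnFirst = 1;
        if (st.hasN) {
          V3 e1 = st.p(j) - st.p(seed), e2 = st.p(k) - st.p(seed);
          V3 tn = cross(e1, e2);
          V3 na = st.nv(seed) + st.nv(j) + st.nv(k);
          sgnFirst = dot(tn, na) >= 0 ? 1 : -1;
        }
        const int sgns[2] = { sgnFirst, -sgnFirst };
        int nsgn = st.hasN ? 1 : 2;
        for (int q = 0; q < nsgn && !seeded; ++q) {
          V3 c;
          if (!st.ballCenter(seed, j, k, sgns[q], c)) continue;
          if (!st.ballEmpty(c, scratch)) continue;
          st.addTriangle(seed, j, k, c);
          // also push the seed's own edge (j,k was not pushed by addTriangle)
          FrontEdge e = {seed, j, k, c};  // ensure all 3 edges reachable
          st.front.push_back(e);
          seeded = true;
        }
      }
    }
    // pivot until the front is exhausted
    while (!st.front.empty() && st.out.size() < maxTri) {
      FrontEdge e = st.front.back();
      st.front.pop_back();
      if (st.edgeCount(e.a, e.b) >= 2) continue;
      V3 pa = st.p(e.a), pb = st.p(e.b);
      V3 m = (pa + pb) * 0.5;
      V3 u = pb - pa;
      double un = norm(u);
      if (un == 0) continue;
      u = u * (1.0 / un);
      V3 v1 = e.c - m;
      // rotation direction: initial center velocity must point away from the
      // opposite vertex of the current triangle
      V3 away = m - st.p(e.o);
      if (dot(cross(u, v1), away) < 0) u = u * (-1.0);
      st.grid.query(m.x, m.y, m.z, 2.0 * r, cand);
      int bestX = -1; V3 bestC;
      std::vector<std::pair<double, std::pair<int, V3> > > hits;
      for (size_t s = 0; s < cand.size(); ++s) {
        int x = cand[s];
        if (x == e.a || x == e.b || x == e.o) continue;
        for (int sg = -1; sg <= 1; sg += 2) {
          V3 c;
          if (!st.ballCenter(e.a, e.b, x, sg, c)) continue;
          if (st.hasN) {
            // keep the ball on the outward side of the surface: rejects
            // pivots that roll through an open boundary onto the back face
            V3 na = st.nv(e.a) + st.nv(e.b) + st.nv(x);
            V3 cen = (st.p(e.a) + st.p(e.b) + st.p(x)) * (1.0 / 3.0);
            if (dot(c - cen, na) <= 0) continue;
          }
          V3 v2 = c - m;
          double th = std::atan2(dot(cross(v1, v2), u), dot(v1, v2));
          if (th < 1e-7) th += 2.0 * M_PI;
          hits.push_back(std::make_pair(th, std::make_pair(x, c)));
        }
      }
      std::sort(hits.begin(), hits.end(),
                [](const std::pair<double, std::pair<int, V3> >& l,
                   const std::pair<double, std::pair<int, V3> >& rr) {
                  return l.first < rr.first;
                });
      for (size_t s = 0; s < hits.size(); ++s) {
        if (st.ballEmpty(hits[s].second.second, scratch)) {
          bestX = hits[s].second.first;
          bestC = hits[s].second.second;
          break;
        }
      }
      if (bestX < 0) continue;  // boundary edge
      st.addTriangle(e.a, e.b, bestX, bestC);
    }
  }

  IntegerMatrix tri((int)st.out.size(), 3);
  for (size_t t = 0; t < st.out.size(); ++t) {
    tri(t, 0) = st.out[t][0] + 1;
    tri(t, 1) = st.out[t][1] + 1;
    tri(t, 2) = st.out[t][2] + 1;
  }
  return tri;
}
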