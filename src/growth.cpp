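// Hot loops for confined self-avoiding chain growth and geometric analysis.
// Chains are grown one persistence unit (beads_per_unit beads of diameter
// bead_d, collinear) at a time among k candidate directions; the Rosenbluth
// log-weight sum(log(m_t/k)) corrects the growth bias. All coordinates in nm.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>
#include <random>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic seed derivation (splitmix64)
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// ---------------------------------------------------------------------------
// spatial hash grid over an unbounded domain; cell edge = query radius
struct CellGrid {
  double cell;
  std::unordered_map<int64_t, std::vector<int>> cells;

  explicit CellGrid(double cell_, size_t reserve_n = 0) : cell(cell_) {
    if (reserve_n) cells.reserve(reserve_n);
  }
  static inline int64_t key(int ix, int iy, int iz) {
    // 21 bits per axis, offset to stay positive; domain << 3e7 nm
    return (static_cast<int64_t>(ix + (1 << 20)) << 42) |
           (static_cast<int64_t>(iy + (1 << 20)) << 21) |
            static_cast<int64_t>(iz + (1 << 20));
  }
  inline void insert(int id, double x, double y, double z) {
    int ix = (int)std::floor(x / cell), iy = (int)std::floor(y / cell),
        iz = (int)std::floor(z / cell);
    cells[key(ix, iy, iz)].push_back(id);
  }
  // true if any stored point lies strictly within r of (x,y,z);
  // points listed in `skip` (sorted, tiny) are ignored
  template <typename F>
  inline bool any_within(double x, double y, double z, double r, F accept) const {
    double r2 = r * r;
    int ix = (int)std::floor(x / cell), iy = (int)std::floor(y / cell),
        iz = (int)std::floor(z / cell);
    int span = (int)std::ceil(r / cell);
    for (int dx = -span; dx <= span; ++dx)
      for (int dy = -span; dy <= span; ++dy)
        for (int dz = -span; dz <= span; ++dz) {
          auto it = cells.find(key(ix + dx, iy + dy, iz + dz));
          if (it == cells.end()) continue;
          for (int id : it->second) {
            if (!accept(id)) continue;
            double ddx = xs[id] - x, ddy = ys[id] - y, ddz = zs[id] - z;
            if (ddx * ddx + ddy * ddy + ddz * ddz < r2) return true;
          }
        }
    return false;
  }
  // coordinate storage shared with the grower
  std::vector<double> xs, ys, zs;
  inline void push_point(double x, double y, double z) {
    int id = (int)xs.size();
    xs.push_back(x); ys.push_back(y); zs.push_back(z);
    insert(id, x, y, z);
  }
};

// ---------------------------------------------------------------------------
// k near-uniform unit directions (Fibonacci sphere), optionally rotated
static void fibonacci_dirs(int k, std::vector<double> &dx,
                           std::vector<double> &dy, std::vector<double> &dz) {
  dx.resize(k); dy.resize(k); dz.resize(k);
  const double ga = 2.39996322972865332;  // golden angle
  for (int i = 0; i < k; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / k;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    dx[i] = r * std::cos(phi); dy[i] = r * std::sin(phi); dz[i] = z;
  }
}

// uniform random rotation from a quaternion
static void random_rotation(std::mt19937_64 &rng, double R[3][3]) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  double u1 = U(rng), u2 = U(rng), u3 = U(rng);
  double q0 = std::sqrt(1 - u1) * std::sin(2 * M_PI * u2);
  double q1 = std::sqrt(1 - u1) * std::cos(2 * M_PI * u2);
  double q2 = std::sqrt(u1) * std::sin(2 * M_PI * u3);
  double q3 = std::sqrt(u1) * std::cos(2 * M_PI * u3);
  R[0][0] = 1 - 2 * (q2 * q2 + q3 * q3);
  R[0][1] = 2 * (q1 * q2 - q0 * q3);
  R[0][2] = 2 * (q1 * q3 + q0 * q2);
  R[1][0] = 2 * (q1 * q2 + q0 * q3);
  R[1][1] = 1 - 2 * (q1 * q1 + q3 * q3);
  R[1][2] = 2 * (q2 * q3 - q0 * q1);
  R[2][0] = 2 * (q1 * q3 - q0 * q2);
  R[2][1] = 2 * (q2 * q3 + q0 * q1);
  R[2][2] = 1 - 2 * (q1 * q1 + q2 * q2);
}

// [[Rcpp::export]]
NumericMatrix cpp_fibonacci_sphere(int k) {
  std::vector<double> dx, dy, dz;
  fibonacci_dirs(k, dx, dy, dz);
  NumericMatrix out(k, 3);
  for (int i = 0; i < k; ++i) { out(i,0)=dx[i]; out(i,1)=dy[i]; out(i,2)=dz[i]; }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_random_rotation(double seed) {
  std::mt19937_64 rng(splitmix64((uint64_t)seed));
  double R[3][3];
  random_rotation(rng, R);
  NumericMatrix out(3, 3);
  for (int i = 0; i < 3; ++i) for (int j = 0; j < 3; ++j) out(i,j) = R[i][j];
  return out;
}

// ---------------------------------------------------------------------------
// single-chain growth attempt
struct GrowResult {
  bool completed;
  int steps_completed;           // persistence units successfully added
  double log_weight;
  std::vector<int> m_counts;     // feasible-candidate count per step
  std::vector<double> coords;    // row-major x,y,z
};

static const double OVERLAP_TOL = 1e-6;  // nm, on the equality boundary

// candidate feasibility: all bpu interpolated beads of the unit must stay
// inside the allowed radius (if finite) and >= bead_d from every stored bead
static inline bool unit_feasible(const CellGrid &g, double tx, double ty,
                                 double tz, double ux, double uy, double uz,
                                 double bead_d, int bpu, double R_allow) {
  bool confined = R_allow > 0;
  double R2 = R_allow * R_allow;
  for (int j = 1; j <= bpu; ++j) {
    double px = tx + j * bead_d * ux;
    double py = ty + j * bead_d * uy;
    double pz = tz + j * bead_d * uz;
    if (confined && px * px + py * py + pz * pz > R2) return false;
    if (g.any_within(px, py, pz, bead_d - OVERLAP_TOL,
                     [](int) { return true; }))
      return false;
  }
  return true;
}

static GrowResult grow_attempt(int n_units, double R_allow, double bead_d,
                               int bpu, int k, uint64_t seed,
                               bool rotate_dirs) {
  GrowResult res;
  res.completed = false;
  res.steps_completed = 0;
  res.log_weight = 0.0;
  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> bx, by, bz;
  fibonacci_dirs(k, bx, by, bz);
  std::vector<double> dx(k), dy(k), dz(k);
  if (rotate_dirs) {
    double R[3][3];
    random_rotation(rng, R);
    for (int i = 0; i < k; ++i) {
      dx[i] = R[0][0]*bx[i] + R[0][1]*by[i] + R[0][2]*bz[i];
      dy[i] = R[1][0]*bx[i] + R[1][1]*by[i] + R[1][2]*bz[i];
      dz[i] = R[2][0]*bx[i] + R[2][1]*by[i] + R[2][2]*bz[i];
    }
  } else { dx = bx; dy = by; dz = bz; }

  int n_beads = 1 + (n_units - 1) * bpu;
  // cell edge of two bead diameters: fewer hash probes per query at the
  // same exactness (span stays 1 since 2d > query radius d)
  CellGrid grid(bead_d * 2, (size_t)(n_beads / 2));
  grid.xs.reserve(n_beads); grid.ys.reserve(n_beads); grid.zs.reserve(n_beads);

  // seed bead: uniform in the allowed sphere when confined, else the origin
  double sx = 0, sy = 0, sz = 0;
  if (R_allow > 0) {
    do {
      sx = (2 * U(rng) - 1) * R_allow;
      sy = (2 * U(rng) - 1) * R_allow;
      sz = (2 * U(rng) - 1) * R_allow;
    } while (sx * sx + sy * sy + sz * sz > R_allow * R_allow);
  }
  grid.push_point(sx, sy, sz);
  double tx = sx, ty = sy, tz = sz;

  std::vector<int> feas;
  feas.reserve(k);
  res.m_counts.reserve(n_units - 1);
  for (int t = 1; t < n_units; ++t) {
    feas.clear();
    for (int c = 0; c < k; ++c)
      if (unit_feasible(grid, tx, ty, tz, dx[c], dy[c], dz[c], bead_d, bpu,
                        R_allow))
        feas.push_back(c);
    int m = (int)feas.size();
    res.m_counts.push_back(m);
    if (m == 0) return res;  // dead end
    int pick = feas[std::min<int>(m - 1, (int)(U(rng) * m))];
    res.log_weight += std::log((double)m / (double)k);
    for (int j = 1; j <= bpu; ++j)
      grid.push_point(tx + j * bead_d * dx[pick], ty + j * bead_d * dy[pick],
                      tz + j * bead_d * dz[pick]);
    tx += bpu * bead_d * dx[pick];
    ty += bpu * bead_d * dy[pick];
    tz += bpu * bead_d * dz[pick];
    res.steps_completed = t;
  }
  res.completed = true;
  res.coords.resize((size_t)n_beads * 3);
  for (int i = 0; i < n_beads; ++i) {
    res.coords[3 * i]     = grid.xs[i];
    res.coords[3 * i + 1] = grid.ys[i];
    res.coords[3 * i + 2] = grid.zs[i];
  }
  return res;
}

static inline uint64_t attempt_seed(double master, int chain, int attempt) {
  uint64_t m = (uint64_t)(int64_t)master;
  return splitmix64(m * 0x100000001B3ULL + (uint64_t)chain * 1000003ULL +
                    (uint64_t)attempt);
}

// [[Rcpp::export]]
List cpp_grow_chain(int n_units, double R_allow, double bead_d, int bpu,
                    int k, double master_seed, int chain_index,
                    int max_attempts, bool rotate_dirs) {
  int attempts = 0;
  GrowResult res;
  while (attempts < max_attempts) {
    res = grow_attempt(n_units, R_allow, bead_d, bpu, k,
                       attempt_seed(master_seed, chain_index, attempts),
                       rotate_dirs);
    ++attempts;
    if (res.completed) break;
  }
  List out;
  out["completed"] = res.completed;
  out["attempts"] = attempts;
  out["log_weight"] = res.log_weight;
  out["steps_completed"] = res.steps_completed;
  out["m_counts"] = IntegerVector(res.m_counts.begin(), res.m_counts.end());
  if (res.completed) {
    int n = (int)res.coords.size() / 3;
    NumericMatrix M(n, 3);
    for (int i = 0; i < n; ++i) {
      M(i,0)=res.coords[3*i]; M(i,1)=res.coords[3*i+1]; M(i,2)=res.coords[3*i+2];
    }
    out["coords"] = M;
  } else {
    out["coords"] = R_NilValue;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_grow_ensemble(int n_chains, int n_units, double R_allow,
                       double bead_d, int bpu, int k, double master_seed,
                       int max_attempts_per_chain, bool rotate_dirs) {
  List chains(n_chains);
  NumericVector logw(n_chains);
  IntegerVector attempts(n_chains);
  int attrition = 0;
  for (int c = 0; c < n_chains; ++c) {
    int a = 0;
    GrowResult res;
    while (a < max_attempts_per_chain) {
      res = grow_attempt(n_units, R_allow, bead_d, bpu, k,
                         attempt_seed(master_seed, c, a), rotate_dirs);
      ++a;
      if (res.completed) break;
    }
    if (!res.completed)
      stop("chain %d: attrition ceiling reached (%d failed attempts at N=%d)",
           c + 1, a, n_units);
    attrition += a - 1;
    attempts[c] = a;
    logw[c] = res.log_weight;
    int n = (int)res.coords.size() / 3;
    NumericMatrix M(n, 3);
    for (int i = 0; i < n; ++i) {
      M(i,0)=res.coords[3*i]; M(i,1)=res.coords[3*i+1]; M(i,2)=res.coords[3*i+2];
    }
    chains[c] = M;
    if (c % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["coords"] = chains, _["log_weight"] = logw,
                      _["attempts"] = attempts,
                      _["attrition_count"] = attrition);
}

// feasibility of each candidate direction from the tip of an existing chain
// [[Rcpp::export]]
LogicalVector cpp_feasible_moves(NumericMatrix coords, NumericMatrix dirs,
                                 double R_allow, double bead_d, int bpu) {
  int n = coords.nrow(), k = dirs.nrow();
  CellGrid grid(bead_d, (size_t)n * 2);
  grid.xs.reserve(n); grid.ys.reserve(n); grid.zs.reserve(n);
  for (int i = 0; i < n; ++i) grid.push_point(coords(i,0), coords(i,1), coords(i,2));
  double tx = coords(n-1,0), ty = coords(n-1,1), tz = coords(n-1,2);
  LogicalVector ok(k);
  for (int c = 0; c < k; ++c)
    ok[c] = unit_feasible(grid, tx, ty, tz, dirs(c,0), dirs(c,1), dirs(c,2),
                          bead_d, bpu, R_allow);
  return ok;
}

// grid-accelerated self-avoidance check; returns violating pairs (1-based)
// [[Rcpp::export]]
IntegerMatrix cpp_overlap_pairs(NumericMatrix coords, double bead_d,
                                double tol) {
  int n = coords.nrow();
  CellGrid grid(bead_d, (size_t)n * 2);
  grid.xs.reserve(n); grid.ys.reserve(n); grid.zs.reserve(n);
  for (int i = 0; i < n; ++i) grid.push_point(coords(i,0), coords(i,1), coords(i,2));
  std::vector<int> pi, pj;
  double r = bead_d - tol, r2 = r * r;
  int span = (int)std::ceil(r / grid.cell);
  for (int i = 0; i < n; ++i) {
    int ix = (int)std::floor(grid.xs[i] / grid.cell);
    int iy = (int)std::floor(grid.ys[i] / grid.cell);
    int iz = (int)std::floor(grid.zs[i] / grid.cell);
    for (int dx = -span; dx <= span; ++dx)
      for (int dy = -span; dy <= span; ++dy)
        for (int dz = -span; dz <= span; ++dz) {
          auto it = grid.cells.find(CellGrid::key(ix+dx, iy+dy, iz+dz));
          if (it == grid.cells.end()) continue;
          for (int j : it->second) {
            if (j <= i + 1) continue;  // self and bonded neighbor exempt
            double ddx = grid.xs[j]-grid.xs[i], ddy = grid.ys[j]-grid.ys[i],
                   ddz = grid.zs[j]-grid.zs[i];
            if (ddx*ddx + ddy*ddy + ddz*ddz < r2) { pi.push_back(i+1); pj.push_back(j+1); }
          }
        }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t q = 0; q < pi.size(); ++q) { out(q,0)=pi[q]; out(q,1)=pj[q]; }
  return out;
}

// ---------------------------------------------------------------------------
// minimal enclosing sphere (Welzl, randomized incremental with supports <= 4)
struct Sphere { double x, y, z, r2; };

static Sphere sphere_from0() { return {0, 0, 0, -1}; }
static Sphere sphere_from1(const double *p) { return {p[0], p[1], p[2], 0}; }
static Sphere sphere_from2(const double *a, const double *b) {
  Sphere s;
  s.x = 0.5 * (a[0] + b[0]); s.y = 0.5 * (a[1] + b[1]); s.z = 0.5 * (a[2] + b[2]);
  double dx = a[0]-s.x, dy = a[1]-s.y, dz = a[2]-s.z;
  s.r2 = dx*dx + dy*dy + dz*dz;
  return s;
}
// circumsphere of 3 points (center in their plane)
static Sphere sphere_from3(const double *a, const double *b, const double *c) {
  double ab[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double ac[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double ab2 = ab[0]*ab[0]+ab[1]*ab[1]+ab[2]*ab[2];
  double ac2 = ac[0]*ac[0]+ac[1]*ac[1]+ac[2]*ac[2];
  double cr[3] = {ab[1]*ac[2]-ab[2]*ac[1], ab[2]*ac[0]-ab[0]*ac[2],
                  ab[0]*ac[1]-ab[1]*ac[0]};
  double cr2 = cr[0]*cr[0]+cr[1]*cr[1]+cr[2]*cr[2];
  if (cr2 < 1e-20) {  // collinear: widest pair
    Sphere s1 = sphere_from2(a, b), s2 = sphere_from2(a, c), s3 = sphere_from2(b, c);
    Sphere best = s1;
    if (s2.r2 > best.r2) best = s2;
    if (s3.r2 > best.r2) best = s3;
    return best;
  }
  double t1[3] = {ab2*ac[0]-ac2*ab[0], ab2*ac[1]-ac2*ab[1], ab2*ac[2]-ac2*ab[2]};
  double to[3] = {t1[1]*cr[2]-t1[2]*cr[1], t1[2]*cr[0]-t1[0]*cr[2],
                  t1[0]*cr[1]-t1[1]*cr[0]};
  Sphere s;
  s.x = a[0] + to[0] / (2*cr2); s.y = a[1] + to[1] / (2*cr2); s.z = a[2] + to[2] / (2*cr2);
  double dx = a[0]-s.x, dy = a[1]-s.y, dz = a[2]-s.z;
  s.r2 = dx*dx + dy*dy + dz*dz;
  return s;
}
static Sphere sphere_from4(const double *a, const double *b, const double *c,
                           const double *d) {
  // solve linear system for circumcenter
  double A[3][3], rhs[3];
  const double *pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    A[i][0] = pts[i][0]-a[0]; A[i][1] = pts[i][1]-a[1]; A[i][2] = pts[i][2]-a[2];
    rhs[i] = 0.5 * (A[i][0]*A[i][0] + A[i][1]*A[i][1] + A[i][2]*A[i][2]);
  }
  double det = A[0][0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
             - A[0][1]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
             + A[0][2]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]);
  if (std::fabs(det) < 1e-14) {  // degenerate: fall back to face spheres
    Sphere best = sphere_from3(a, b, c);
    Sphere s;
    s = sphere_from3(a, b, d); if (s.r2 > best.r2) best = s;
    s = sphere_from3(a, c, d); if (s.r2 > best.r2) best = s;
    s = sphere_from3(b, c, d); if (s.r2 > best.r2) best = s;
    return best;
  }
  double inv = 1.0 / det, u[3];
  u[0] = inv * ( rhs[0]*(A[1][1]*A[2][2]-A[1][2]*A[2][1])
               - A[0][1]*(rhs[1]*A[2][2]-A[1][2]*rhs[2])
               + A[0][2]*(rhs[1]*A[2][1]-A[1][1]*rhs[2]));
  u[1] = inv * ( A[0][0]*(rhs[1]*A[2][2]-A[1][2]*rhs[2])
               - rhs[0]*(A[1][0]*A[2][2]-A[1][2]*A[2][0])
               + A[0][2]*(A[1][0]*rhs[2]-rhs[1]*A[2][0]));
  u[2] = inv * ( A[0][0]*(A[1][1]*rhs[2]-rhs[1]*A[2][1])
               - A[0][1]*(A[1][0]*rhs[2]-rhs[1]*A[2][0])
               + rhs[0]*(A[1][0]*A[2][1]-A[1][1]*A[2][0]));
  Sphere s;
  s.x = a[0]+u[0]; s.y = a[1]+u[1]; s.z = a[2]+u[2];
  s.r2 = u[0]*u[0]+u[1]*u[1]+u[2]*u[2];
  return s;
}

static inline bool in_sphere(const Sphere &s, const double *p, double eps2) {
  double dx = p[0]-s.x, dy = p[1]-s.y, dz = p[2]-s.z;
  return dx*dx + dy*dy + dz*dz <= s.r2 + eps2;
}

static Sphere sphere_of_support(const std::vector<const double*> &R) {
  switch (R.size()) {
    case 0: return sphere_from0();
    case 1: return sphere_from1(R[0]);
    case 2: return sphere_from2(R[0], R[1]);
    case 3: return sphere_from3(R[0], R[1], R[2]);
    default: return sphere_from4(R[0], R[1], R[2], R[3]);
  }
}

static Sphere welzl(std::vector<const double*> &P, size_t n,
                    std::vector<const double*> &R, double eps2) {
  if (n == 0 || R.size() == 4) return sphere_of_support(R);
  Sphere s = welzl(P, n - 1, R, eps2);
  const double *p = P[n - 1];
  if (in_sphere(s, p, eps2)) return s;
  R.push_back(p);
  s = welzl(P, n - 1, R, eps2);
  R.pop_back();
  // move-to-front heuristic
  for (size_t i = n - 1; i > 0; --i) P[i] = P[i - 1];
  P[0] = p;
  return s;
}

static Sphere min_enclosing_sphere(const double *pts, const int *idx, int n,
                                   uint64_t shuffle_seed) {
  std::vector<const double*> P(n);
  for (int i = 0; i < n; ++i) P[i] = pts + 3 * (idx ? idx[i] : i);
  std::mt19937_64 rng(shuffle_seed);
  std::shuffle(P.begin(), P.end(), rng);
  std::vector<const double*> R;
  R.reserve(4);
  return welzl(P, P.size(), R, 1e-7);
}

// [[Rcpp::export]]
NumericVector cpp_min_enclosing_sphere(NumericMatrix coords) {
  int n = coords.nrow();
  std::vector<double> pts((size_t)n * 3);
  for (int i = 0; i < n; ++i) {
    pts[3*i] = coords(i,0); pts[3*i+1] = coords(i,1); pts[3*i+2] = coords(i,2);
  }
  Sphere s = min_enclosing_sphere(pts.data(), nullptr, n, 12345);
  return NumericVector::create(_["x"] = s.x, _["y"] = s.y, _["z"] = s.z,
                               _["radius"] = std::sqrt(std::max(0.0, s.r2)));
}

// contiguous-window scan: greedy left-to-right maximal windows whose minimal
// enclosing sphere has diameter <= diam_nm and that contain >= min_beads beads
// (exploits that the MES radius is monotone under set growth: binary search)
// [[Rcpp::export]]
IntegerMatrix cpp_scan_substructures(NumericMatrix coords, double diam_nm,
                                     int min_beads) {
  int n = coords.nrow();
  std::vector<double> pts((size_t)n * 3);
  for (int i = 0; i < n; ++i) {
    pts[3*i] = coords(i,0); pts[3*i+1] = coords(i,1); pts[3*i+2] = coords(i,2);
  }
  double rmax = diam_nm / 2.0;
  std::vector<int> starts, ends;  // half-open [start, end), 0-based
  auto window_fits = [&](int i, int e) {  // beads i..e-1
    // cheap prefilter: bounding-box diagonal of first/last vs rmax is unsafe;
    // use exact MES directly (fast enough with move-to-front Welzl)
    std::vector<int> idx(e - i);
    for (int q = i; q < e; ++q) idx[q - i] = q;
    Sphere s = min_enclosing_sphere(pts.data(), idx.data(), e - i,
                                    (uint64_t)(i * 2654435761u + e));
    return std::sqrt(std::max(0.0, s.r2)) <= rmax + 1e-9;
  };
  int i = 0;
  while (i + min_beads <= n) {
    if (!window_fits(i, i + min_beads)) { ++i; continue; }
    int lo = i + min_beads, hi = n;  // largest e with window_fits(i, e)
    while (lo < hi) {
      int mid = lo + (hi - lo + 1) / 2;
      if (mid == lo) break;
      if (window_fits(i, mid)) lo = mid; else hi = mid - 1;
    }
    while (lo < n && window_fits(i, lo + 1)) ++lo;  // guard boundary
    starts.push_back(i);
    ends.push_back(lo);
    i = lo;
    Rcpp::checkUserInterrupt();
  }
  IntegerMatrix out((int)starts.size(), 2);
  for (size_t q = 0; q < starts.size(); ++q) {
    out(q,0) = starts[q] + 1;  // 1-based start bead
    out(q,1) = ends[q];        // inclusive end bead in 1-based indexing
  }
  return out;
}

// cover scan: a sphere of radius `radius` is centred on every unit-boundary
// bead; the maximal contiguous bead run inside it is a candidate fragment;
// qualifying fragments (>= min_beads) overlapping on the chain are merged
// [[Rcpp::export]]
IntegerMatrix cpp_scan_substructures_cover(NumericMatrix coords, double radius,
                                           int min_beads, int unit_stride) {
  int n = coords.nrow();
  double r2 = radius * radius;
  std::vector<std::pair<int,int>> runs;  // 0-based inclusive
  for (int c = 0; c < n; c += unit_stride) {
    double cx = coords(c,0), cy = coords(c,1), cz = coords(c,2);
    auto inside = [&](int b) {
      double dx = coords(b,0)-cx, dy = coords(b,1)-cy, dz = coords(b,2)-cz;
      return dx*dx + dy*dy + dz*dz <= r2;
    };
    int lo = c, hi = c;
    while (lo > 0 && inside(lo - 1)) --lo;
    while (hi < n - 1 && inside(hi + 1)) ++hi;
    if (hi - lo + 1 >= min_beads) runs.emplace_back(lo, hi);
  }
  std::sort(runs.begin(), runs.end());
  std::vector<std::pair<int,int>> merged;
  for (auto &r : runs) {
    if (!merged.empty() && r.first <= merged.back().second)
      merged.back().second = std::max(merged.back().second, r.second);
    else
      merged.push_back(r);
  }
  IntegerMatrix out((int)merged.size(), 2);
  for (size_t q = 0; q < merged.size(); ++q) {
    out(q,0) = merged[q].first + 1;
    out(q,1) = merged[q].second + 1;
  }
  return out;
}

// per-substructure fraction of persistence units with any bead within r_c of
// any bead of a different substructure; intervals are 1-based inclusive
// [[Rcpp::export]]
NumericMatrix cpp_interaction_fractions(NumericMatrix coords,
                                        IntegerVector starts,
                                        IntegerVector ends, double r_c,
                                        int bpu) {
  int ns = starts.size();
  int n = coords.nrow();
  // substructure membership per bead (-1 none)
  std::vector<int> member(n, -1);
  for (int s = 0; s < ns; ++s)
    for (int b = starts[s] - 1; b <= ends[s] - 1; ++b) member[b] = s;
  CellGrid grid(r_c, (size_t)n);
  grid.xs.reserve(n); grid.ys.reserve(n); grid.zs.reserve(n);
  for (int i = 0; i < n; ++i) grid.push_point(coords(i,0), coords(i,1), coords(i,2));
  // unit of bead b (0-based): ceil(b/bpu) in 0-based bead indexing
  auto unit_of = [bpu](int b) { return (b + bpu - 1) / bpu; };
  NumericMatrix out(ns, 3);  // fraction, n_prox_units, n_units
  for (int s = 0; s < ns; ++s) {
    int b0 = starts[s] - 1, b1 = ends[s] - 1;
    int u0 = unit_of(b0), u1 = unit_of(b1);
    int n_units_s = u1 - u0 + 1;
    std::vector<char> prox(n_units_s, 0);
    for (int b = b0; b <= b1; ++b) {
      int u = unit_of(b) - u0;
      if (prox[u]) continue;
      bool near = grid.any_within(coords(b,0), coords(b,1), coords(b,2),
                                  r_c + 1e-9, [&](int id) {
                                    return member[id] >= 0 && member[id] != s;
                                  });
      if (near) prox[u] = 1;
    }
    int np = 0;
    for (char c : prox) np += c;
    out(s,0) = n_units_s > 0 ? (double)np / n_units_s : 0.0;
    out(s,1) = np;
    out(s,2) = n_units_s;
  }
  return out;
}

// number of unordered site pairs (unit indices, |i-j| >= 2) within r_c
// [[Rcpp::export]]
int cpp_count_bound_pairs(NumericMatrix site_coords, IntegerVector site_units,
                          double r_c) {
  int m = site_coords.nrow();
  double r2 = r_c * r_c;
  int count = 0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      if (std::abs(site_units[i] - site_units[j]) < 2) continue;
      double dx = site_coords(i,0)-site_coords(j,0);
      double dy = site_coords(i,1)-site_coords(j,1);
      double dz = site_coords(i,2)-site_coords(j,2);
      if (dx*dx + dy*dy + dz*dz <= r2) ++count;
    }
  return count;
}

// per-s contact counts between unit-boundary beads (i, i+s) of one chain
// [[Rcpp::export]]
List cpp_contact_counts(NumericMatrix unit_coords, IntegerVector s_values,
                        double r_c) {
  int n = unit_coords.nrow(), ns = s_values.size();
  double r2 = r_c * r_c;
  IntegerVector hits(ns), windows(ns);
  for (int q = 0; q < ns; ++q) {
    int s = s_values[q];
    int w = n - s;
    windows[q] = w > 0 ? w : 0;
    int h = 0;
    for (int i = 0; i + s < n; ++i) {
      double dx = unit_coords(i,0)-unit_coords(i+s,0);
      double dy = unit_coords(i,1)-unit_coords(i+s,1);
      double dz = unit_coords(i,2)-unit_coords(i+s,2);
      if (dx*dx + dy*dy + dz*dz <= r2) ++h;
    }
    hits[q] = h;
  }
  return List::create(_["hits"] = hits, _["windows"] = windows);
}

// per-s mean squared distance between unit-boundary beads (i, i+s), one chain
// [[Rcpp::export]]
NumericVector cpp_msd_by_s(NumericMatrix unit_coords, IntegerVector s_values) {
  int n = unit_coords.nrow(), ns = s_values.size();
  NumericVector out(ns);
  for (int q = 0; q < ns; ++q) {
    int s = s_values[q];
    double acc = 0;
    int w = 0;
    for (int i = 0; i + s < n; ++i, ++w) {
      double dx = unit_coords(i,0)-unit_coords(i+s,0);
      double dy = unit_coords(i,1)-unit_coords(i+s,1);
      double dz = unit_coords(i,2)-unit_coords(i+s,2);
      acc += dx*dx + dy*dy + dz*dz;
    }
    out[q] = w > 0 ? acc / w : NA_REAL;
  }
  return out;
}
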