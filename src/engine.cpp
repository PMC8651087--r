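// Time-stepping engine for flexible-rod gliding agents on a periodic domain.
//
// Units throughout: micrometres, minutes, piconewtons (pN = 1e-12 N).
// Dynamics are overdamped: node velocity = net force / drag coefficient,
// followed by a length-constraint projection that keeps consecutive node
// spacing at L/(N-1).  All coordinate differences use the minimum-image
// convention of the periodic square domain.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;
static const double PI_ = 3.141592653589793238462643383280;

// ---------------------------------------------------------------------------
// Self-contained RNG (xorshift128+ seeded via splitmix64).  The engine owns
// its randomness so that a run is a pure function of (config, seed),
// independent of R's global RNG state.  Separate streams (placement, head
// assignment, labels, clocks, turns) are derived deterministically so that
// ablations do not shift unrelated draws.
// ---------------------------------------------------------------------------
struct Xrng {
  uint64_t s0, s1;
  explicit Xrng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t z = seed;
    for (int i = 0; i < 2; ++i) {
      z += 0x9E3779B97F4A7C15ULL;
      uint64_t t = z;
      t = (t ^ (t >> 30)) * 0xBF58476D1CE4E5B9ULL;
      t = (t ^ (t >> 27)) * 0x94D049BB133111EBULL;
      t = t ^ (t >> 31);
      if (i == 0) s0 = t ? t : 1u; else s1 = t ? t : 2u;
    }
  }
  inline uint64_t nextu() {
    uint64_t x = s0, y = s1;
    s0 = y;
    x ^= x << 23;
    s1 = x ^ y ^ (x >> 17) ^ (y >> 26);
    return s1 + y;
  }
  inline double unif() { return (nextu() >> 11) * (1.0 / 9007199254740992.0); }
  inline int coin() { return (nextu() >> 32) & 1u; }
};

static inline uint64_t substream(uint64_t seed, uint64_t k) {
  return seed * 0x100000001B3ULL + 0x9E3779B97F4A7C15ULL * (k + 1);
}

// ---------------------------------------------------------------------------
// Parameters (mirrors the R-side configuration; validated in R)
// ---------------------------------------------------------------------------
struct Params {
  double L, w, N_nodes_dummy;  // agent geometry
  int    N;
  double k_b, F_T, c, k_a, d_a_max;
  double tau_r, tau_t, turn_duration;
  double L_sim, eta, dt;
  double k_adh_wt, k_adh_oe, k_adh_mismatch, k_adh_cross;
  double dR_e, dR_l, tau_thr;
  double d_thr_ee, d_thr_lat;
  bool   slime_following;
  double slime_cell, omega_s;   // omega_s in rad/min
  double slime_max_age;         // trails older than this are not followed
  int    slime_min_visits;      // visits needed before a trail steers
  double run_duration, snapshot_interval;
  double k_rep;
  double turn_curvature;         // spontaneous front-joint bend during turns (rad)
  bool   agent_pair_counts;
  int    place_attempt_factor;
  double seglen;                 // L/(N-1)
};

static Params parseParams(const List& cfg) {
  Params P;
  P.L = as<double>(cfg["L"]); P.w = as<double>(cfg["w"]);
  P.N = as<int>(cfg["N"]);
  P.k_b = as<double>(cfg["k_b"]); P.F_T = as<double>(cfg["F_T"]);
  P.c = as<double>(cfg["c"]); P.k_a = as<double>(cfg["k_a"]);
  P.d_a_max = as<double>(cfg["d_a_max"]);
  P.tau_r = as<double>(cfg["tau_r"]); P.tau_t = as<double>(cfg["tau_t"]);
  P.turn_duration = as<double>(cfg["turn_duration"]);
  P.L_sim = as<double>(cfg["L_sim"]); P.eta = as<double>(cfg["eta"]);
  P.dt = as<double>(cfg["dt"]);
  P.k_adh_wt = as<double>(cfg["k_adh_wt"]);
  P.k_adh_oe = as<double>(cfg["k_adh_oe"]);
  P.k_adh_mismatch = as<double>(cfg["k_adh_mismatch"]);
  P.k_adh_cross = as<double>(cfg["k_adh_cross"]);
  P.dR_e = as<double>(cfg["dR_e"]); P.dR_l = as<double>(cfg["dR_l"]);
  P.tau_thr = as<double>(cfg["tau_thr"]);
  P.d_thr_ee = as<double>(cfg["d_thr_ee"]); P.d_thr_lat = as<double>(cfg["d_thr_lat"]);
  P.slime_following = as<bool>(cfg["slime_following"]);
  P.slime_cell = as<double>(cfg["slime_cell"]);
  P.slime_max_age = as<double>(cfg["slime_max_age"]);
  P.slime_min_visits = as<int>(cfg["slime_min_visits"]);
  P.omega_s = as<double>(cfg["omega_s_rad"]);
  P.run_duration = as<double>(cfg["run_duration"]);
  P.snapshot_interval = as<double>(cfg["snapshot_interval"]);
  P.k_rep = as<double>(cfg["k_rep"]);
  P.turn_curvature = as<double>(cfg["turn_curvature"]);
  P.agent_pair_counts = as<bool>(cfg["agent_pair_counts"]);
  P.place_attempt_factor = as<int>(cfg["place_attempt_factor"]);
  P.seglen = P.L / (P.N - 1);
  return P;
}

static inline double wrapPi(double a) {
  while (a > PI_) a -= TWO_PI;
  while (a <= -PI_) a += TWO_PI;
  return a;
}

// ---------------------------------------------------------------------------
// Segment-segment closest points (Ericson, Real-Time Collision Detection)
// Returns squared distance; s, u in [0,1] are the barycentric parameters.
// ---------------------------------------------------------------------------
static double closestSegSeg(double p1x, double p1y, double q1x, double q1y,
                            double p2x, double p2y, double q2x, double q2y,
                            double& s, double& u) {
  double d1x = q1x - p1x, d1y = q1y - p1y;
  double d2x = q2x - p2x, d2y = q2y - p2y;
  double rx = p1x - p2x, ry = p1y - p2y;
  double a = d1x * d1x + d1y * d1y;
  double e = d2x * d2x + d2y * d2y;
  double f = d2x * rx + d2y * ry;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = u = 0.0; }
  else if (a <= EPS) { s = 0.0; u = f / e; u = u < 0 ? 0 : (u > 1 ? 1 : u); }
  else {
    double cterm = d1x * rx + d1y * ry;
    if (e <= EPS) { u = 0.0; s = -cterm / a; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
    else {
      double b = d1x * d2x + d1y * d2y;
      double denom = a * e - b * b;
      if (denom > EPS) { s = (b * f - cterm * e) / denom; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
      else s = 0.0;
      u = (b * s + f) / e;
      if (u < 0) { u = 0; s = -cterm / a; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
      else if (u > 1) { u = 1; s = (b - cterm) / a; s = s < 0 ? 0 : (s > 1 ? 1 : s); }
    }
  }
  double cx = p1x + d1x * s - (p2x + d2x * u);
  double cy = p1y + d1y * s - (p2y + d2y * u);
  return cx * cx + cy * cy;
}

// ---------------------------------------------------------------------------
// Uniform cell list on the periodic square
// ---------------------------------------------------------------------------
struct CellList {
  int nc; double cw, L;
  std::vector<int> head_, next_;
  bool brute;
  void build(const std::vector<double>& xs, const std::vector<double>& ys,
             int n, double L_, double hmin) {
    L = L_;
    nc = (int)std::floor(L / hmin);
    brute = nc < 4;
    if (brute) return;
    cw = L / nc;
    head_.assign((size_t)nc * nc, -1);
    next_.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      int cx = (int)(xs[i] / cw); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
      int cy = (int)(ys[i] / cw); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
      int c = cy * nc + cx;
      next_[i] = head_[c];
      head_[c] = i;
    }
  }
  // visit all unordered pairs (i<j) within the 3x3 periodic neighborhood
  template <typename F>
  void pairs(int n, F&& f) const {
    if (brute) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) f(i, j);
      return;
    }
    for (int cy = 0; cy < nc; ++cy) {
      for (int cx = 0; cx < nc; ++cx) {
        int c = cy * nc + cx;
        for (int i = head_[c]; i >= 0; i = next_[i]) {
          for (int oy = -1; oy <= 1; ++oy) {
            int ny = cy + oy; if (ny < 0) ny += nc; else if (ny >= nc) ny -= nc;
            for (int ox = -1; ox <= 1; ++ox) {
              int nx = cx + ox; if (nx < 0) nx += nc; else if (nx >= nc) nx -= nc;
              int c2 = ny * nc + nx;
              for (int j = head_[c2]; j >= 0; j = next_[j])
                if (j > i) f(i, j);
            }
          }
        }
      }
    }
  }
};

// ---------------------------------------------------------------------------
// Verlet neighbor-pair entries.  Adhesion bond state (existence, age) lives
// directly in the node-pair entry; lists are rebuilt from cell lists when
// accumulated displacement exceeds half the skin.
// ---------------------------------------------------------------------------
struct NodePair {
  int i, j;            // global node ids, i < j
  float ka;            // pair adhesion factor (constant over a run)
  uint8_t exists;      // bond currently formed
  uint8_t type;        // 0 lateral, 1 end-end
  float age;
  double formed;
};
struct SegPair { int si, sj; };

struct Sim {
  Params P;
  int M, n;                      // agents, total nodes (M*N)
  double Lh;                     // half domain
  std::vector<double> x, y, ax, ay, fx, fy;
  std::vector<int> head;         // 0 or N-1
  std::vector<int> strain;       // 0 WT, 1 OE, 2 NR
  std::vector<int> allele;
  std::vector<double> clockr, psi, turn_timer, turn_left;
  std::vector<int> turn_sign;
  std::vector<char> suppressed;
  std::vector<int> n_ee, n_lat;
  // slime grid
  int G; double gw;
  std::vector<double> sl_or, sl_t;  // orientation in [0,pi); sl_t < 0 => empty
  std::vector<int> sl_cnt;          // distinct visits (reinforcement)
  double t; long step_no;
  Xrng rng_turns;
  // Verlet lists
  double skin = 0.4;
  std::vector<NodePair> npairs;
  std::vector<SegPair> spairs;
  std::vector<double> ref_x, ref_y;   // positions at last list build
  bool lists_valid = false;
  // logs
  std::vector<int> ev_agent; std::vector<double> ev_t;
  std::vector<int> bl_type, bl_a, bl_b;
  std::vector<double> bl_formed, bl_broke;
  void logBreak(const NodePair& e) {
    bl_type.push_back(e.type); bl_formed.push_back(e.formed);
    bl_broke.push_back(t);
    bl_a.push_back(e.i / P.N + 1); bl_b.push_back(e.j / P.N + 1);
  }

  Sim(const Params& P_, uint64_t seed)
    : P(P_), rng_turns(substream(seed, 4)) {
    Lh = P.L_sim / 2.0;
    G = (int)std::lround(P.L_sim / P.slime_cell);
    if (G < 1) G = 1;
    gw = P.L_sim / G;
    sl_or.assign((size_t)G * G, 0.0);
    sl_t.assign((size_t)G * G, -1.0);
    sl_cnt.assign((size_t)G * G, 0);
    t = 0.0; step_no = 0;
  }

  inline double mi(double d) const {
    if (d > Lh) d -= P.L_sim; else if (d < -Lh) d += P.L_sim;
    return d;
  }
  inline double wrapc(double v) const {
    v -= P.L_sim * std::floor(v / P.L_sim);
    if (v >= P.L_sim) v = 0.0;   // guard against round-off at the edge
    return v;
  }
  inline int tailOf(int a) const { return P.N - 1 - head[a]; }

  double kadh(int a, int b) const {
    int sa = strain[a], sb = strain[b];
    if (sa == 1 && sb == 1) {
      if (allele[a] == allele[b]) return P.k_adh_oe;
      return P.k_adh_mismatch;
    }
    if (sa == 1 || sb == 1) return P.k_adh_cross;
    return P.k_adh_wt;
  }

  // ---- placement ---------------------------------------------------------
  void place(uint64_t seed, const List& composition) {
    NumericVector frac = composition["fraction"];
    IntegerVector scode = composition["strain_code"];
    IntegerVector acode = composition["allele"];
    M = (int)std::lround(P.eta * P.L_sim * P.L_sim);
    if (M < 1) stop("density and domain give zero agents");
    n = M * P.N;
    // strain labels by cumulative rounding, then shuffle
    std::vector<int> lab_s(M), lab_a(M);
    int prev = 0, pos = 0;
    double cum = 0.0;
    for (int k = 0; k < frac.size(); ++k) {
      cum += frac[k];
      int upto = (k == frac.size() - 1) ? M : (int)std::lround(cum * M);
      for (int i = prev; i < upto && pos < M; ++i, ++pos) {
        lab_s[pos] = scode[k]; lab_a[pos] = acode[k];
      }
      prev = upto;
    }
    Xrng rl(substream(seed, 2));
    for (int i = M - 1; i > 0; --i) {
      int j = (int)(rl.unif() * (i + 1)); if (j > i) j = i;
      std::swap(lab_s[i], lab_s[j]); std::swap(lab_a[i], lab_a[j]);
    }
    strain = lab_s; allele = lab_a;

    x.assign(n, 0.0); y.assign(n, 0.0);
    Xrng rp(substream(seed, 0));
    // occupancy grid of placed segment midpoints for overlap rejection
    double hcell = P.seglen + P.w;   // capsule reach
    int gc = std::max(1, (int)std::floor(P.L_sim / hcell));
    double gcw = P.L_sim / gc;
    std::vector<std::vector<int>> occ((size_t)gc * gc);  // stored seg ids
    std::vector<double> sax, say, sbx, sby;              // placed segment endpoints (unwrapped per agent frame)
    long budget = (long)P.place_attempt_factor * M;
    long attempts = 0;
    int placed = 0;
    std::vector<double> cand(2 * P.N);
    while (placed < M) {
      if (++attempts > budget)
        stop("failed to place %d agents at density %g (placed %d); reduce eta or L",
             M, P.eta, placed);
      double cx = rp.unif() * P.L_sim, cy = rp.unif() * P.L_sim;
      double th = rp.unif() * TWO_PI;
      double ux = std::cos(th), uy = std::sin(th);
      for (int j = 0; j < P.N; ++j) {
        double off = (j - (P.N - 1) / 2.0) * P.seglen;
        cand[2 * j] = wrapc(cx + off * ux);
        cand[2 * j + 1] = wrapc(cy + off * uy);
      }
      // overlap test: each candidate segment vs stored segments nearby
      bool ok = true;
      for (int j = 0; j + 1 < P.N && ok; ++j) {
        double mx = wrapc(cand[2 * j] + 0.5 * mi(cand[2 * j + 2] - cand[2 * j]));
        double my = wrapc(cand[2 * j + 1] + 0.5 * mi(cand[2 * j + 3] - cand[2 * j + 1]));
        int ccx = std::min(gc - 1, (int)(mx / gcw)), ccy = std::min(gc - 1, (int)(my / gcw));
        for (int oy = -1; oy <= 1 && ok; ++oy) {
          int nyc = (ccy + oy + gc) % gc;
          for (int ox = -1; ox <= 1 && ok; ++ox) {
            int nxc = (ccx + ox + gc) % gc;
            for (int sid : occ[(size_t)nyc * gc + nxc]) {
              // shift stored segment into candidate frame (minimum image)
              double p2x = sax[sid], p2y = say[sid];
              double q2x = sbx[sid], q2y = sby[sid];
              double smx = p2x + 0.5 * (q2x - p2x), smy = p2y + 0.5 * (q2y - p2y);
              double shx = mi(smx - mx) - (smx - mx);
              double shy = mi(smy - my) - (smy - my);
              double s, u;
              double d2 = closestSegSeg(cand[2 * j], cand[2 * j + 1],
                                        wrapc_rel(cand[2 * j], cand[2 * j + 2]),
                                        wrapc_rel(cand[2 * j + 1], cand[2 * j + 3]),
                                        p2x + shx, p2y + shy, q2x + shx, q2y + shy,
                                        s, u);
              if (d2 < P.w * P.w) { ok = false; break; }
            }
          }
        }
      }
      if (!ok) continue;
      for (int j = 0; j < P.N; ++j) {
        x[placed * P.N + j] = cand[2 * j];
        y[placed * P.N + j] = cand[2 * j + 1];
      }
      for (int j = 0; j + 1 < P.N; ++j) {
        int gid = placed * (P.N - 1) + j;
        double p1x = cand[2 * j], p1y = cand[2 * j + 1];
        double q1x = wrapc_rel(p1x, cand[2 * j + 2]);
        double q1y = wrapc_rel(p1y, cand[2 * j + 3]);
        sax.push_back(p1x); say.push_back(p1y);
        sbx.push_back(q1x); sby.push_back(q1y);
        double mx = wrapc(p1x + 0.5 * (q1x - p1x)), my = wrapc(p1y + 0.5 * (q1y - p1y));
        occ[(size_t)std::min(gc - 1, (int)(my / gcw)) * gc + std::min(gc - 1, (int)(mx / gcw))]
          .push_back(gid);
      }
      ++placed;
    }
    finishInit(seed);
  }

  // bring b next to a by minimum image (returns the unwrapped coordinate)
  inline double wrapc_rel(double a, double b) const { return a + mi(b - a); }

  // explicit initial condition (fixtures): straight agents from centers/angles
  void placeExplicit(uint64_t seed, const List& init) {
    NumericVector cx = init["x"], cy = init["y"], th = init["theta"];
    IntegerVector hd = init["head"], sc = init["strain_code"], al = init["allele"];
    M = cx.size(); n = M * P.N;
    x.assign(n, 0.0); y.assign(n, 0.0);
    strain.assign(M, 0); allele.assign(M, 1);
    for (int a = 0; a < M; ++a) {
      double ux = std::cos(th[a]), uy = std::sin(th[a]);
      for (int j = 0; j < P.N; ++j) {
        double off = (j - (P.N - 1) / 2.0) * P.seglen;
        x[a * P.N + j] = wrapc(cx[a] + off * ux);
        y[a * P.N + j] = wrapc(cy[a] + off * uy);
      }
      strain[a] = sc[a]; allele[a] = al[a];
    }
    finishInit(seed);
    for (int a = 0; a < M; ++a) {
      head[a] = hd[a] ? (P.N - 1) : 0;
      psi[a] = bodyHeading(a);
    }
    if (init.containsElementNamed("clock")) {
      NumericVector cl = init["clock"];
      for (int a = 0; a < M; ++a) clockr[a] = cl[a];
    }
    if (init.containsElementNamed("turn_timer")) {
      NumericVector tt = init["turn_timer"];
      for (int a = 0; a < M; ++a) turn_timer[a] = tt[a];
    }
  }

  void finishInit(uint64_t seed) {
    ax = x; ay = y;
    fx.assign(n, 0.0); fy.assign(n, 0.0);
    head.assign(M, 0);
    clockr.assign(M, 0.0); psi.assign(M, 0.0);
    turn_timer.assign(M, 0.0); turn_left.assign(M, 0.0);
    turn_sign.assign(M, 0);
    suppressed.assign(M, 0);
    n_ee.assign(M, 0); n_lat.assign(M, 0);
    Xrng rh(substream(seed, 1)), rc(substream(seed, 3));
    for (int a = 0; a < M; ++a) {
      head[a] = rh.coin() ? (P.N - 1) : 0;
      if (strain[a] == 2) clockr[a] = 0.0;
      else clockr[a] = std::isfinite(P.tau_r) ? rc.unif() * P.tau_r : 0.0;
      turn_timer[a] = std::isfinite(P.tau_t) ? rc.unif() * P.tau_t : 0.0;
      psi[a] = bodyHeading(a);
    }
  }

  inline double bodyHeading(int a) const {
    int h = a * P.N + head[a];
    int nk = a * P.N + (head[a] == 0 ? 1 : P.N - 2);
    return std::atan2(mi(y[h] - y[nk]), mi(x[h] - x[nk]));
  }

  // ---- pairwise interactions (bonds + repulsion) ------------------------
  // Stateless node-pair kernel (adhesion force only); used by the
  // force-inspection entry point and equivalent to the in-run force rule.
  void nodePairKernel(int i, int j, double* fxv, double* fyv) {
    int aA = i / P.N, aB = j / P.N;
    if (aA == aB) return;
    double ka = kadh(aA, aB);
    if (ka <= 0.0) return;
    double dx = mi(x[j] - x[i]), dy = mi(y[j] - y[i]);
    double d2 = dx * dx + dy * dy;
    if (d2 >= P.d_thr_ee * P.d_thr_ee) return;
    double d = std::sqrt(d2);
    int jA = i % P.N, jB = j % P.N;
    bool ee = (jA == head[aA] && jB == tailOf(aB)) ||
              (jA == tailOf(aA) && jB == head[aB]);
    double thr = ee ? P.d_thr_ee : P.d_thr_lat;
    if (d >= thr) return;
    if (d > P.w) {
      double fm = ka * (d - P.w) / P.w * P.F_T;
      double ex = dx / d, ey = dy / d;
      fxv[i] += fm * ex; fyv[i] += fm * ey;
      fxv[j] -= fm * ex; fyv[j] -= fm * ey;
    }
  }

  void segPairKernel(int si, int sj, const std::vector<double>& smx,
                     const std::vector<double>& smy, double* fxv, double* fyv) {
    int aA = si / (P.N - 1), aB = sj / (P.N - 1);
    int jA = si % (P.N - 1), jB = sj % (P.N - 1);
    if (aA == aB && std::abs(jA - jB) < 2) return;  // share a node or adjacent
    double ddx = mi(smx[sj] - smx[si]), ddy = mi(smy[sj] - smy[si]);
    double reach = P.w + P.seglen;   // midpoint cutoff
    if (ddx * ddx + ddy * ddy >= reach * reach) return;
    int i0 = aA * P.N + jA, j0 = aB * P.N + jB;
    double p1x = x[i0], p1y = y[i0];
    double q1x = wrapc_rel(p1x, x[i0 + 1]), q1y = wrapc_rel(p1y, y[i0 + 1]);
    // shift segment B into A's frame via midpoint minimum image
    double shx = mi(smx[sj] - smx[si]) - (smx[sj] - smx[si]);
    double shy = mi(smy[sj] - smy[si]) - (smy[sj] - smy[si]);
    double p2x = x[j0], p2y = y[j0];
    double q2x = wrapc_rel(p2x, x[j0 + 1]), q2y = wrapc_rel(p2y, y[j0 + 1]);
    p2x += shx; q2x += shx; p2y += shy; q2y += shy;
    double s, u;
    double d2 = closestSegSeg(p1x, p1y, q1x, q1y, p2x, p2y, q2x, q2y, s, u);
    if (d2 >= P.w * P.w) return;
    double d = std::sqrt(d2);
    double nx, ny;
    if (d > 1e-9) {
      nx = (p1x + (q1x - p1x) * s - (p2x + (q2x - p2x) * u)) / d;
      ny = (p1y + (q1y - p1y) * s - (p2y + (q2y - p2y) * u)) / d;
    } else {  // coincident closest points: push along A's normal
      double tx = q1x - p1x, ty = q1y - p1y;
      double tn = std::sqrt(tx * tx + ty * ty);
      nx = -ty / tn; ny = tx / tn;
    }
    double fm = P.k_rep * (P.w - d);
    // distribute to segment end nodes by barycentric weights
    fxv[i0]     += fm * nx * (1 - s); fyv[i0]     += fm * ny * (1 - s);
    fxv[i0 + 1] += fm * nx * s;       fyv[i0 + 1] += fm * ny * s;
    fxv[j0]     -= fm * nx * (1 - u); fyv[j0]     -= fm * ny * (1 - u);
    fxv[j0 + 1] -= fm * nx * u;       fyv[j0 + 1] -= fm * ny * u;
  }

  void segMidpoints(std::vector<double>& smx, std::vector<double>& smy) const {
    int ns = M * (P.N - 1);
    smx.resize(ns); smy.resize(ns);
    for (int a = 0; a < M; ++a)
      for (int j = 0; j + 1 < P.N; ++j) {
        int i0 = a * P.N + j, sid = a * (P.N - 1) + j;
        smx[sid] = wrapc(x[i0] + 0.5 * mi(x[i0 + 1] - x[i0]));
        smy[sid] = wrapc(y[i0] + 0.5 * mi(y[i0 + 1] - y[i0]));
      }
  }

  // stateless full pass (spatial hash or brute force); oracle entry point
  void forcesStateless(bool all_pairs) {
    double* fxv = fx.data();
    double* fyv = fy.data();
    if (all_pairs) {
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) nodePairKernel(i, j, fxv, fyv);
    } else {
      CellList cl;
      cl.build(x, y, n, P.L_sim, P.d_thr_ee);
      cl.pairs(n, [&](int i, int j) { nodePairKernel(i, j, fxv, fyv); });
    }
    std::vector<double> smx, smy;
    segMidpoints(smx, smy);
    int ns = M * (P.N - 1);
    if (all_pairs) {
      for (int i = 0; i < ns; ++i)
        for (int j = i + 1; j < ns; ++j) segPairKernel(i, j, smx, smy, fxv, fyv);
    } else {
      CellList cl;
      cl.build(smx, smy, ns, P.L_sim, P.w + P.seglen);
      cl.pairs(ns, [&](int i, int j) { segPairKernel(i, j, smx, smy, fxv, fyv); });
    }
  }

  void rebuildLists() {
    // carry over live bond state keyed by node-pair id
    std::unordered_map<uint64_t, NodePair> live;
    for (const auto& e : npairs)
      if (e.exists)
        live.emplace(((uint64_t)(uint32_t)e.i << 32) | (uint32_t)e.j, e);
    npairs.clear();
    double cut_n = P.d_thr_ee + skin;
    {
      CellList cl;
      cl.build(x, y, n, P.L_sim, cut_n);
      cl.pairs(n, [&](int i, int j) {
        int aA = i / P.N, aB = j / P.N;
        if (aA == aB) return;
        double ka = kadh(aA, aB);
        if (ka <= 0.0) return;
        double dx = mi(x[j] - x[i]), dy = mi(y[j] - y[i]);
        if (dx * dx + dy * dy >= cut_n * cut_n) return;
        int lo = std::min(i, j), hi = std::max(i, j);
        NodePair e{lo, hi, (float)ka, 0, 0, 0.0f, 0.0};
        auto it = live.find(((uint64_t)(uint32_t)lo << 32) | (uint32_t)hi);
        if (it != live.end()) { e = it->second; live.erase(it); }
        npairs.push_back(e);
      });
    }
    // any live bond not re-listed has escaped the reach: log as broken
    for (const auto& kv : live) logBreak(kv.second);
    spairs.clear();
    std::vector<double> smx, smy;
    segMidpoints(smx, smy);
    int ns = M * (P.N - 1);
    double cut_s = P.w + P.seglen + skin;
    {
      CellList cl;
      cl.build(smx, smy, ns, P.L_sim, cut_s);
      cl.pairs(ns, [&](int si, int sj) {
        int aA = si / (P.N - 1), aB = sj / (P.N - 1);
        int jA = si % (P.N - 1), jB = sj % (P.N - 1);
        if (aA == aB && std::abs(jA - jB) < 2) return;
        double dx = mi(smx[sj] - smx[si]), dy = mi(smy[sj] - smy[si]);
        if (dx * dx + dy * dy >= cut_s * cut_s) return;
        spairs.push_back(SegPair{si, sj});
      });
    }
    ref_x = x; ref_y = y;
    lists_valid = true;
  }

  bool listsStale() const {
    if (!lists_valid) return true;
    double lim2 = 0.45 * skin * 0.45 * skin;
    for (int i = 0; i < n; ++i) {
      double dx = mi(x[i] - ref_x[i]), dy = mi(y[i] - ref_y[i]);
      if (dx * dx + dy * dy > lim2) return true;
    }
    return false;
  }

  // in-run pass: bond bookkeeping + adhesion forces + repulsion
  void verletForces() {
    if (listsStale()) rebuildLists();
    std::fill(n_ee.begin(), n_ee.end(), 0);
    std::fill(n_lat.begin(), n_lat.end(), 0);
    std::fill(suppressed.begin(), suppressed.end(), 0);
    double* fxv = fx.data();
    double* fyv = fy.data();
    for (auto& e : npairs) {
      int i = e.i, j = e.j;
      double dx = mi(x[j] - x[i]), dy = mi(y[j] - y[i]);
      double d2 = dx * dx + dy * dy;
      if (d2 >= P.d_thr_ee * P.d_thr_ee) {
        if (e.exists) { logBreak(e); e.exists = 0; e.age = 0.0f; }
        continue;
      }
      int aA = i / P.N, aB = j / P.N;
      int jA = i % P.N, jB = j % P.N;
      uint8_t type = ((jA == head[aA] && jB == tailOf(aB)) ||
                      (jA == tailOf(aA) && jB == head[aB])) ? 1 : 0;
      double thr = type ? P.d_thr_ee : P.d_thr_lat;
      if (d2 >= thr * thr) {
        if (e.exists) { logBreak(e); e.exists = 0; e.age = 0.0f; }
        continue;
      }
      double d = std::sqrt(d2);
      if (false) {
        if (e.exists) { logBreak(e); e.exists = 0; e.age = 0.0f; }
        continue;
      }
      if (!e.exists) {
        e.exists = 1; e.type = type; e.age = 0.0f; e.formed = t;
      } else if (e.type != type) {   // head/tail role change: bond resets
        logBreak(e);
        e.type = type; e.age = 0.0f; e.formed = t;
      } else {
        e.age += (float)P.dt;
      }
      if (e.age > P.tau_thr && !P.agent_pair_counts) {
        if (type) { ++n_ee[aA]; ++n_ee[aB]; }
        else      { ++n_lat[aA]; ++n_lat[aB]; }
      }
      if (d > P.w) {
        double fm = e.ka * (d - P.w) / P.w * P.F_T;
        double ex = dx / d, ey = dy / d;
        fxv[i] += fm * ex; fyv[i] += fm * ey;
        fxv[j] -= fm * ex; fyv[j] -= fm * ey;
      }
    }
    if (P.agent_pair_counts) recountAgentPairs();
    // an agent counts as reversal-suppressed when its aged contacts stall
    // the clock entirely (total suppression weight >= 1)
    for (int a = 0; a < M; ++a)
      suppressed[a] = (n_ee[a] * P.dR_e + n_lat[a] * P.dR_l >= 1.0 - 1e-9);
    std::vector<double> smx, smy;
    segMidpoints(smx, smy);
    for (const auto& sp : spairs)
      segPairKernel(sp.si, sp.sj, smx, smy, fxv, fyv);
  }

  // alternative suppression count: distinct partner agents, not node pairs
  void recountAgentPairs() {
    std::unordered_map<uint64_t, int> seen;  // agent pair -> type flags
    for (const auto& e : npairs) {
      if (!e.exists || e.age <= P.tau_thr) continue;
      int aA = e.i / P.N, aB = e.j / P.N;
      uint64_t pk = ((uint64_t)(uint32_t)std::min(aA, aB) << 32) |
                    (uint32_t)std::max(aA, aB);
      int flag = e.type == 1 ? 1 : 2;
      int& fl = seen[pk];
      if (fl & flag) continue;
      fl |= flag;
      if (flag == 1) { ++n_ee[aA]; ++n_ee[aB]; }
      else           { ++n_lat[aA]; ++n_lat[aB]; }
    }
  }

  // ---- internal forces ---------------------------------------------------
  void internalForces() {
    double Fp = P.F_T / (P.N - 1);
    for (int a = 0; a < M; ++a) {
      int base = a * P.N;
      int h = head[a], tl = P.N - 1 - h;
      int s = (h == P.N - 1) ? 1 : -1;
      // propulsion on every node except the tail, toward the forward neighbor
      for (int j = 0; j < P.N; ++j) {
        if (j == tl || j == h) continue;
        int i = base + j, k = base + j + s;
        double dx = mi(x[k] - x[i]), dy = mi(y[k] - y[i]);
        double dn = std::sqrt(dx * dx + dy * dy);
        if (dn < 1e-9) stop("degenerate geometry: coincident nodes in agent %d", a + 1);
        fx[i] += Fp * dx / dn; fy[i] += Fp * dy / dn;
      }
      // head node: steering-adjusted direction
      double dir;
      double thb = bodyHeading(a);
      if (turn_sign[a] != 0) {
        dir = thb + turn_sign[a] * PI_ / 2.0;
        psi[a] = thb;                       // no slime steering during a turn
      } else {
        double dmax = P.omega_s * P.dt;
        double target, delta;
        // the head pole senses trails in its own and the 8 surrounding
        // grid cells; the most reinforced fresh trail wins
        int hn = base + h;
        int hcx = (int)(x[hn] / gw); if (hcx >= G) hcx = G - 1;
        int hcy = (int)(y[hn] / gw); if (hcy >= G) hcy = G - 1;
        int best = -1, bestc = 0;
        if (P.slime_following) {
          for (int oy = -1; oy <= 1; ++oy) {
            int cyy = hcy + oy; if (cyy < 0) cyy += G; else if (cyy >= G) cyy -= G;
            for (int ox = -1; ox <= 1; ++ox) {
              int cxx = hcx + ox; if (cxx < 0) cxx += G; else if (cxx >= G) cxx -= G;
              int c = cyy * G + cxx;
              if (sl_t[c] >= 0.0 && t - sl_t[c] <= P.slime_max_age &&
                  sl_cnt[c] >= P.slime_min_visits && sl_cnt[c] > bestc) {
                best = c; bestc = sl_cnt[c];
              }
            }
          }
        }
        if (best >= 0) {
          double o = sl_or[best];
          double d1 = wrapPi(o - psi[a]);
          double d2 = wrapPi(o + PI_ - psi[a]);
          delta = (std::fabs(d1) <= std::fabs(d2)) ? d1 : d2;
        } else {
          target = thb;
          delta = wrapPi(target - psi[a]);
        }
        if (delta > dmax) delta = dmax; else if (delta < -dmax) delta = -dmax;
        psi[a] = wrapPi(psi[a] + delta);
        double db = wrapPi(psi[a] - thb);   // keep propulsion forward-facing
        if (db > PI_ / 2) psi[a] = wrapPi(thb + PI_ / 2);
        else if (db < -PI_ / 2) psi[a] = wrapPi(thb - PI_ / 2);
        dir = psi[a];
      }
      fx[base + h] += Fp * std::cos(dir);
      fy[base + h] += Fp * std::sin(dir);
      // bending at interior joints: E = k_b * (phi - phi0)^2 / 2.
      // During an active turn the two joints behind the head acquire a
      // spontaneous curvature (the cell flexes its front to steer).
      for (int j = 1; j + 1 < P.N; ++j) {
        int im = base + j - 1, i0 = base + j, ip = base + j + 1;
        double axv = mi(x[i0] - x[im]), ayv = mi(y[i0] - y[im]);
        double bxv = mi(x[ip] - x[i0]), byv = mi(y[ip] - y[i0]);
        double phi = std::atan2(axv * byv - ayv * bxv, axv * bxv + ayv * byv);
        double phi0 = 0.0;
        if (turn_sign[a] != 0 && (j == 1 || j == 2 || j == P.N - 2 || j == P.N - 3)) {
          bool frontJoint = (h == P.N - 1) ? (j >= P.N - 3) : (j <= 2);
          if (frontJoint) {
            // joint angle phi is defined tail-to-head along increasing j;
            // flip the sign so the bend turns the HEAD by +90 deg * sign
            phi0 = P.turn_curvature * ((h == P.N - 1) ? turn_sign[a] : -turn_sign[a]);
          }
        }
        double a2 = axv * axv + ayv * ayv, b2 = bxv * bxv + byv * byv;
        double gmx = -ayv / a2, gmy = axv / a2;        // d phi / d x_{j-1}
        double gpx = -byv / b2, gpy = bxv / b2;        // d phi / d x_{j+1}
        double mom = -P.k_b * (phi - phi0);
        fx[im] += mom * gmx; fy[im] += mom * gmy;
        fx[ip] += mom * gpx; fy[ip] += mom * gpy;
        fx[i0] -= mom * (gmx + gpx); fy[i0] -= mom * (gmy + gpy);
      }
      // substrate focal-adhesion springs: resist transverse displacement only
      for (int j = 0; j < P.N; ++j) {
        int i = base + j;
        int jm = j > 0 ? j - 1 : 0, jp = j + 1 < P.N ? j + 1 : P.N - 1;
        double txv = mi(x[base + jp] - x[base + jm]);
        double tyv = mi(y[base + jp] - y[base + jm]);
        double tn = std::sqrt(txv * txv + tyv * tyv);
        if (tn < 1e-9) continue;
        double nxv = -tyv / tn, nyv = txv / tn;
        double dxv = mi(x[i] - ax[i]), dyv = mi(y[i] - ay[i]);
        double proj = dxv * nxv + dyv * nyv;
        fx[i] -= P.k_a * proj * nxv;
        fy[i] -= P.k_a * proj * nyv;
      }
    }
  }

  inline int slCell(int node) const {
    int cx = (int)(x[node] / gw); if (cx >= G) cx = G - 1;
    int cy = (int)(y[node] / gw); if (cy >= G) cy = G - 1;
    return cy * G + cx;
  }

  // ---- one time step -----------------------------------------------------
  void step() {
    ++step_no;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    verletForces();
    internalForces();
    // overdamped update
    double inv_c_dt = P.dt / P.c;
    for (int i = 0; i < n; ++i) {
      x[i] += fx[i] * inv_c_dt;
      y[i] += fy[i] * inv_c_dt;
    }
    // length-constraint projection (Gauss-Seidel, symmetric moves).
    // The full sweep count is always run: in dense packs a slack spacing
    // constraint measurably degrades the nematic order of rotating
    // aggregates, so the solver is kept tight.
    for (int sweep = 0; sweep < 6; ++sweep) {
      for (int a = 0; a < M; ++a) {
        int base = a * P.N;
        for (int j = 0; j + 1 < P.N; ++j) {
          int i = base + j, k = i + 1;
          double dx = mi(x[k] - x[i]), dy = mi(y[k] - y[i]);
          double dn = std::sqrt(dx * dx + dy * dy);
          if (dn < 1e-12) continue;
          double corr = 0.5 * (dn - P.seglen) / dn;
          x[i] += corr * dx; y[i] += corr * dy;
          x[k] -= corr * dx; y[k] -= corr * dy;
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]))
        stop("non-finite coordinate for agent %d node %d at t=%g",
             i / P.N + 1, i % P.N + 1, t);
      x[i] = wrapc(x[i]); y[i] = wrapc(y[i]);
    }
    // substrate anchors: detach + instant reattach past break distance
    for (int i = 0; i < n; ++i) {
      double dxv = mi(x[i] - ax[i]), dyv = mi(y[i] - ay[i]);
      if (dxv * dxv + dyv * dyv >= P.d_a_max * P.d_a_max) { ax[i] = x[i]; ay[i] = y[i]; }
    }
    t = step_no * P.dt;
    // slime deposition from the tail node
    for (int a = 0; a < M; ++a) {
      int tl = tailOf(a), base = a * P.N;
      int nb = base + (tl == 0 ? 1 : P.N - 2);
      int i = base + tl;
      double dx = mi(x[nb] - x[i]), dy = mi(y[nb] - y[i]);
      double o = std::atan2(dy, dx);
      if (o < 0) o += PI_;           // apolar: store in [0, pi)
      if (o >= PI_) o -= PI_;
      int c = slCell(i);
      // a deposit more than a body-transit after the previous one counts
      // as a distinct visit; stale trails restart the count
      if (sl_t[c] < 0.0 || t - sl_t[c] > P.slime_max_age) sl_cnt[c] = 1;
      else if (t - sl_t[c] > 1.0) ++sl_cnt[c];
      sl_or[c] = o; sl_t[c] = t;
    }
    // reversal clocks (suppression counts from this step's bond pass)
    for (int a = 0; a < M; ++a) {
      if (strain[a] == 2) { clockr[a] = 0.0; continue; }
      if (std::isfinite(P.tau_r) && clockr[a] >= P.tau_r) {
        ev_agent.push_back(a + 1); ev_t.push_back(t);
        head[a] = P.N - 1 - head[a];
        clockr[a] = 0.0;
        turn_sign[a] = 0;
        psi[a] = bodyHeading(a);
      } else {
        double inc = P.dt * (1.0 - n_ee[a] * P.dR_e - n_lat[a] * P.dR_l);
        clockr[a] += inc;
        if (clockr[a] < 0) clockr[a] = 0.0;
      }
    }
    // random 90-degree turns
    for (int a = 0; a < M; ++a) {
      if (turn_sign[a] != 0) {
        turn_left[a] -= P.dt;
        if (turn_left[a] <= 0) turn_sign[a] = 0;
      }
      if (!std::isfinite(P.tau_t)) continue;
      turn_timer[a] += P.dt;
      if (turn_timer[a] >= P.tau_t && turn_sign[a] == 0) {
        turn_sign[a] = rng_turns.coin() ? 1 : -1;
        turn_left[a] = P.turn_duration;
        turn_timer[a] = 0.0;
      }
    }
  }
};

// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_engine(List cfg, int seed) {
  Params P = parseParams(cfg);
  Sim sim(P, (uint64_t)(uint32_t)seed);
  if (cfg.containsElementNamed("init") && !Rf_isNull(cfg["init"]))
    sim.placeExplicit((uint64_t)(uint32_t)seed, cfg["init"]);
  else
    sim.place((uint64_t)(uint32_t)seed, cfg["composition"]);

  int n_snap = (int)std::floor(P.run_duration / P.snapshot_interval + 1e-9) + 1;
  NumericMatrix X(sim.n, n_snap), Y(sim.n, n_snap);
  IntegerMatrix H(sim.M, n_snap);
  NumericMatrix CK(sim.M, n_snap);
  LogicalMatrix SP(sim.M, n_snap);
  NumericVector times(n_snap);

  int rec = 0;
  auto record = [&](void) {
    for (int i = 0; i < sim.n; ++i) { X(i, rec) = sim.x[i]; Y(i, rec) = sim.y[i]; }
    for (int a = 0; a < sim.M; ++a) {
      H(a, rec) = sim.head[a];
      CK(a, rec) = sim.clockr[a];
      SP(a, rec) = sim.suppressed[a] != 0;
    }
    times[rec] = sim.t;
    ++rec;
  };
  record();
  double next_snap = P.snapshot_interval;
  while (sim.t < P.run_duration - 1e-9 && rec < n_snap) {
    sim.step();
    if (sim.t >= next_snap - 1e-9) {
      record();
      next_snap += P.snapshot_interval;
    }
    if ((sim.step_no & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // surviving bonds reported as censored (broke = NA)
  std::vector<int> open_type, open_a, open_b; std::vector<double> open_formed;
  for (const auto& e : sim.npairs) {
    if (!e.exists) continue;
    open_type.push_back(e.type);
    open_formed.push_back(e.formed);
    open_a.push_back(e.i / P.N + 1); open_b.push_back(e.j / P.N + 1);
  }
  int nb = (int)sim.bl_type.size(), no = (int)open_type.size();
  IntegerVector btype(nb + no), ba(nb + no), bb(nb + no);
  NumericVector bformed(nb + no), bbroke(nb + no);
  for (int i = 0; i < nb; ++i) {
    btype[i] = sim.bl_type[i]; bformed[i] = sim.bl_formed[i]; bbroke[i] = sim.bl_broke[i];
    ba[i] = sim.bl_a[i]; bb[i] = sim.bl_b[i];
  }
  for (int i = 0; i < no; ++i) {
    btype[nb + i] = open_type[i]; bformed[nb + i] = open_formed[i];
    bbroke[nb + i] = NA_REAL;
    ba[nb + i] = open_a[i]; bb[nb + i] = open_b[i];
  }

  return List::create(
    _["times"] = times,
    _["x"] = X, _["y"] = Y,
    _["head"] = H, _["clock"] = CK, _["suppressed"] = SP,
    _["strain_code"] = IntegerVector(sim.strain.begin(), sim.strain.end()),
    _["allele"] = IntegerVector(sim.allele.begin(), sim.allele.end()),
    _["M"] = sim.M, _["N"] = P.N,
    _["reversal_agent"] = IntegerVector(sim.ev_agent.begin(), sim.ev_agent.end()),
    _["reversal_time"] = NumericVector(sim.ev_t.begin(), sim.ev_t.end()),
    _["bond_type"] = btype, _["bond_formed"] = bformed, _["bond_broke"] = bbroke,
    _["bond_agent_a"] = ba, _["bond_agent_b"] = bb,
    _["slime_orientation"] = NumericVector(sim.sl_or.begin(), sim.sl_or.end()),
    _["slime_time"] = NumericVector(sim.sl_t.begin(), sim.sl_t.end()),
    _["slime_dim"] = sim.G);
}

// Pairwise interaction forces (adhesion + excluded-volume repulsion) for an
// explicit node configuration; used to cross-check the spatially hashed path
// against brute-force enumeration.
// [[Rcpp::export]]
NumericMatrix interaction_forces_engine(List cfg, NumericMatrix pos,
                                        IntegerVector heads,
                                        IntegerVector strain_code,
                                        IntegerVector allele,
                                        bool all_pairs) {
  Params P = parseParams(cfg);
  Sim sim(P, 1);
  sim.M = heads.size();
  sim.n = sim.M * P.N;
  if (pos.nrow() != sim.n) stop("pos must have M*N rows");
  sim.x.resize(sim.n); sim.y.resize(sim.n);
  for (int i = 0; i < sim.n; ++i) { sim.x[i] = pos(i, 0); sim.y[i] = pos(i, 1); }
  sim.strain.assign(strain_code.begin(), strain_code.end());
  sim.allele.assign(allele.begin(), allele.end());
  sim.head.assign(heads.begin(), heads.end());
  sim.fx.assign(sim.n, 0.0); sim.fy.assign(sim.n, 0.0);
  sim.n_ee.assign(sim.M, 0); sim.n_lat.assign(sim.M, 0);
  sim.suppressed.assign(sim.M, 0);
  sim.forcesStateless(all_pairs);
  NumericMatrix out(sim.n, 2);
  for (int i = 0; i < sim.n; ++i) { out(i, 0) = sim.fx[i]; out(i, 1) = sim.fy[i]; }
  return out;
}

// Reversal-clock recursion as used by the engine, exposed for oracle tests.
// [[Rcpp::export]]
List clock_update_engine(double r, int n_ee, int n_lat, double dt,
                         double tau_r, double dR_e, double dR_l) {
  if (n_ee < 0 || n_lat < 0) stop("bond counts must be non-negative");
  bool fired = std::isfinite(tau_r) && r >= tau_r;
  double rn;
  if (fired) rn = 0.0;
  else {
    rn = r + dt * (1.0 - n_ee * dR_e - n_lat * dR_l);
    if (rn < 0) rn = 0.0;
  }
  return List::create(_["r"] = rn, _["fired"] = fired);
}
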