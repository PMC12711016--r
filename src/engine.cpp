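// Agent-based simulator core: toroidal grid world, NetLogo-style phase
// scheduler, point-to-point spreading, and the enhanced information
// environment (posting/consumption, stigmergic infection, homophily).
// All randomness is drawn from R's RNG so that set.seed() on the R side
// gives bit-identical runs on any platform.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double EPS = 1e-9;

// ---------------------------------------------------------------------------
// Parameters and world state
// ---------------------------------------------------------------------------

struct Params {
  int M, N;
  double beta, sigma, gamma, xi;
  int has_E, rec_mode, has_xi;     // rec_mode: 0 none, 1 I->S, 2 I->R
  double r, theta, d_c, d_e, e_c;
  double growth, q_max;
  double contact_scale;            // multiplier mapping beta to per-contact prob
  int enhanced, homophily;
  double group_fraction;
  double I_R;                      // true-information regrowth (enhanced)
  double L_M_S, L_M_I, L_P_S, L_P_I;
  int D_P_S, D_P_I;
  double post_quantum, consume_bite;
  double e0;
  int I0, E0;
};

struct World {
  int M, N, tick;
  std::vector<int> x, y, status, group, post_timer; // status 0=S 1=E 2=I 3=R
  std::vector<char> armed;
  std::vector<double> heading, energy;
  std::vector<double> qt, qf;      // row-major cell index = y*M + x
};

static Params unpack_params(List cfg) {
  Params p;
  p.M = as<int>(cfg["M"]); p.N = as<int>(cfg["N"]);
  p.beta = as<double>(cfg["beta"]); p.sigma = as<double>(cfg["sigma"]);
  p.gamma = as<double>(cfg["gamma"]); p.xi = as<double>(cfg["xi"]);
  p.has_E = as<int>(cfg["has_E"]); p.rec_mode = as<int>(cfg["rec_mode"]);
  p.has_xi = as<int>(cfg["has_xi"]);
  p.r = as<double>(cfg["r"]); p.theta = as<double>(cfg["theta"]);
  p.d_c = as<double>(cfg["d_c"]); p.d_e = as<double>(cfg["d_e"]);
  p.e_c = as<double>(cfg["e_c"]);
  p.growth = as<double>(cfg["growth"]); p.q_max = as<double>(cfg["q_max"]);
  p.contact_scale = as<double>(cfg["contact_scale"]);
  p.enhanced = as<int>(cfg["enhanced"]); p.homophily = as<int>(cfg["homophily"]);
  p.group_fraction = as<double>(cfg["group_fraction"]);
  p.I_R = as<double>(cfg["I_R"]);
  p.L_M_S = as<double>(cfg["L_M_S"]); p.L_M_I = as<double>(cfg["L_M_I"]);
  p.L_P_S = as<double>(cfg["L_P_S"]); p.L_P_I = as<double>(cfg["L_P_I"]);
  p.D_P_S = as<int>(cfg["D_P_S"]); p.D_P_I = as<int>(cfg["D_P_I"]);
  p.post_quantum = as<double>(cfg["post_quantum"]);
  p.consume_bite = as<double>(cfg["consume_bite"]);
  p.e0 = as<double>(cfg["e0"]);
  p.I0 = as<int>(cfg["I0"]); p.E0 = as<int>(cfg["E0"]);
  return p;
}

static World unpack_world(List w) {
  World W;
  W.M = as<int>(w["M"]); W.N = as<int>(w["N"]); W.tick = as<int>(w["tick"]);
  W.x = as<std::vector<int> >(w["x"]);
  W.y = as<std::vector<int> >(w["y"]);
  W.status = as<std::vector<int> >(w["status"]);
  W.group = as<std::vector<int> >(w["group"]);
  W.post_timer = as<std::vector<int> >(w["post_timer"]);
  std::vector<int> armed = as<std::vector<int> >(w["armed"]);
  W.armed.assign(armed.begin(), armed.end());
  W.heading = as<std::vector<double> >(w["heading"]);
  W.energy = as<std::vector<double> >(w["energy"]);
  W.qt = as<std::vector<double> >(w["q_true"]);
  W.qf = as<std::vector<double> >(w["q_false"]);
  return W;
}

static List pack_world(const World &W) {
  std::vector<int> armed(W.armed.begin(), W.armed.end());
  return List::create(
    _["M"] = W.M, _["N"] = W.N, _["tick"] = W.tick,
    _["x"] = W.x, _["y"] = W.y, _["status"] = W.status,
    _["group"] = W.group, _["post_timer"] = W.post_timer,
    _["armed"] = armed, _["heading"] = W.heading, _["energy"] = W.energy,
    _["q_true"] = W.qt, _["q_false"] = W.qf);
}

// minimal-image signed delta on a ring of size M
static inline double mindelta(int a, int b, int M) {
  double d = (double)(a - b);
  d -= M * std::floor(d / M + 0.5);
  return d;
}

static inline int wrapc(int v, int M) { int r = v % M; return r < 0 ? r + M : r; }

// Fisher-Yates permutation of 0..n-1 using R's RNG
static std::vector<int> rand_perm(int n) {
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(p[i], p[j]);
  }
  return p;
}

// visible-cell offset table within radius rad (excluding the agent's own
// cell), sorted by angle so a view cone maps to contiguous slices
struct Offset { int dx, dy; double dist, ang; };
static bool by_angle(const Offset &a, const Offset &b) { return a.ang < b.ang; }
static std::vector<Offset> make_offsets(double rad) {
  std::vector<Offset> off;
  int R = (int)std::ceil(rad);
  for (int dy = -R; dy <= R; ++dy)
    for (int dx = -R; dx <= R; ++dx) {
      if (dx == 0 && dy == 0) continue;
      double d = std::sqrt((double)(dx * dx + dy * dy));
      if (d <= rad + EPS) {
        Offset o; o.dx = dx; o.dy = dy; o.dist = d;
        o.ang = std::atan2((double)dy, (double)dx) * 180.0 / M_PI;
        if (o.ang < 0) o.ang += 360.0;
        off.push_back(o);
      }
    }
  std::sort(off.begin(), off.end(), by_angle);
  return off;
}

static inline double ang_diff(double a, double b) {
  double d = std::fmod(a - b + 540.0, 360.0) - 180.0;
  return std::fabs(d);
}

static inline double move_cost(const Params &p, int status) {
  if (!p.enhanced) return p.e_c;
  return status == 2 ? p.L_M_I : p.L_M_S;
}

// ---------------------------------------------------------------------------
// Phases
// ---------------------------------------------------------------------------

// target selection for one agent; returns cell (cx, cy) or false.
// `flat` reports whether every visible cell carries the same quantity
// (no gradient to seek: the movement phase then falls back to a random
// heading, keeping the movement path random on a saturated landscape).
struct TargetScan {
  const World *W; const Params *p; int a;
  bool found; double best_q, best_d, min_q; int best_idx, cx, cy;
  void visit(const Offset &o) {
    int gx = wrapc(W->x[a] + o.dx, W->M);
    int gy = wrapc(W->y[a] + o.dy, W->M);
    int idx = gy * W->M + gx;
    double q = W->qt[idx] + W->qf[idx];
    if (!found || q < min_q) min_q = q;
    bool better = false;
    if (!found) better = true;
    else if (q > best_q) better = true;
    else if (q == best_q && o.dist < best_d - EPS) better = true;
    else if (q == best_q && std::fabs(o.dist - best_d) <= EPS &&
             idx < best_idx) better = true;
    if (better) {
      found = true; best_q = q; best_d = o.dist; best_idx = idx;
      cx = gx; cy = gy;
    }
  }
};

static bool select_target(const World &W, const Params &p, int a,
                          const std::vector<Offset> &off, int &cx, int &cy,
                          bool *flat = 0) {
  TargetScan sc; sc.W = &W; sc.p = &p; sc.a = a;
  sc.found = false; sc.best_q = -1.0; sc.best_d = 0.0; sc.min_q = 0.0;
  sc.best_idx = 0; sc.cx = 0; sc.cy = 0;
  double half = p.theta / 2.0 + EPS;
  if (half >= 180.0) {
    for (size_t k = 0; k < off.size(); ++k) sc.visit(off[k]);
  } else {
    double lo = W.heading[a] - half, hi = W.heading[a] + half;
    lo = std::fmod(lo, 360.0); if (lo < 0) lo += 360.0;
    hi = std::fmod(hi, 360.0); if (hi < 0) hi += 360.0;
    Offset probe;
    // angle-sorted slices: one contiguous range, or two when wrapping 0
    const Offset *base = off.empty() ? 0 : &off[0];
    size_t n = off.size();
    if (n) {
      if (lo <= hi) {
        probe.ang = lo;
        for (size_t k = std::lower_bound(base, base + n, probe, by_angle) -
                        base;
             k < n && off[k].ang <= hi; ++k) sc.visit(off[k]);
      } else {
        probe.ang = lo;
        for (size_t k = std::lower_bound(base, base + n, probe, by_angle) -
                        base;
             k < n; ++k) sc.visit(off[k]);
        for (size_t k = 0; k < n && off[k].ang <= hi; ++k) sc.visit(off[k]);
      }
    }
  }
  cx = sc.cx; cy = sc.cy;
  if (flat) *flat = sc.found && sc.best_q == sc.min_q;
  return sc.found;
}

static void phase_movement(World &W, const Params &p) {
  std::vector<Offset> off = make_offsets(p.d_e);
  // a globally uniform field has no gradient anywhere: every agent takes
  // the random-heading fallback without scanning its cone
  bool uniform = true;
  double q0 = W.qt[0] + W.qf[0];
  for (int c = 1; c < W.M * W.M && uniform; ++c)
    uniform = (W.qt[c] + W.qf[c]) == q0;
  std::vector<int> perm = rand_perm(W.N);
  for (int i = 0; i < W.N; ++i) {
    int a = perm[i];
    int cx = 0, cy = 0;
    bool flat = uniform;
    double ang;
    if (!uniform && select_target(W, p, a, off, cx, cy, &flat) && !flat) {
      double dx = mindelta(cx, W.x[a], W.M), dy = mindelta(cy, W.y[a], W.M);
      ang = std::atan2(dy, dx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
    } else {
      ang = unif_rand() * 360.0;
    }
    W.heading[a] = ang;
    double rad = ang * M_PI / 180.0;
    int sx = (int)std::lround(std::cos(rad));
    int sy = (int)std::lround(std::sin(rad));
    W.x[a] = wrapc(W.x[a] + sx, W.M);
    W.y[a] = wrapc(W.y[a] + sy, W.M);
    W.energy[a] -= move_cost(p, W.status[a]);
  }
}

static void phase_consume(World &W, const Params &p) {
  std::vector<int> perm = rand_perm(W.N);
  for (int i = 0; i < W.N; ++i) {
    int a = perm[i];
    int idx = W.y[a] * W.M + W.x[a];
    double tot = W.qt[idx] + W.qf[idx];
    double b = std::min(tot, p.consume_bite);
    if (b <= 0) continue;
    double fshare = tot > 0 ? W.qf[idx] / tot : 0.0;
    W.qf[idx] = std::max(W.qf[idx] - b * fshare, 0.0);
    W.qt[idx] = std::max(W.qt[idx] - b * (1.0 - fshare), 0.0);
    W.energy[a] += b;
    if (!W.armed[a]) {  // arm the next post; countdown starts now
      W.armed[a] = 1;
      W.post_timer[a] = W.status[a] == 2 ? p.D_P_I : p.D_P_S;
    }
  }
}

static void phase_post(World &W, const Params &p) {
  std::vector<int> perm = rand_perm(W.N);
  for (int i = 0; i < W.N; ++i) {
    int a = perm[i];
    if (!W.armed[a] || W.post_timer[a] > 0) continue;
    int idx = W.y[a] * W.M + W.x[a];
    double cap = p.q_max - (W.qt[idx] + W.qf[idx]);
    double amt = std::min(p.post_quantum, std::max(cap, 0.0));
    if (W.status[a] == 2) W.qf[idx] += amt; else W.qt[idx] += amt;
    W.energy[a] -= W.status[a] == 2 ? p.L_P_I : p.L_P_S;
    W.armed[a] = 0;
    W.post_timer[a] = W.status[a] == 2 ? p.D_P_I : p.D_P_S;
  }
}

struct EventLog {
  std::vector<int> tick, agent, channel, source, src_group, tgt_group;
  void add(int t, int a, int ch, int src, int sg, int tg) {
    tick.push_back(t); agent.push_back(a); channel.push_back(ch);
    source.push_back(src); src_group.push_back(sg); tgt_group.push_back(tg);
  }
};

// contact spreading: each infected agent targets its nearest susceptible
// within d_c; per-tick success probability beta * share * contact_scale
static void phase_spreading(World &W, const Params &p, std::vector<char> &guard,
                            EventLog *ev) {
  double share = p.enhanced ? 0.5 : 1.0;
  double pc = p.beta * share * p.contact_scale;
  if (pc > 1.0) pc = 1.0;
  // cell buckets
  std::vector<int> head(W.M * W.M, -1), nxt(W.N, -1);
  for (int a = 0; a < W.N; ++a) {
    int idx = W.y[a] * W.M + W.x[a];
    nxt[a] = head[idx]; head[idx] = a;
  }
  int R = (int)std::ceil(p.d_c);
  std::vector<int> perm = rand_perm(W.N);
  for (int i = 0; i < W.N; ++i) {
    int a = perm[i];
    if (W.status[a] != 2) continue;
    int best = -1; double bestd = 0.0;
    for (int dy = -R; dy <= R; ++dy)
      for (int dx = -R; dx <= R; ++dx) {
        int gx = wrapc(W.x[a] + dx, W.M), gy = wrapc(W.y[a] + dy, W.M);
        for (int k = head[gy * W.M + gx]; k != -1; k = nxt[k]) {
          if (W.status[k] != 0) continue;
          double ddx = mindelta(W.x[k], W.x[a], W.M);
          double ddy = mindelta(W.y[k], W.y[a], W.M);
          double d = std::sqrt(ddx * ddx + ddy * ddy);
          if (d >= p.d_c) continue;
          if (best == -1 || d < bestd - EPS ||
              (std::fabs(d - bestd) <= EPS && k < best)) { best = k; bestd = d; }
        }
      }
    if (best == -1) continue;
    if (p.enhanced && p.homophily && W.group[a] != W.group[best]) continue;
    if (pc <= 0) continue;
    if (unif_rand() < pc) {
      W.status[best] = p.has_E ? 1 : 2;
      guard[best] = 1;
      if (ev) ev->add(W.tick, best, 1, a, W.group[a], W.group[best]);
    }
  }
}

// environment-mediated infection from false information on the agent's cell
static void phase_stigmergy(World &W, const Params &p, std::vector<char> &guard,
                            EventLog *ev) {
  for (int a = 0; a < W.N; ++a) {
    if (W.status[a] != 0 || guard[a]) continue;
    double qf = W.qf[W.y[a] * W.M + W.x[a]];
    if (qf <= 0 || p.beta <= 0) continue;
    double pe = 0.5 * p.beta * std::min(qf / p.q_max, 1.0);
    if (unif_rand() < pe) {
      W.status[a] = p.has_E ? 1 : 2;
      guard[a] = 1;
      if (ev) ev->add(W.tick, a, 2, -1, -1, W.group[a]);
    }
  }
}

// incubation, recovery, immunity loss; one transition per agent per tick
static void phase_state(World &W, const Params &p, std::vector<char> &guard) {
  for (int a = 0; a < W.N; ++a) {
    if (guard[a]) continue;
    int s = W.status[a];
    if (s == 1 && p.has_E) {
      if (unif_rand() < p.sigma) W.status[a] = 2;
    } else if (s == 2 && p.rec_mode) {
      if (unif_rand() < p.gamma) W.status[a] = p.rec_mode == 1 ? 0 : 3;
    } else if (s == 3 && p.has_xi) {
      if (unif_rand() < p.xi) W.status[a] = 0;
    }
  }
}

static void phase_cells(World &W, const Params &p) {
  int ncell = W.M * W.M;
  if (!p.enhanced) {
    for (int c = 0; c < ncell; ++c)
      W.qt[c] = std::min(W.qt[c] + p.growth, p.q_max);
  } else {
    for (int c = 0; c < ncell; ++c)
      W.qt[c] = std::min(W.qt[c] + p.I_R, std::max(p.q_max - W.qf[c], 0.0));
  }
}

static void run_tick(World &W, const Params &p, EventLog *ev) {
  std::vector<char> guard(W.N, 0);
  phase_movement(W, p);
  if (p.enhanced) {  // zero-bite/zero-quantum channels are disabled outright
    if (p.consume_bite > 0) phase_consume(W, p);
    if (p.post_quantum > 0) phase_post(W, p);
  }
  phase_spreading(W, p, guard, ev);
  if (p.enhanced) phase_stigmergy(W, p, guard, ev);
  phase_state(W, p, guard);
  phase_cells(W, p);
  if (p.enhanced)
    for (int a = 0; a < W.N; ++a)
      if (W.post_timer[a] > 0) --W.post_timer[a];
  ++W.tick;
}

static void tally(const World &W, int *out) {
  out[0] = out[1] = out[2] = out[3] = 0;
  for (int a = 0; a < W.N; ++a) ++out[W.status[a]];
}

// ---------------------------------------------------------------------------
// Exported entry points
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List abm_init_cpp(List cfg) {
  Params p = unpack_params(cfg);
  World W;
  W.M = p.M; W.N = p.N; W.tick = 0;
  W.x.resize(p.N); W.y.resize(p.N); W.status.resize(p.N);
  W.group.assign(p.N, 0); W.post_timer.assign(p.N, 0);
  W.armed.assign(p.N, 0);
  W.heading.resize(p.N); W.energy.assign(p.N, p.e0);
  W.qt.assign(p.M * p.M, 0.0); W.qf.assign(p.M * p.M, 0.0);
  int k = (int)std::ceil(std::sqrt((double)p.N));
  double spacing = (double)p.M / (double)k;
  for (int i = 0; i < p.N; ++i) {
    W.x[i] = wrapc((int)std::floor((i % k) * spacing + spacing / 2.0), p.M);
    W.y[i] = wrapc((int)std::floor((i / k) * spacing + spacing / 2.0), p.M);
    W.heading[i] = std::fmod(i * 137.5, 360.0);
  }
  // deterministic seeds, strided across the index range so the initial
  // infected/exposed are dispersed over the lattice instead of forming one
  // contiguous band (which would turn the outbreak into a single wave)
  for (int j = 0; j < p.I0; ++j) {
    int idx = (int)(((long long)j * p.N) / p.I0);
    while (W.status[idx] != 0) idx = (idx + 1) % p.N;
    W.status[idx] = 2;
  }
  for (int j = 0; j < p.E0; ++j) {
    int idx = (int)(((long long)(2 * j + 1) * p.N) / (2 * p.E0));
    while (W.status[idx] != 0) idx = (idx + 1) % p.N;
    W.status[idx] = 1;
  }
  // fixed deterministic information landscape (all true-type)
  for (int yy = 0; yy < p.M; ++yy)
    for (int xx = 0; xx < p.M; ++xx)
      W.qt[yy * p.M + xx] = p.q_max * 0.5 *
        (1.0 + std::sin(2.0 * M_PI * xx / p.M) * std::cos(2.0 * M_PI * yy / p.M));
  return pack_world(W);  // group tags are assigned R-side (assign_groups)
}

// [[Rcpp::export]]
List abm_run_cpp(List world, List cfg, int T, bool record_events) {
  Params p = unpack_params(cfg);
  World W = unpack_world(world);
  EventLog ev;
  IntegerMatrix counts(T + 1, 4);
  int c[4];
  tally(W, c);
  for (int j = 0; j < 4; ++j) counts(0, j) = c[j];
  GetRNGstate();
  for (int t = 0; t < T; ++t) {
    run_tick(W, p, record_events ? &ev : (EventLog *)0);
    tally(W, c);
    for (int j = 0; j < 4; ++j) counts(t + 1, j) = c[j];
  }
  PutRNGstate();
  List out = List::create(_["counts"] = counts, _["world"] = pack_world(W));
  if (record_events)
    out["events"] = List::create(
      _["tick"] = ev.tick, _["agent"] = ev.agent, _["channel"] = ev.channel,
      _["source"] = ev.source, _["src_group"] = ev.src_group,
      _["tgt_group"] = ev.tgt_group);
  return out;
}

// run a single named phase (unit-testing hook); the one-transition-per-tick
// guard is reset on entry, so each call behaves like the phase at tick start
// [[Rcpp::export]]
List abm_phase_cpp(List world, List cfg, std::string phase) {
  Params p = unpack_params(cfg);
  World W = unpack_world(world);
  std::vector<char> guard(W.N, 0);
  GetRNGstate();
  if (phase == "movement") phase_movement(W, p);
  else if (phase == "consume") phase_consume(W, p);
  else if (phase == "post") phase_post(W, p);
  else if (phase == "spreading") phase_spreading(W, p, guard, 0);
  else if (phase == "stigmergy") phase_stigmergy(W, p, guard, 0);
  else if (phase == "state") phase_state(W, p, guard);
  else if (phase == "cells") phase_cells(W, p);
  else { PutRNGstate(); stop("unknown phase '%s'", phase.c_str()); }
  PutRNGstate();
  return pack_world(W);
}

// [[Rcpp::export]]
List select_target_cpp(int x, int y, double heading, NumericMatrix q,
                       double d_e, double theta) {
  int M = q.nrow();
  World W;
  W.M = M; W.N = 1; W.tick = 0;
  W.x.assign(1, x); W.y.assign(1, y); W.heading.assign(1, heading);
  W.status.assign(1, 0);
  W.qt.assign(M * M, 0.0); W.qf.assign(M * M, 0.0);
  for (int yy = 0; yy < M; ++yy)
    for (int xx = 0; xx < M; ++xx)
      W.qt[yy * M + xx] = q(yy, xx);   // q[row, col] = q[y+1, x+1]
  Params p; p.theta = theta; p.d_e = d_e;
  std::vector<Offset> off = make_offsets(d_e);
  int cx = 0, cy = 0;
  if (select_target(W, p, 0, off, cx, cy))
    return List::create(_["x"] = cx, _["y"] = cy);
  return List::create();
}

// ---------------------------------------------------------------------------
// Discrete-time equation-based iterator (forward Euler, one tick per step)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix ebm_run_cpp(NumericVector init, double beta, double sigma,
                          double gamma, double xi, int has_E, int rec_mode,
                          int has_xi, double N, int T) {
  NumericMatrix out(T + 1, 4);
  double S = init[0], E = init[1], I = init[2], R = init[3];
  out(0, 0) = S; out(0, 1) = E; out(0, 2) = I; out(0, 3) = R;
  for (int t = 0; t < T; ++t) {
    double inf = beta * S * I / N;
    if (inf > S) inf = S;                       // proportional outflux clamp
    double inc = has_E ? sigma * E : 0.0;
    if (inc > E) inc = E;
    double rec = rec_mode ? gamma * I : 0.0;
    if (rec > I) rec = I;
    double loss = has_xi ? xi * R : 0.0;
    if (loss > R) loss = R;
    if (has_E) { S += -inf + loss; E += inf - inc; I += inc - rec; }
    else       { S += -inf + loss + (rec_mode == 1 ? rec : 0.0); E = 0.0; I += inf - rec; }
    R += (rec_mode == 2 ? rec : 0.0) - loss;
    // two-compartment models (SI, SIS): close conservation exactly so the
    // S and I series are bit-exact mirrors
    if (!has_E && rec_mode != 2 && !has_xi) I = N - S;
    out(t + 1, 0) = S; out(t + 1, 1) = E; out(t + 1, 2) = I; out(t + 1, 3) = R;
  }
  return out;
}
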