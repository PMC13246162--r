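// Coarse-grained sticker-spacer Langevin dynamics core.
//
// Internal units: length nm, time ns, mass ag (1e-21 kg).  Potential
// parameters enter in kBT units; the integrator converts to mechanical
// units with ekt = kB*T in ag nm^2/ns^2 (4.1419 at 300 K).  With these
// units the pressure (energy/volume) comes out in MPa.

#include <Rcpp.h>
#include <vector>
#include <functional>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// deterministic RNG: splitmix64 seeding + xoshiro-free mt19937_64 core with
// hand-rolled Box-Muller so the normal stream is implementation-independent
// ---------------------------------------------------------------------------
struct RNG {
  std::uint64_t s;
  bool have_spare = false;
  double spare = 0.0;
  explicit RNG(std::uint64_t seed) : s(seed) {}
  std::uint64_t next_u64() {
    // splitmix64
    std::uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { // in (0,1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0) +
           5.551115123125783e-17;
  }
  double gauss() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586 * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

// ---------------------------------------------------------------------------
// geometry helpers
// ---------------------------------------------------------------------------
static inline double min_image(double d, double L) {
  d -= L * std::round(d / L);
  return d;
}

struct Box {
  double L[3];
};

// ---------------------------------------------------------------------------
// force field tables (all in kBT units)
// ---------------------------------------------------------------------------
struct FF {
  int ntypes;
  std::vector<double> eps, sigma;         // WCA, ntypes^2
  std::vector<double> soft_u0, soft_r0;   // sticker-sticker attraction
  std::vector<double> cl_eps, cl_R, cl_ra; // client-sticker attraction
  double cutmax;
  double at(const std::vector<double>& v, int a, int b) const {
    return v[a * ntypes + b];
  }
};

static FF parse_ff(const List& ff) {
  FF f;
  NumericMatrix eps = ff["pair_eps"], sig = ff["pair_sigma"],
    su = ff["soft_u0"], sr = ff["soft_r0"],
    ce = ff["client_eps"], cR = ff["client_R"], cr = ff["client_ra"];
  f.ntypes = eps.nrow();
  int n2 = f.ntypes * f.ntypes;
  f.eps.assign(eps.begin(), eps.begin() + n2);
  f.sigma.assign(sig.begin(), sig.begin() + n2);
  f.soft_u0.assign(su.begin(), su.begin() + n2);
  f.soft_r0.assign(sr.begin(), sr.begin() + n2);
  f.cl_eps.assign(ce.begin(), ce.begin() + n2);
  f.cl_R.assign(cR.begin(), cR.begin() + n2);
  f.cl_ra.assign(cr.begin(), cr.begin() + n2);
  f.cutmax = 0.0;
  const double wca_fac = std::pow(2.0, 1.0 / 6.0);
  for (int i = 0; i < n2; ++i) {
    if (f.eps[i] > 0) f.cutmax = std::max(f.cutmax, wca_fac * f.sigma[i]);
    if (f.soft_u0[i] != 0) f.cutmax = std::max(f.cutmax, f.soft_r0[i]);
    if (f.cl_eps[i] != 0) f.cutmax = std::max(f.cutmax, f.cl_R[i] + f.cl_ra[i]);
  }
  return f;
}

// precomputed per-type-pair interaction table (kBT units)
struct PairTab {
  bool any = false;
  bool wca = false, soft = false, client = false;
  double cut2 = 0.0;                 // overall squared cutoff for this pair
  double eps4 = 0.0, sigma2 = 0.0, wcacut2 = 0.0, eshift = 0.0;
  double u0 = 0.0, r0 = 0.0;
  double ce = 0.0, cR = 0.0, cra = 0.0, clo = 0.0;
};

static std::vector<PairTab> build_tabs(const FF& ff) {
  int nt = ff.ntypes;
  std::vector<PairTab> tabs(nt * nt);
  const double wca_fac2 = std::pow(2.0, 1.0 / 3.0);
  for (int a = 0; a < nt; ++a)
    for (int b = 0; b < nt; ++b) {
      PairTab& t = tabs[a * nt + b];
      double e = ff.at(ff.eps, a, b);
      if (e > 0) {
        double s = ff.at(ff.sigma, a, b);
        t.wca = true;
        t.eps4 = 4.0 * e;
        t.sigma2 = s * s;
        t.wcacut2 = wca_fac2 * s * s;
        t.eshift = e;
        t.cut2 = std::max(t.cut2, t.wcacut2);
      }
      double u0 = ff.at(ff.soft_u0, a, b);
      if (u0 != 0) {
        t.soft = true;
        t.u0 = u0;
        t.r0 = ff.at(ff.soft_r0, a, b);
        t.cut2 = std::max(t.cut2, t.r0 * t.r0);
      }
      double ce = ff.at(ff.cl_eps, a, b);
      if (ce != 0) {
        t.client = true;
        t.ce = ce;
        t.cR = ff.at(ff.cl_R, a, b);
        t.cra = ff.at(ff.cl_ra, a, b);
        t.clo = std::max(0.0, t.cR - t.cra);
        double hi = t.cR + t.cra;
        t.cut2 = std::max(t.cut2, hi * hi);
      }
      t.any = t.wca || t.soft || t.client;
    }
  return tabs;
}

// energy and dU/dr at squared distance r2 (sqrt only when a soft/trig term
// is active); soft_scale multiplies the sticker attraction (anneal ramp)
static inline void pair_eval2(const PairTab& t, double r2, double soft_scale,
                              double& u, double& dudr_over_r) {
  u = 0.0; dudr_over_r = 0.0;
  if (t.wca && r2 < t.wcacut2) {
    double sr2 = t.sigma2 / r2;
    double sr6 = sr2 * sr2 * sr2;
    double sr12 = sr6 * sr6;
    u += t.eps4 * (sr12 - sr6) + t.eshift;
    dudr_over_r += t.eps4 * (-12.0 * sr12 + 6.0 * sr6) / r2;
  }
  if (t.soft || t.client) {
    double r = std::sqrt(r2);
    if (t.soft && soft_scale != 0.0 && r < t.r0) {
      double a = M_PI * r / t.r0;
      u += -0.5 * t.u0 * soft_scale * (1.0 + std::cos(a));
      dudr_over_r += 0.5 * t.u0 * soft_scale * std::sin(a) * M_PI /
                     (t.r0 * r);
    }
    if (t.client && r >= t.clo && r <= t.cR + t.cra) {
      double a = M_PI * (r - t.cR) / t.cra;
      u += -0.5 * t.ce * (1.0 + std::cos(a));
      dudr_over_r += 0.5 * t.ce * std::sin(a) * M_PI / (t.cra * r);
    }
  }
}

// bond energy/force; style 0 = FENE (p1 = k, p2 = rmax), 1 = harmonic
// (p1 = kb, p2 = rb; note U = kb (r-rb)^2, no factor 1/2)
static inline void bond_eval(int style, double p1, double p2, double r,
                             double& u, double& dudr) {
  if (style == 0) {
    if (r >= p2) stop("FENE bond overextended (r >= rmax): unstable dynamics");
    double x = r / p2;
    u = -0.5 * p1 * p2 * p2 * std::log(1.0 - x * x);
    dudr = p1 * r / (1.0 - x * x);
  } else {
    u = p1 * (r - p2) * (r - p2);
    dudr = 2.0 * p1 * (r - p2);
  }
}

// ---------------------------------------------------------------------------
// cell list (optionally over a subset of beads; tracks occupied cells)
// ---------------------------------------------------------------------------
struct CellList {
  int nc[3];
  double inv[3];
  std::vector<int> head, next, occupied;
  bool ok;
  void setup(const Box& box, double cutoff) {
    ok = true;
    for (int d = 0; d < 3; ++d) {
      nc[d] = std::max(1, (int)std::floor(box.L[d] / cutoff));
      if (nc[d] < 3) ok = false;
      inv[d] = nc[d] / box.L[d];
    }
  }
  int cell_of(const double* p) const {
    int c[3];
    for (int d = 0; d < 3; ++d) {
      double L = 1.0 / inv[d] * nc[d];
      double xi = p[d] - L * std::floor(p[d] / L);
      c[d] = std::min(nc[d] - 1, (int)(xi * inv[d]));
    }
    return (c[2] * nc[1] + c[1]) * nc[0] + c[0];
  }
  void build(const std::vector<double>& x, int n, const Box& box,
             double cutoff) {
    std::vector<int> ids(n);
    for (int i = 0; i < n; ++i) ids[i] = i;
    build_ids(x, n, ids, box, cutoff);
  }
  void build_ids(const std::vector<double>& x, int n,
                 const std::vector<int>& ids, const Box& box,
                 double cutoff) {
    setup(box, cutoff);
    if (!ok) return;
    head.assign(nc[0] * nc[1] * nc[2], -1);
    next.assign(n, -1);
    occupied.clear();
    for (int i : ids) {
      int c[3];
      for (int d = 0; d < 3; ++d) {
        double xi = x[3 * i + d];
        xi -= box.L[d] * std::floor(xi / box.L[d]);
        c[d] = std::min(nc[d] - 1, (int)(xi * inv[d]));
      }
      int idx = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
      if (head[idx] < 0) occupied.push_back(idx);
      next[i] = head[idx];
      head[idx] = i;
    }
  }
};

// bonded-neighbour exclusion table (1-2 pairs excluded from nonbonded)
struct Excl {
  std::vector<std::vector<int>> nb;
  void build(int n, const IntegerMatrix& bonds) {
    nb.assign(n, {});
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      nb[i].push_back(j);
      nb[j].push_back(i);
    }
  }
  bool excluded(int i, int j) const {
    for (int k : nb[i]) if (k == j) return true;
    return false;
  }
};

// ---------------------------------------------------------------------------
// force/energy/virial evaluation (kBT units)
// ---------------------------------------------------------------------------
struct ForceOut {
  double pe;      // kBT
  double virial;  // sum r.f, kBT
};

// neighbour plan: types with few beads and system-dominating cutoffs are
// handled by a wide cell scan ("big"); everything else shares a compact
// cell list sized to the largest small-small cutoff
struct Ctx {
  int nt = 0;
  std::vector<PairTab> tabs;
  std::vector<char> big_type;
  double smallcut = 0.0, bigcut = 0.0;
  std::vector<int> small_idx, big_idx;
};

static Ctx make_ctx(const FF& ff, const std::vector<int>& type, int n) {
  Ctx c;
  c.nt = ff.ntypes;
  c.tabs = build_tabs(ff);
  c.big_type.assign(c.nt, 0);
  std::vector<int> count(c.nt, 0);
  for (int i = 0; i < n; ++i) count[type[i]]++;
  auto smallmax = [&]() {
    double m = 0.0;
    for (int a = 0; a < c.nt; ++a)
      for (int b = 0; b < c.nt; ++b)
        if (!c.big_type[a] && !c.big_type[b] && count[a] && count[b])
          m = std::max(m, std::sqrt(c.tabs[a * c.nt + b].cut2));
    return m;
  };
  bool changed = true;
  while (changed) {
    changed = false;
    double cur = smallmax();
    for (int t = 0; t < c.nt; ++t) {
      if (c.big_type[t] || count[t] == 0) continue;
      if (count[t] > std::max(32, n / 10)) continue;
      c.big_type[t] = 1;
      double without = smallmax();
      if (without > 0.0 && without < 0.75 * cur) {
        changed = true;
      } else {
        c.big_type[t] = 0;
      }
    }
  }
  c.smallcut = smallmax();
  for (int a = 0; a < c.nt; ++a)
    for (int b = 0; b < c.nt; ++b)
      if ((c.big_type[a] || c.big_type[b]) && count[a] && count[b])
        c.bigcut = std::max(c.bigcut, std::sqrt(c.tabs[a * c.nt + b].cut2));
  for (int i = 0; i < n; ++i)
    (c.big_type[type[i]] ? c.big_idx : c.small_idx).push_back(i);
  return c;
}

// Verlet neighbour list with skin, rebuilt when any bead has moved more
// than skin/2 since the last build.  Small-small candidate pairs come from
// a compact cell list, big-bead pairs from a coarse one (see Ctx).
struct NList {
  double skin = 0.4;
  std::vector<int> pi, pj;
  std::vector<int> tab;
  std::vector<double> xref;
  bool valid = false;
  CellList cl, clb;

  bool need_rebuild(const std::vector<double>& x, int n, const Box& box) {
    if (!valid || (int)xref.size() != 3 * n) return true;
    double h2 = 0.25 * skin * skin;
    for (int i = 0; i < n; ++i) {
      double dx = min_image(x[3 * i] - xref[3 * i], box.L[0]);
      double dy = min_image(x[3 * i + 1] - xref[3 * i + 1], box.L[1]);
      double dz = min_image(x[3 * i + 2] - xref[3 * i + 2], box.L[2]);
      if (dx * dx + dy * dy + dz * dz > h2) return true;
    }
    return false;
  }

  void rebuild(const std::vector<double>& x, int n,
               const std::vector<int>& type, const Box& box, const Ctx& ctx,
               const Excl& excl) {
    const int nt = ctx.nt;
    pi.clear(); pj.clear(); tab.clear();
    std::vector<double> lc2(nt * nt, -1.0);
    for (int a = 0; a < nt * nt; ++a)
      if (ctx.tabs[a].any) {
        double rc = std::sqrt(ctx.tabs[a].cut2) + skin;
        lc2[a] = rc * rc;
      }
    auto consider = [&](int i, int j) {
      int a = type[i] * nt + type[j];
      if (lc2[a] < 0) return;
      double dx = min_image(x[3 * i] - x[3 * j], box.L[0]);
      double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box.L[1]);
      double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box.L[2]);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= lc2[a]) return;
      if (excl.excluded(i, j)) return;
      pi.push_back(i); pj.push_back(j); tab.push_back(a);
    };

    bool cells_ok = false;
    if (ctx.smallcut > 0 && !ctx.small_idx.empty()) {
      cl.build_ids(x, n, ctx.small_idx, box, ctx.smallcut + skin);
      cells_ok = cl.ok;
    }
    if (cells_ok) {
      static const int off[14][3] = {
        {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
        {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},
        {1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
      const int nx = cl.nc[0], ny = cl.nc[1], nz = cl.nc[2];
      for (int c1 : cl.occupied) {
        int cx = c1 % nx, cy = (c1 / nx) % ny, cz = c1 / (nx * ny);
        for (int k = 0; k < 14; ++k) {
          int ax = cx + off[k][0];
          if (ax < 0) ax += nx; else if (ax >= nx) ax -= nx;
          int ay = cy + off[k][1];
          if (ay < 0) ay += ny; else if (ay >= ny) ay -= ny;
          int az = cz + off[k][2];
          if (az < 0) az += nz; else if (az >= nz) az -= nz;
          int c2 = (az * ny + ay) * nx + ax;
          for (int i = cl.head[c1]; i >= 0; i = cl.next[i])
            for (int j = cl.head[c2]; j >= 0; j = cl.next[j]) {
              if (k == 0 && j >= i) continue;
              consider(i, j);
            }
        }
      }
    } else {
      const std::vector<int>& s = ctx.small_idx;
      for (size_t a = 0; a + 1 < s.size(); ++a)
        for (size_t b = a + 1; b < s.size(); ++b) consider(s[a], s[b]);
    }
    if (!ctx.big_idx.empty()) {
      bool cb_ok = false;
      if (!ctx.small_idx.empty()) {
        clb.build_ids(x, n, ctx.small_idx, box, ctx.bigcut + skin);
        cb_ok = clb.ok;
      }
      for (size_t a = 0; a < ctx.big_idx.size(); ++a) {
        int i = ctx.big_idx[a];
        if (cb_ok) {
          int c[3];
          for (int d = 0; d < 3; ++d) {
            double xi = x[3 * i + d];
            xi -= box.L[d] * std::floor(xi / box.L[d]);
            c[d] = std::min(clb.nc[d] - 1, (int)(xi * clb.inv[d]));
          }
          for (int dz = -1; dz <= 1; ++dz)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dx = -1; dx <= 1; ++dx) {
                int ax = c[0] + dx, ay = c[1] + dy, az = c[2] + dz;
                if (ax < 0) ax += clb.nc[0];
                else if (ax >= clb.nc[0]) ax -= clb.nc[0];
                if (ay < 0) ay += clb.nc[1];
                else if (ay >= clb.nc[1]) ay -= clb.nc[1];
                if (az < 0) az += clb.nc[2];
                else if (az >= clb.nc[2]) az -= clb.nc[2];
                int c2 = (az * clb.nc[1] + ay) * clb.nc[0] + ax;
                for (int j = clb.head[c2]; j >= 0; j = clb.next[j])
                  consider(i, j);
              }
        } else {
          for (int j : ctx.small_idx) consider(i, j);
        }
        for (size_t b = a + 1; b < ctx.big_idx.size(); ++b)
          consider(i, ctx.big_idx[b]);
      }
    }
    xref = x;
    valid = true;
  }
};

static ForceOut forces_kbt(const std::vector<double>& x, int n,
                           const std::vector<int>& type, const Box& box,
                           const Ctx& ctx, const IntegerMatrix& bonds,
                           const IntegerVector& bstyle,
                           const NumericVector& bp1, const NumericVector& bp2,
                           const Excl& excl, double soft_scale,
                           std::vector<double>& f, int method, NList& nl) {
  // method: 0/1 neighbour list, 2 all-pairs (reference path)
  std::fill(f.begin(), f.end(), 0.0);
  ForceOut out{0.0, 0.0};
  const int nt = ctx.nt;

  auto eval_pair = [&](int i, int j, const PairTab& t) {
    double dx = min_image(x[3 * i] - x[3 * j], box.L[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box.L[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box.L[2]);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= t.cut2 || r2 == 0.0) return;
    double u, fr2;
    pair_eval2(t, r2, soft_scale, u, fr2);
    if (u == 0.0 && fr2 == 0.0) return;
    out.pe += u;
    double fr = -fr2; // -(dU/dr)/r, multiplier on the separation vector
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    out.virial += -fr2 * r2;
  };

  if (n > 1) {
    if (method == 2) {
      for (int i = 0; i < n - 1; ++i)
        for (int j = i + 1; j < n; ++j) {
          const PairTab& t = ctx.tabs[type[i] * nt + type[j]];
          if (!t.any || excl.excluded(i, j)) continue;
          eval_pair(i, j, t);
        }
    } else {
      if (nl.need_rebuild(x, n, box)) nl.rebuild(x, n, type, box, ctx, excl);
      size_t np = nl.pi.size();
      for (size_t k = 0; k < np; ++k)
        eval_pair(nl.pi[k], nl.pj[k], ctx.tabs[nl.tab[k]]);
    }
  }
  // bonds
  for (int b = 0; b < bonds.nrow(); ++b) {
    int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1, c = bonds(b, 2) - 1;
    double dx = min_image(x[3 * i] - x[3 * j], box.L[0]);
    double dy = min_image(x[3 * i + 1] - x[3 * j + 1], box.L[1]);
    double dz = min_image(x[3 * i + 2] - x[3 * j + 2], box.L[2]);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r == 0.0) continue;
    double u, dudr;
    bond_eval(bstyle[c], bp1[c], bp2[c], r, u, dudr);
    out.pe += u;
    double fr = -dudr / r;
    f[3 * i] += fr * dx; f[3 * i + 1] += fr * dy; f[3 * i + 2] += fr * dz;
    f[3 * j] -= fr * dx; f[3 * j + 1] -= fr * dy; f[3 * j + 2] -= fr * dz;
    out.virial += -dudr * r;
  }
  return out;
}

// [[Rcpp::export]]
List cs_forces(NumericMatrix pos, IntegerVector type, NumericVector box_L,
               List ff_list, IntegerMatrix bonds, IntegerVector bond_style,
               NumericVector bond_p1, NumericVector bond_p2,
               double soft_scale = 1.0, int method = 0) {
  int n = pos.nrow();
  FF ff = parse_ff(ff_list);
  Box box{{box_L[0], box_L[1], box_L[2]}};
  std::vector<double> x(3 * n), f(3 * n, 0.0);
  std::vector<int> ty(n);
  for (int i = 0; i < n; ++i) {
    x[3 * i] = pos(i, 0); x[3 * i + 1] = pos(i, 1); x[3 * i + 2] = pos(i, 2);
    ty[i] = type[i] - 1;
  }
  Excl excl; excl.build(n, bonds);
  Ctx ctx = make_ctx(ff, ty, n);
  NList nl;
  ForceOut fo = forces_kbt(x, n, ty, box, ctx, bonds, bond_style, bond_p1,
                           bond_p2, excl, soft_scale, f, method, nl);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i) {
    F(i, 0) = f[3 * i]; F(i, 1) = f[3 * i + 1]; F(i, 2) = f[3 * i + 2];
  }
  return List::create(_["forces"] = F, _["pe"] = fo.pe,
                      _["virial"] = fo.virial);
}

// ---------------------------------------------------------------------------
// Langevin dynamics (BAOAB splitting); thermostat off -> velocity Verlet
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cs_run(NumericMatrix pos, NumericMatrix vel, IntegerVector type,
            NumericVector mass_by_type, NumericVector box_L, List ff_list,
            IntegerMatrix bonds, IntegerVector bond_style,
            NumericVector bond_p1, NumericVector bond_p2,
            double dt, int nsteps, double tau, double ekt, int seed,
            bool thermostat = true,
            double ramp_from = 1.0, double ramp_to = 1.0,
            double wall_xlo = NA_REAL, double wall_xhi = NA_REAL,
            double wall_k = 10.0, IntegerVector wall_mask = IntegerVector(0),
            double fcap = -1.0, int record_every = 0, int sample_every = 100,
            int method = 0) {
  int n = pos.nrow();
  FF ff = parse_ff(ff_list);
  Box box{{box_L[0], box_L[1], box_L[2]}};
  std::vector<double> x(3 * n), v(3 * n), f(3 * n, 0.0), m(n);
  std::vector<int> ty(n), img(3 * n, 0);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = pos(i, d);
      v[3 * i + d] = vel(i, d);
    }
    ty[i] = type[i] - 1;
    m[i] = mass_by_type[ty[i]];
  }
  bool have_wall = R_finite(wall_xlo) && R_finite(wall_xhi) &&
                   wall_mask.size() == n;
  Excl excl; excl.build(n, bonds);
  RNG rng((std::uint64_t)seed * 0x9e3779b97f4a7c15ULL + 12345u);

  double c1 = std::exp(-dt / tau);
  double c2 = std::sqrt(1.0 - c1 * c1);
  double maxdisp = 0.5 * std::min({box.L[0], box.L[1], box.L[2]});

  auto add_walls = [&](ForceOut& fo) {
    if (!have_wall) return;
    for (int i = 0; i < n; ++i) {
      if (!wall_mask[i]) continue;
      // wall position in unwrapped coordinates of the primary image
      double xi = x[3 * i];
      if (xi < wall_xlo) {
        f[3 * i] += 2.0 * wall_k * (wall_xlo - xi);
        fo.pe += wall_k * (wall_xlo - xi) * (wall_xlo - xi);
      } else if (xi > wall_xhi) {
        f[3 * i] -= 2.0 * wall_k * (xi - wall_xhi);
        fo.pe += wall_k * (xi - wall_xhi) * (xi - wall_xhi);
      }
    }
  };
  auto cap_forces = [&]() {
    if (fcap <= 0) return;
    for (int i = 0; i < n; ++i) {
      double fx = f[3 * i], fy = f[3 * i + 1], fz = f[3 * i + 2];
      double fn = std::sqrt(fx * fx + fy * fy + fz * fz);
      if (fn > fcap) {
        double s = fcap / fn;
        f[3 * i] *= s; f[3 * i + 1] *= s; f[3 * i + 2] *= s;
      }
    }
  };

  Ctx ctx = make_ctx(ff, ty, n);
  NList nl;
  double soft_scale = ramp_from;
  ForceOut fo = forces_kbt(x, n, ty, box, ctx, bonds, bond_style, bond_p1,
                           bond_p2, excl, soft_scale, f, method, nl);
  add_walls(fo); cap_forces();

  int nrec = (record_every > 0) ? nsteps / record_every : 0;
  List frames(nrec);
  IntegerVector rec_steps(nrec);
  int nsamp = (sample_every > 0) ? nsteps / sample_every : 0;
  NumericVector pe_s(nsamp), ke_s(nsamp), vir_s(nsamp);
  int irec = 0, isamp = 0;

  for (int step = 0; step < nsteps; ++step) {
    soft_scale = ramp_from +
      (ramp_to - ramp_from) * ((double)(step + 1) / (double)nsteps);
    // B: half kick (convert kBT forces to mechanical units with ekt)
    for (int i = 0; i < n; ++i) {
      double s = 0.5 * dt * ekt / m[i];
      v[3 * i] += s * f[3 * i];
      v[3 * i + 1] += s * f[3 * i + 1];
      v[3 * i + 2] += s * f[3 * i + 2];
    }
    // A: half drift
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double dr = 0.5 * dt * v[3 * i + d];
        if (std::abs(dr) > maxdisp)
          stop("numerical blow-up: displacement exceeds box/2 at step %d",
               step + 1);
        x[3 * i + d] += dr;
      }
    // O: Ornstein-Uhlenbeck
    if (thermostat) {
      for (int i = 0; i < n; ++i) {
        double sv = std::sqrt(ekt / m[i]);
        for (int d = 0; d < 3; ++d)
          v[3 * i + d] = c1 * v[3 * i + d] + c2 * sv * rng.gauss();
      }
    }
    // A: half drift + wrap
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        double dr = 0.5 * dt * v[3 * i + d];
        if (std::abs(dr) > maxdisp)
          stop("numerical blow-up: displacement exceeds box/2 at step %d",
               step + 1);
        double xi = x[3 * i + d] + dr;
        double L = box.L[d];
        if (xi < 0)  { xi += L; img[3 * i + d] -= 1; }
        else if (xi >= L) { xi -= L; img[3 * i + d] += 1; }
        x[3 * i + d] = xi;
      }
    // force recompute + B
    fo = forces_kbt(x, n, ty, box, ctx, bonds, bond_style, bond_p1, bond_p2,
                    excl, soft_scale, f, method, nl);
    add_walls(fo); cap_forces();
    for (int i = 0; i < n; ++i) {
      double s = 0.5 * dt * ekt / m[i];
      v[3 * i] += s * f[3 * i];
      v[3 * i + 1] += s * f[3 * i + 1];
      v[3 * i + 2] += s * f[3 * i + 2];
    }

    if (sample_every > 0 && (step + 1) % sample_every == 0 &&
        isamp < nsamp) {
      double ke = 0.0;
      for (int i = 0; i < n; ++i)
        ke += 0.5 * m[i] * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                            v[3 * i + 2] * v[3 * i + 2]);
      pe_s[isamp] = fo.pe;
      ke_s[isamp] = ke;          // mechanical units (ag nm^2/ns^2)
      vir_s[isamp] = fo.virial;  // kBT units
      ++isamp;
    }
    if (record_every > 0 && (step + 1) % record_every == 0 && irec < nrec) {
      NumericMatrix P(n, 3);
      IntegerMatrix I(n, 3);
      for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
          P(i, d) = x[3 * i + d];
          I(i, d) = img[3 * i + d];
        }
      frames[irec] = List::create(_["pos"] = P, _["img"] = I);
      rec_steps[irec] = step + 1;
      ++irec;
    }
    if ((step & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix P(n, 3), V(n, 3);
  IntegerMatrix I(n, 3);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      P(i, d) = x[3 * i + d];
      V(i, d) = v[3 * i + d];
      I(i, d) = img[3 * i + d];
    }
  return List::create(_["pos"] = P, _["vel"] = V, _["img"] = I,
                      _["frames"] = frames, _["rec_steps"] = rec_steps,
                      _["pe"] = pe_s, _["ke"] = ke_s, _["virial"] = vir_s);
}

// ---------------------------------------------------------------------------
// hard-sphere Widom insertion
// ---------------------------------------------------------------------------
// For each probe position the largest radius R that fits satisfies
// R < min_j(dist_j - rC_j) over excluding beads j; a probe of radius R is
// accepted iff no excluding bead centre lies within R + rC of it.
// [[Rcpp::export]]
List cs_widom(NumericMatrix pos, IntegerVector type, NumericVector box_L,
              NumericVector excl_radius_by_type, NumericVector radii,
              IntegerVector grid_dims, int nrandom, int seed,
              double region_xlo, double region_xhi) {
  Box box{{box_L[0], box_L[1], box_L[2]}};
  int nall = pos.nrow();
  // collect excluding beads (types with finite, non-negative radius entry)
  std::vector<double> x; x.reserve(3 * nall);
  std::vector<double> rc; rc.reserve(nall);
  double rcmax = 0.0;
  for (int i = 0; i < nall; ++i) {
    double r = excl_radius_by_type[type[i] - 1];
    if (R_finite(r) && r >= 0) {
      x.push_back(pos(i, 0)); x.push_back(pos(i, 1)); x.push_back(pos(i, 2));
      rc.push_back(r);
      rcmax = std::max(rcmax, r);
    }
  }
  int n = (int)rc.size();
  int nr = radii.size();
  double Rmax = 0.0;
  for (int k = 0; k < nr; ++k) Rmax = std::max(Rmax, radii[k]);
  double cutoff = Rmax + rcmax + 1e-12;

  CellList cl;
  bool use_cells = false;
  if (n > 0) {
    cl.build(x, n, box, cutoff);
    use_cells = cl.ok;
  }

  std::vector<double> rs(radii.begin(), radii.end());
  std::vector<long long> acc(nr, 0);

  auto clearance = [&](double px, double py, double pz) {
    // returns min over beads of (dist - rC), capped just above Rmax
    double best = Rmax + 1.0;
    if (n == 0) return best;
    if (use_cells) {
      int c[3]; double p[3] = {px, py, pz};
      for (int d = 0; d < 3; ++d) {
        double q = p[d] - box.L[d] * std::floor(p[d] / box.L[d]);
        c[d] = std::min(cl.nc[d] - 1, (int)(q * cl.inv[d]));
      }
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int ax = (c[0] + dx + cl.nc[0]) % cl.nc[0];
            int ay = (c[1] + dy + cl.nc[1]) % cl.nc[1];
            int az = (c[2] + dz + cl.nc[2]) % cl.nc[2];
            int cc = (az * cl.nc[1] + ay) * cl.nc[0] + ax;
            for (int j = cl.head[cc]; j >= 0; j = cl.next[j]) {
              double ddx = min_image(px - x[3 * j], box.L[0]);
              double ddy = min_image(py - x[3 * j + 1], box.L[1]);
              double ddz = min_image(pz - x[3 * j + 2], box.L[2]);
              double dist = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
              best = std::min(best, dist - rc[j]);
              if (best < 0 && -best > Rmax) return best;
            }
          }
    } else {
      for (int j = 0; j < n; ++j) {
        double ddx = min_image(px - x[3 * j], box.L[0]);
        double ddy = min_image(py - x[3 * j + 1], box.L[1]);
        double ddz = min_image(pz - x[3 * j + 2], box.L[2]);
        double dist = std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz);
        best = std::min(best, dist - rc[j]);
      }
    }
    return best;
  };

  double xlo = R_finite(region_xlo) ? region_xlo : 0.0;
  double xhi = R_finite(region_xhi) ? region_xhi : box.L[0];
  long long total = 0;

  if (grid_dims.size() == 3) {
    int nx = grid_dims[0], ny = grid_dims[1], nz = grid_dims[2];
    double dx = (xhi - xlo) / nx, dy = box.L[1] / ny, dz = box.L[2] / nz;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          double m = clearance(xlo + (ix + 0.5) * dx, (iy + 0.5) * dy,
                               (iz + 0.5) * dz);
          ++total;
          for (int k = 0; k < nr; ++k) if (rs[k] < m) ++acc[k];
        }
  } else {
    RNG rng((std::uint64_t)seed * 0x9e3779b97f4a7c15ULL + 777u);
    for (int t = 0; t < nrandom; ++t) {
      double m = clearance(xlo + rng.unif() * (xhi - xlo),
                           rng.unif() * box.L[1], rng.unif() * box.L[2]);
      ++total;
      for (int k = 0; k < nr; ++k) if (rs[k] < m) ++acc[k];
    }
  }
  NumericVector accepted(nr);
  for (int k = 0; k < nr; ++k) accepted[k] = (double)acc[k];
  return List::create(_["accepted"] = accepted, _["total"] = (double)total);
}

// ---------------------------------------------------------------------------
// molecule-level single-linkage clustering (beads within scale*(ri+rj))
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
IntegerVector cs_cluster(NumericMatrix pos, IntegerVector mol,
                         NumericVector radius, NumericVector box_L,
                         double scale = 1.2) {
  int n = pos.nrow();
  Box box{{box_L[0], box_L[1], box_L[2]}};
  int nmol = 0;
  for (int i = 0; i < n; ++i) nmol = std::max(nmol, mol[i]);
  if (nmol == 0) return IntegerVector(0);
  std::vector<int> parent(nmol + 1);
  for (int i = 0; i <= nmol; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  double rmax = 0.0;
  for (int i = 0; i < n; ++i)
    if (mol[i] > 0) rmax = std::max(rmax, radius[i]);
  double cutoff = scale * 2.0 * rmax;

  std::vector<double> x; x.reserve(3 * n);
  std::vector<int> id; id.reserve(n);
  for (int i = 0; i < n; ++i) {
    if (mol[i] <= 0) continue;
    x.push_back(pos(i, 0)); x.push_back(pos(i, 1)); x.push_back(pos(i, 2));
    id.push_back(i);
  }
  int np = (int)id.size();
  CellList cl;
  cl.build(x, np, box, cutoff);

  auto try_pair = [&](int a, int b) {
    int i = id[a], j = id[b];
    if (mol[i] == mol[j]) return;
    double dx = min_image(x[3 * a] - x[3 * b], box.L[0]);
    double dy = min_image(x[3 * a + 1] - x[3 * b + 1], box.L[1]);
    double dz = min_image(x[3 * a + 2] - x[3 * b + 2], box.L[2]);
    double cut = scale * (radius[i] + radius[j]);
    if (dx * dx + dy * dy + dz * dz <= cut * cut) unite(mol[i], mol[j]);
  };
  if (cl.ok) {
    static const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},
      {1,0,1},{-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < cl.nc[2]; ++cz)
      for (int cy = 0; cy < cl.nc[1]; ++cy)
        for (int cx = 0; cx < cl.nc[0]; ++cx) {
          int c1 = (cz * cl.nc[1] + cy) * cl.nc[0] + cx;
          for (int k = 0; k < 14; ++k) {
            int ax = (cx + off[k][0] + cl.nc[0]) % cl.nc[0];
            int ay = (cy + off[k][1] + cl.nc[1]) % cl.nc[1];
            int az = (cz + off[k][2] + cl.nc[2]) % cl.nc[2];
            int c2 = (az * cl.nc[1] + ay) * cl.nc[0] + ax;
            for (int a = cl.head[c1]; a >= 0; a = cl.next[a])
              for (int b = cl.head[c2]; b >= 0; b = cl.next[b]) {
                if (k == 0 && b >= a) continue;
                try_pair(a, b);
              }
          }
        }
  } else {
    for (int a = 0; a < np - 1; ++a)
      for (int b = a + 1; b < np; ++b) try_pair(a, b);
  }
  IntegerVector lab(nmol);
  for (int mId = 1; mId <= nmol; ++mId) lab[mId - 1] = find(mId);
  return lab;
}
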