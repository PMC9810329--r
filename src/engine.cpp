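// Overdamped Brownian dynamics of the confined multiblock copolymer with
// transient Topoisomerase-II pair kinetics.
//
// Reduced units throughout: length l, energy e = kBT, time tau with
// viscosity 1.  Mobility of bead i is 1/(3*pi*d_i); noise amplitude
// sqrt(2*mob*dt).  Euler-Maruyama integration.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_map>

using namespace Rcpp;

namespace {

// Marsaglia polar Gaussian driven by R's uniform stream (much cheaper
// than the inversion-based norm_rand for the 3N draws per step)
struct Gauss {
  double spare; bool has;
  Gauss() : spare(0), has(false) {}
  inline double next() {
    if (has) { has = false; return spare; }
    double u, v, s2;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s2 = u * u + v * v;
    } while (s2 >= 1.0 || s2 == 0.0);
    double f = std::sqrt(-2.0 * std::log(s2) / s2);
    spare = v * f; has = true;
    return u * f;
  }
};

// Cubic-Hermite tabulation of a smooth radial kernel on u = r^2 in
// [0, 1].  Value and analytic derivative are stored at the knots, so the
// interpolant is C1 and its derivative is the exact derivative of the
// evaluated polynomial: forces remain exactly consistent with energies.
// With 4096 intervals the deviation from the closed form is O(1e-11).
struct HTab {
  double h, inv_h;
  std::vector<double> f, d;
  void init(int n, double umax, double (*fun)(double, const double*),
            double (*der)(double, const double*), const double* par) {
    h = umax / n; inv_h = 1.0 / h;
    f.resize(n + 1); d.resize(n + 1);
    for (int k = 0; k <= n; ++k) {
      double u = k * h;
      f[k] = fun(u, par); d[k] = der(u, par);
    }
  }
  inline void eval(double u, double& val, double& dval) const {
    double s = u * inv_h;
    int k = (int)s;
    if (k >= (int)f.size() - 1) k = f.size() - 2;
    double t = s - k;
    double t2 = t * t, t3 = t2 * t;
    double f0 = f[k], f1 = f[k + 1], d0 = d[k], d1 = d[k + 1];
    val = (2 * t3 - 3 * t2 + 1) * f0 + h * (t3 - 2 * t2 + t) * d0 +
          (-2 * t3 + 3 * t2) * f1 + h * (t3 - t2) * d1;
    dval = ((6 * t2 - 6 * t) * (f0 - f1) + h * ((3 * t2 - 4 * t + 1) * d0 +
            (3 * t2 - 2 * t) * d1)) * inv_h;
  }
};

double gauss_f(double u, const double* par) { return std::exp(-par[0] * u); }
double gauss_d(double u, const double* par) {
  return -par[0] * std::exp(-par[0] * u);
}
// heterochromatin kernel u * exp(-aHC (c - sqrt(u))^2) as a function of
// u = r^2
double hc_f(double u, const double* par) {
  double r = std::sqrt(u), dd = par[1] - r;
  return u * std::exp(-par[0] * dd * dd);
}
double hc_d(double u, const double* par) {
  double r = std::sqrt(u), dd = par[1] - r;
  double g = std::exp(-par[0] * dd * dd);
  return g * (1.0 + par[0] * dd * r);
}

struct Params {
  double eps_vex[3];    // AA, AB, BB  (pair type = s_i + s_j)
  double alpha_vex[3];
  double k;
  double r0[3];
  double eps_HC, alpha_HC, d_B, cshift;
  double cutoff, cutoff2;
  double d_bead[2];
  // confinement per species: pref = p*s^1.5, Rs, kappa, gamma, a2
  double conf_pref[2], conf_Rs[2], conf_kappa[2], conf_gamma[2], conf_a2[2];
  double conf_erfcRs[2];
  int geom_type;        // 0 sphere, 1 slab
  double R;             // sphere radius
  double Lx, Ly, Lz;    // slab box
  int variant;          // 0 RANR 1 RAR 2 RNR 3 PHANTOM 4 NONTRANSIENT 5 PASSIVE
  double eps_AA_eff;    // signed amplitude for NONTRANSIENT
  double lam_ra, lam_an, lam_nr;
  bool excl_neighbors, exclusive;
  HTab vex_tab[3], hc_tab;
};

Params unpack(const List& pl) {
  Params p;
  NumericVector ev = pl["eps_vex"], av = pl["alpha_vex"], r0 = pl["r0"],
                db = pl["d_bead"], geom = pl["geom"], rates = pl["rates"];
  for (int t = 0; t < 3; ++t) {
    p.eps_vex[t] = ev[t]; p.alpha_vex[t] = av[t]; p.r0[t] = r0[t];
  }
  p.k = as<double>(pl["k"]);
  p.eps_HC = as<double>(pl["eps_HC"]);
  p.alpha_HC = as<double>(pl["alpha_HC"]);
  p.d_B = as<double>(pl["d_B"]);
  p.cshift = p.d_B - 1.0 / (p.alpha_HC * p.d_B);
  p.cutoff = as<double>(pl["cutoff"]);
  p.cutoff2 = p.cutoff * p.cutoff;
  p.d_bead[0] = db[0]; p.d_bead[1] = db[1];
  NumericMatrix conf = pl["conf"];
  for (int s = 0; s < 2; ++s) {
    double pp = conf(s, 0), ss = conf(s, 1);
    p.conf_pref[s] = pp * std::pow(ss, 1.5);
    p.conf_Rs[s] = conf(s, 2);
    p.conf_kappa[s] = conf(s, 3);
    p.conf_gamma[s] = conf(s, 4);
    double x = p.conf_kappa[s] * p.conf_Rs[s];
    p.conf_a2[s] = 1.0 / (1.0 + 2.0 * x * x) - 0.5;
    p.conf_erfcRs[s] = std::erfc(x);
  }
  p.geom_type = as<int>(pl["geom_type"]);
  if (p.geom_type == 0) { p.R = geom[0]; p.Lx = p.Ly = p.Lz = 0; }
  else { p.Lx = geom[0]; p.Ly = geom[1]; p.Lz = geom[2]; p.R = 0; }
  p.variant = as<int>(pl["variant"]);
  p.eps_AA_eff = as<double>(pl["eps_AA_effective"]);
  p.lam_ra = rates[0]; p.lam_an = rates[1]; p.lam_nr = rates[2];
  p.excl_neighbors = as<bool>(pl["exclude_neighbors"]);
  p.exclusive = as<bool>(pl["exclusive_binding"]);
  for (int t = 0; t < 3; ++t) {
    double par[1] = {p.alpha_vex[t]};
    p.vex_tab[t].init(4096, p.cutoff2, gauss_f, gauss_d, par);
  }
  {
    double par[2] = {p.alpha_HC, p.cshift};
    p.hc_tab.init(4096, p.cutoff2, hc_f, hc_d, par);
  }
  return p;
}

// displacement j -> i with minimum image in periodic axes (slab only);
// positions are kept wrapped in [0, L), so raw differences lie in
// (-L, L) and one conditional fold is the minimum image
inline void disp(const Params& p, double xi, double yi, double zi,
                 double xj, double yj, double zj,
                 double& dx, double& dy, double& dz) {
  dx = xi - xj; dy = yi - yj; dz = zi - zj;
  if (p.geom_type == 1) {
    if (dx > 0.5 * p.Lx) dx -= p.Lx; else if (dx < -0.5 * p.Lx) dx += p.Lx;
    if (dy > 0.5 * p.Ly) dy -= p.Ly; else if (dy < -0.5 * p.Ly) dy += p.Ly;
  }
}

struct System {
  int N;
  std::vector<double> x, y, z;
  std::vector<int> sp;                 // 0 = A, 1 = B
  std::vector<int> nbound;             // enzyme-bound pairs per bead
};

inline double wall_dist(const Params& p, const System& s, int i) {
  if (p.geom_type == 0) {
    double r = std::sqrt(s.x[i] * s.x[i] + s.y[i] * s.y[i] + s.z[i] * s.z[i]);
    return p.R - r;
  }
  return std::min(s.z[i], p.Lz - s.z[i]);
}

// Verlet pair list built via linked cells (no periodic wrap needed for the
// sphere; for the slab the x/y axes wrap, falling back to an all-pairs
// scan when the box is too small for a 3-cell stencil).
typedef std::unordered_map<long long, int8_t> BoundMap;

struct PairList {
  std::vector<int> pi, pj;
  std::vector<int8_t> pst;          // per-pair enzyme state: 0/1 ATT/2 NONE
  std::vector<int> aa_q;            // indices of enzyme-eligible AA pairs
  double rlist, rlist2, skin;
  std::vector<double> x0, y0, z0;   // positions at last build

  inline void push(const Params& p, const System& s, int i, int j) {
    if (i > j) std::swap(i, j);
    pi.push_back(i); pj.push_back(j); pst.push_back(0);
    if (s.sp[i] == 0 && s.sp[j] == 0 &&
        !(p.excl_neighbors && j - i == 1)) {
      aa_q.push_back((int)pi.size() - 1);
    }
  }

  // bound-pair states, keyed by bead indices, surviving list rebuilds
  BoundMap harvest(int N) const {
    BoundMap m;
    for (size_t q = 0; q < pi.size(); ++q) {
      if (pst[q] > 0) m[(long long)pi[q] * N + pj[q]] = pst[q];
    }
    return m;
  }

  void restore(const BoundMap& m, int N) {
    if (m.empty()) return;
    for (size_t q = 0; q < pi.size(); ++q) {
      BoundMap::const_iterator it = m.find((long long)pi[q] * N + pj[q]);
      if (it != m.end()) pst[q] = it->second;
    }
  }

  void build(const Params& p, const System& s, double cutoff, double skin_) {
    skin = skin_; rlist = cutoff + skin; rlist2 = rlist * rlist;
    size_t guess = pi.size() + pi.size() / 8 + 64;
    pi.clear(); pj.clear(); pst.clear(); aa_q.clear();
    pi.reserve(guess); pj.reserve(guess); pst.reserve(guess);
    x0 = s.x; y0 = s.y; z0 = s.z;
    double lox, loy, loz, hix, hiy, hiz;
    if (p.geom_type == 0) {
      lox = loy = loz = -p.R - 1e-9; hix = hiy = hiz = p.R + 1e-9;
    } else {
      lox = 0; loy = 0; loz = 0; hix = p.Lx; hiy = p.Ly; hiz = p.Lz;
    }
    int ncx = std::max(1, (int)std::floor((hix - lox) / rlist));
    int ncy = std::max(1, (int)std::floor((hiy - loy) / rlist));
    int ncz = std::max(1, (int)std::floor((hiz - loz) / rlist));
    bool periodic = (p.geom_type == 1);
    if (periodic && (ncx < 3 || ncy < 3)) {   // stencil would double count
      for (int i = 0; i < s.N; ++i)
        for (int j = i + 1; j < s.N; ++j) {
          double dx, dy, dz;
          disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j], dx, dy, dz);
          if (dx * dx + dy * dy + dz * dz <= rlist2) push(p, s, i, j);
        }
      return;
    }
    long ncells = (long)ncx * ncy * ncz;
    std::vector<int> head(ncells, -1), nxt(s.N, -1);
    auto cell_of = [&](int i) {
      int cx = (int)((s.x[i] - lox) / (hix - lox) * ncx);
      int cy = (int)((s.y[i] - loy) / (hiy - loy) * ncy);
      int cz = (int)((s.z[i] - loz) / (hiz - loz) * ncz);
      cx = std::min(std::max(cx, 0), ncx - 1);
      cy = std::min(std::max(cy, 0), ncy - 1);
      cz = std::min(std::max(cz, 0), ncz - 1);
      return (long)cx + ncx * ((long)cy + (long)ncy * cz);
    };
    for (int i = 0; i < s.N; ++i) {
      long c = cell_of(i); nxt[i] = head[c]; head[c] = i;
    }
    // half stencil: 13 forward neighbours + same cell
    const int off[14][3] = {
      {0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
      {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},
      {-1,1,1},{0,1,1},{1,1,1}};
    for (int cz = 0; cz < ncz; ++cz)
      for (int cy = 0; cy < ncy; ++cy)
        for (int cx = 0; cx < ncx; ++cx) {
          long c = (long)cx + ncx * ((long)cy + (long)ncy * cz);
          if (head[c] < 0) continue;
          for (int o = 0; o < 14; ++o) {
            int nx = cx + off[o][0], ny = cy + off[o][1], nz = cz + off[o][2];
            if (periodic) {
              nx = (nx + ncx) % ncx; ny = (ny + ncy) % ncy;
            } else if (nx < 0 || nx >= ncx || ny < 0 || ny >= ncy) continue;
            if (nz < 0 || nz >= ncz) continue;
            long c2 = (long)nx + ncx * ((long)ny + (long)ncy * nz);
            bool same = (c2 == c);
            for (int i = head[c]; i >= 0; i = nxt[i]) {
              int jstart = same ? nxt[i] : head[c2];
              if (!same && o == 0) continue;
              for (int j = jstart; j >= 0; j = nxt[j]) {
                double dx, dy, dz;
                disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j],
                     dx, dy, dz);
                if (dx * dx + dy * dy + dz * dz <= rlist2) push(p, s, i, j);
              }
            }
          }
        }
  }

  bool stale(const Params& p, const System& s) const {
    double lim = 0.25 * skin * skin;   // (skin/2)^2
    for (int i = 0; i < s.N; ++i) {
      double dx, dy, dz;
      disp(p, s.x[i], s.y[i], s.z[i], x0[i], y0[i], z0[i], dx, dy, dz);
      if (dx * dx + dy * dy + dz * dz > lim) return true;
    }
    return false;
  }
};

// signed amplitude of the vex term for a given pair, or 0 if inactive
inline bool vex_amplitude(const Params& p, int t, int8_t st, double& eps) {
  if (t == 0) {                         // AA
    if (p.variant == 3) return false;   // PHANTOM: no AA steric term
    if (p.variant == 4) { eps = p.eps_AA_eff; return eps != 0.0; }
    if (st == 2) return false;          // bound, no-interaction state
    if (st == 1) { eps = -p.eps_vex[0]; return true; }  // attraction
  }
  eps = p.eps_vex[t];
  return true;
}

// accumulate forces; returns potential energy if want_energy
double forces(const Params& p, const System& s, const PairList& pl,
              std::vector<double>& fx, std::vector<double>& fy,
              std::vector<double>& fz, bool want_energy, long step) {
  double E = 0.0;
  std::fill(fx.begin(), fx.end(), 0.0);
  std::fill(fy.begin(), fy.end(), 0.0);
  std::fill(fz.begin(), fz.end(), 0.0);
  // FENE bonds between consecutive beads
  for (int i = 0; i + 1 < s.N; ++i) {
    int j = i + 1;
    double dx, dy, dz;
    disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j], dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    int t = s.sp[i] + s.sp[j];
    double r02 = p.r0[t] * p.r0[t];
    if (r2 >= r02) {
      stop("FENE bond %d-%d overstretched (r = %.4f >= r0 = %.4f) at step %ld",
           i + 1, j + 1, std::sqrt(r2), p.r0[t], step);
    }
    double denom = 1.0 - r2 / r02;
    double g = p.k / denom;             // -dE/dr / r
    fx[i] -= g * dx; fy[i] -= g * dy; fz[i] -= g * dz;
    fx[j] += g * dx; fy[j] += g * dy; fz[j] += g * dz;
    if (want_energy) E += -0.5 * p.k * r02 * std::log(denom);
  }
  // nonbonded Gaussian terms from the pair list
  for (size_t q = 0; q < pl.pi.size(); ++q) {
    int i = pl.pi[q], j = pl.pj[q];
    double dx, dy, dz;
    disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j], dx, dy, dz);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 > p.cutoff2) continue;
    int t = s.sp[i] + s.sp[j];
    double eps;
    if (vex_amplitude(p, t, pl.pst[q], eps)) {
      double val, dv;
      p.vex_tab[t].eval(r2, val, dv);
      double g = -2.0 * eps * dv;       // -dE/dr / r
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      if (want_energy) E += eps * val;
    }
    if (p.eps_HC != 0.0 && t == 2) {    // BB affinity
      double val, dv;
      p.hc_tab.eval(r2, val, dv);
      double g = 2.0 * p.eps_HC * dv;   // -dE/dr / r
      fx[i] += g * dx; fy[i] += g * dy; fz[i] += g * dz;
      fx[j] -= g * dx; fy[j] -= g * dy; fz[j] -= g * dz;
      if (want_energy) E += -p.eps_HC * val;
    }
  }
  // wall confinement
  for (int i = 0; i < s.N; ++i) {
    int sidx = s.sp[i];
    double pref = p.conf_pref[sidx], Rs = p.conf_Rs[sidx],
           kap = p.conf_kappa[sidx], gam = p.conf_gamma[sidx],
           a2 = p.conf_a2[sidx], erfcRs = p.conf_erfcRs[sidx];
    auto e_of = [&](double rw) {
      if (rw <= Rs)
        return pref * (-std::log(rw / Rs) - (rw * rw / (Rs * Rs) - 1.0) * a2 + gam);
      return pref * gam * std::erfc(kap * rw) / erfcRs;
    };
    auto f_of = [&](double rw) {        // -dE/drw (pushes away from wall)
      if (rw <= Rs) return pref * (1.0 / rw + 2.0 * rw / (Rs * Rs) * a2);
      return pref * gam / erfcRs * 2.0 * kap / std::sqrt(M_PI) *
             std::exp(-kap * kap * rw * rw);
    };
    if (p.geom_type == 0) {
      double rr = std::sqrt(s.x[i] * s.x[i] + s.y[i] * s.y[i] + s.z[i] * s.z[i]);
      double rw = p.R - rr;
      if (rw <= 0)
        stop("bead %d at/through the spherical wall at step %ld", i + 1, step);
      double f = f_of(rw);
      if (want_energy) E += e_of(rw);
      if (rr > 1e-12) {                 // push toward the centre
        double g = f / rr;
        fx[i] -= g * s.x[i]; fy[i] -= g * s.y[i]; fz[i] -= g * s.z[i];
      }
    } else {
      double rw1 = s.z[i], rw2 = p.Lz - s.z[i];
      if (rw1 <= 0 || rw2 <= 0)
        stop("bead %d at/through a slab wall at step %ld", i + 1, step);
      if (want_energy) E += e_of(rw1) + e_of(rw2);
      fz[i] += f_of(rw1) - f_of(rw2);
    }
  }
  return E;
}

// Per-step enzyme kinetics.  Every listed AA pair is an independent
// Bernoulli trial in the stream matching its state (unbound / attraction
// / no-interaction); the number of firing pairs per stream is Binomial
// and the firing positions are uniform, which reproduces per-pair trials
// exactly at a cost proportional to the number of events.  Events on
// pairs that are currently out of capture range (paused), or vetoed by
// the exclusivity option, are discarded -- exact thinning, since the
// underlying waiting times are memoryless.
struct KineticStreams {
  std::vector<int> stream[3];   // pair-list indices by state 0/1/2
  std::vector<int> where;       // position of pair q in its stream
  std::vector<int8_t> which;    // which stream pair q lives in (or -1)

  void rebuild(const PairList& pl) {
    for (int c = 0; c < 3; ++c) stream[c].clear();
    where.assign(pl.pi.size(), -1);
    which.assign(pl.pi.size(), -1);
    for (size_t k = 0; k < pl.aa_q.size(); ++k) {
      int q = pl.aa_q[k];
      int c = pl.pst[q];
      which[q] = (int8_t)c;
      where[q] = (int)stream[c].size();
      stream[c].push_back(q);
    }
  }

  void move(int q, int to) {
    int c = which[q], at = where[q];
    int last = stream[c].back();
    stream[c][at] = last; where[last] = at; stream[c].pop_back();
    which[q] = (int8_t)to;
    where[q] = (int)stream[to].size();
    stream[to].push_back(q);
  }

  // sample the distinct firing positions of one stream
  void fire(int c, double prob, std::vector<int>& out) {
    out.clear();
    int n = (int)stream[c].size();
    if (n == 0 || prob <= 0) return;
    int k = (int)R::rbinom((double)n, prob);
    while ((int)out.size() < k) {
      int pos = (int)(unif_rand() * n);
      if (pos >= n) pos = n - 1;
      bool dup = false;
      for (size_t m = 0; m < out.size(); ++m) if (out[m] == pos) dup = true;
      if (!dup) out.push_back(stream[c][pos]);
    }
  }
};

void kinetics(const Params& p, System& s, PairList& pl, KineticStreams& ks,
              double p_ra, double p_an, double p_nr) {
  if (p.variant >= 3) return;           // PHANTOM/NONTRANSIENT/PASSIVE
  int8_t entry = (p.variant == 2) ? 2 : 1;   // RNR enters the N state
  static std::vector<int> ev;           // reused scratch
  auto in_range = [&](int q) {
    int i = pl.pi[q], j = pl.pj[q];
    double dx, dy, dz;
    disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j], dx, dy, dz);
    return dx * dx + dy * dy + dz * dz <= p.cutoff2;
  };
  // release / advance first (from pre-step states), then catches
  ev.clear();
  ks.fire(1, p_an, ev);
  for (size_t m = 0; m < ev.size(); ++m) {
    int q = ev[m];
    if (!in_range(q)) continue;         // paused
    if (p.variant == 1) {               // RAR: release directly
      pl.pst[q] = 0; ks.move(q, 0);
      --s.nbound[pl.pi[q]]; --s.nbound[pl.pj[q]];
    } else {
      pl.pst[q] = 2; ks.move(q, 2);
    }
  }
  ev.clear();
  ks.fire(2, p_nr, ev);
  for (size_t m = 0; m < ev.size(); ++m) {
    int q = ev[m];
    if (!in_range(q)) continue;         // paused
    if (pl.pst[q] != 2) continue;       // advanced this very step
    pl.pst[q] = 0; ks.move(q, 0);
    --s.nbound[pl.pi[q]]; --s.nbound[pl.pj[q]];
  }
  ev.clear();
  ks.fire(0, p_ra, ev);
  for (size_t m = 0; m < ev.size(); ++m) {
    int q = ev[m];
    if (pl.pst[q] != 0) continue;
    if (!in_range(q)) continue;         // not an eligible catch
    int i = pl.pi[q], j = pl.pj[q];
    if (p.exclusive && (s.nbound[i] > 0 || s.nbound[j] > 0)) continue;
    pl.pst[q] = entry; ks.move(q, entry);
    ++s.nbound[i]; ++s.nbound[j];
  }
}

System make_system(const NumericMatrix& pos, const IntegerVector& species,
                   const IntegerMatrix& registry, BoundMap& bound) {
  System s;
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.sp.assign(species.begin(), species.end());
  s.nbound.assign(s.N, 0);
  bound.clear();
  for (int q = 0; q < registry.nrow(); ++q) {
    int i = registry(q, 0) - 1, j = registry(q, 1) - 1;
    if (i > j) std::swap(i, j);
    bound[(long long)i * s.N + j] = (int8_t)registry(q, 2);
    ++s.nbound[i]; ++s.nbound[j];
  }
  return s;
}

IntegerMatrix registry_of(const System& s, const PairList& pl) {
  std::vector<int> ri, rj, rs;
  for (size_t q = 0; q < pl.pi.size(); ++q) {
    if (pl.pst[q] > 0) {
      ri.push_back(pl.pi[q] + 1); rj.push_back(pl.pj[q] + 1);
      rs.push_back(pl.pst[q]);
    }
  }
  IntegerMatrix out(ri.size(), 3);
  for (size_t q = 0; q < ri.size(); ++q) {
    out(q, 0) = ri[q]; out(q, 1) = rj[q]; out(q, 2) = rs[q];
  }
  colnames(out) = CharacterVector::create("i", "j", "state");
  return out;
}

NumericMatrix positions_of(const System& s) {
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out(i, 0) = s.x[i]; out(i, 1) = s.y[i]; out(i, 2) = s.z[i];
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
double cpp_total_energy(NumericMatrix pos, IntegerVector species,
                        IntegerMatrix registry, List params) {
  Params p = unpack(params);
  BoundMap bound;
  System s = make_system(pos, species, registry, bound);
  PairList pl;
  pl.build(p, s, p.cutoff, 0.0);
  pl.restore(bound, s.N);
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  return forces(p, s, pl, fx, fy, fz, true, -1);
}

// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericMatrix pos, IntegerVector species,
                               IntegerMatrix registry, List params) {
  Params p = unpack(params);
  BoundMap bound;
  System s = make_system(pos, species, registry, bound);
  PairList pl;
  pl.build(p, s, p.cutoff, 0.0);
  pl.restore(bound, s.N);
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  forces(p, s, pl, fx, fy, fz, false, -1);
  NumericMatrix out(s.N, 3);
  for (int i = 0; i < s.N; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// Exact pair list within `cutoff` (candidates distance-filtered).
// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_pairs(NumericMatrix pos, double cutoff,
                                 int geom_type, NumericVector geom) {
  Params p{};
  p.geom_type = geom_type;
  if (geom_type == 0) p.R = geom[0];
  else { p.Lx = geom[0]; p.Ly = geom[1]; p.Lz = geom[2]; }
  p.cutoff = cutoff; p.cutoff2 = cutoff * cutoff;
  System s;
  s.N = pos.nrow();
  s.x.resize(s.N); s.y.resize(s.N); s.z.resize(s.N);
  for (int i = 0; i < s.N; ++i) {
    s.x[i] = pos(i, 0); s.y[i] = pos(i, 1); s.z[i] = pos(i, 2);
  }
  s.sp.assign(s.N, 0);
  PairList pl;
  pl.build(p, s, cutoff, 0.0);
  std::vector<int> ri, rj;
  for (size_t q = 0; q < pl.pi.size(); ++q) {
    int i = pl.pi[q], j = pl.pj[q];
    double dx, dy, dz;
    disp(p, s.x[i], s.y[i], s.z[i], s.x[j], s.y[j], s.z[j], dx, dy, dz);
    if (dx * dx + dy * dy + dz * dz <= p.cutoff2) {
      ri.push_back(i + 1); rj.push_back(j + 1);
    }
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t q = 0; q < ri.size(); ++q) { out(q, 0) = ri[q]; out(q, 1) = rj[q]; }
  return out;
}

// Integrate `n_steps` Euler-Maruyama steps; snapshots every `snap_every`
// steps (0 = none).  Uses R's RNG; call from R after set.seed().
// [[Rcpp::export]]
List cpp_run_bd(NumericMatrix pos, IntegerVector species,
                IntegerMatrix registry, List params, double dt,
                long n_steps, long snap_every, double skin = 0.3,
                bool track_energy = false) {
  Params p = unpack(params);
  BoundMap bound;
  System s = make_system(pos, species, registry, bound);
  PairList pl;
  pl.build(p, s, p.cutoff, skin);
  pl.restore(bound, s.N);
  KineticStreams ks;
  ks.rebuild(pl);
  std::vector<double> fx(s.N), fy(s.N), fz(s.N);
  std::vector<double> mob(s.N), amp(s.N);
  for (int i = 0; i < s.N; ++i) {
    double d = p.d_bead[s.sp[i]];
    mob[i] = 1.0 / (3.0 * M_PI * d);
    amp[i] = std::sqrt(2.0 * mob[i] * dt);
  }
  double p_ra = 1.0 - std::exp(-p.lam_ra * dt);
  double p_an = 1.0 - std::exp(-p.lam_an * dt);
  double p_nr = 1.0 - std::exp(-p.lam_nr * dt);
  bool kin = (p.variant <= 2) && p.lam_ra >= 0.0 && p.variant != 5;

  List snaps; std::vector<double> snap_t; std::vector<int> snap_bound;
  std::vector<double> snap_E;
  RNGScope scope;
  Gauss gauss;
  for (long step = 1; step <= n_steps; ++step) {
    if (pl.stale(p, s)) {
      BoundMap carry = pl.harvest(s.N);
      pl.build(p, s, p.cutoff, skin);
      pl.restore(carry, s.N);
      ks.rebuild(pl);
    }
    forces(p, s, pl, fx, fy, fz, false, step);
    for (int i = 0; i < s.N; ++i) {
      s.x[i] += fx[i] * mob[i] * dt + amp[i] * gauss.next();
      s.y[i] += fy[i] * mob[i] * dt + amp[i] * gauss.next();
      s.z[i] += fz[i] * mob[i] * dt + amp[i] * gauss.next();
      if (p.geom_type == 1) {
        s.x[i] -= p.Lx * std::floor(s.x[i] / p.Lx);
        s.y[i] -= p.Ly * std::floor(s.y[i] / p.Ly);
      }
      if (wall_dist(p, s, i) <= 0.0)
        stop("bead %d crossed the wall at step %ld", i + 1, step);
    }
    if (kin) kinetics(p, s, pl, ks, p_ra, p_an, p_nr);
    if (snap_every > 0 && step % snap_every == 0) {
      snaps.push_back(positions_of(s));
      snap_t.push_back(step * dt);
      int nb = 0;
      for (size_t q = 0; q < pl.pst.size(); ++q) if (pl.pst[q] > 0) ++nb;
      snap_bound.push_back(nb);
      if (track_energy) {
        BoundMap carry = pl.harvest(s.N);
        PairList pe; pe.build(p, s, p.cutoff, 0.0);
        pe.restore(carry, s.N);
        snap_E.push_back(forces(p, s, pe, fx, fy, fz, true, step));
      }
    }
    if (step % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["positions"] = positions_of(s),
    _["registry"] = registry_of(s, pl),
    _["snapshots"] = snaps,
    _["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end()),
    _["bound_pairs"] = IntegerVector(snap_bound.begin(), snap_bound.end()),
    _["energies"] = NumericVector(snap_E.begin(), snap_E.end()));
}
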