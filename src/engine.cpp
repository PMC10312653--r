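// Desk-scale implicit-solvent Langevin dynamics engine.
// Energetics: harmonic bonds/angles, periodic torsions, and
// truncated-and-shifted Lennard-Jones under minimum-image periodic
// boundaries, with a cell-list + Verlet-buffer neighbour list.
// Units: nm, ps, kJ/mol, amu, K.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <unordered_set>
#include <unordered_map>
#include <random>
#include <chrono>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double KB = 0.0083144621; // kJ/(mol K)

#ifndef RESTRICT
#define RESTRICT __restrict__
#endif

// ---------------------------------------------------------------------------
// deterministic RNG (seeded mt19937_64 + Box-Muller, own uniform mapping so
// trajectories are bit-reproducible for a given seed)
struct Gauss {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Gauss(uint64_t seed) : eng(seed) {}
  double unif() { // (0,1)
    return (static_cast<double>(eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double operator()() {
    // Marsaglia polar method (no trig calls), deterministic per seed
    if (has_spare) { has_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f;
    has_spare = true;
    return u * f;
  }
};

// ---------------------------------------------------------------------------
// model parameters unpacked from the R side

struct Model {
  int n = 0;
  std::vector<int> itype, chain;   // itype: 0 inert, >0 sticky group
  std::vector<double> mass;
  double eps_attr = 0, eps_rep = 0, sigma = 0, cutoff = 0, fcap = 1e5;
  bool shifted = true;
  double skin = 0.3;
  // bonded terms (0-based indices)
  std::vector<int> b_i, b_j;             std::vector<double> b_r0, b_k;
  std::vector<int> a_i, a_j, a_k;        std::vector<double> a_t0, a_k2;
  std::vector<int> t_i, t_j, t_k, t_l;   std::vector<double> t_p0, t_k2;
  std::vector<double> t_c0, t_s0;        // cos/sin of phi0 (mult-1 fast path)
  std::vector<int> t_m;
  std::unordered_set<uint64_t> excl;

  uint64_t key(int i, int j) const {
    if (i > j) std::swap(i, j);
    return (uint64_t)i * (uint64_t)n + (uint64_t)j;
  }
};

static Model unpack_model(const List& par) {
  Model m;
  IntegerVector it = par["itype"], ch = par["chain"];
  NumericVector ms = par["mass"];
  m.n = it.size();
  m.itype.assign(it.begin(), it.end());
  m.chain.assign(ch.begin(), ch.end());
  m.mass.assign(ms.begin(), ms.end());
  m.eps_attr = as<double>(par["eps_attr"]);
  m.eps_rep = as<double>(par["eps_rep"]);
  m.sigma = as<double>(par["sigma"]);
  m.cutoff = as<double>(par["cutoff"]);
  m.shifted = as<bool>(par["shifted"]);
  m.fcap = as<double>(par["fcap"]);
  m.skin = as<double>(par["skin"]);
  IntegerVector bi = par["bond_i"], bj = par["bond_j"];
  NumericVector br = par["bond_r0"], bk = par["bond_k"];
  for (int q = 0; q < bi.size(); ++q) {
    m.b_i.push_back(bi[q] - 1); m.b_j.push_back(bj[q] - 1);
    m.b_r0.push_back(br[q]);    m.b_k.push_back(bk[q]);
  }
  IntegerVector ai = par["angle_i"], aj = par["angle_j"], ak = par["angle_k"];
  NumericVector at = par["angle_t0"], akf = par["angle_kf"];
  for (int q = 0; q < ai.size(); ++q) {
    m.a_i.push_back(ai[q] - 1); m.a_j.push_back(aj[q] - 1);
    m.a_k.push_back(ak[q] - 1);
    m.a_t0.push_back(at[q]);    m.a_k2.push_back(akf[q]);
  }
  IntegerVector ti = par["tors_i"], tj = par["tors_j"], tk = par["tors_k"],
                tl = par["tors_l"], tm = par["tors_m"];
  NumericVector tp = par["tors_p0"], tkf = par["tors_kf"];
  for (int q = 0; q < ti.size(); ++q) {
    m.t_i.push_back(ti[q] - 1); m.t_j.push_back(tj[q] - 1);
    m.t_k.push_back(tk[q] - 1); m.t_l.push_back(tl[q] - 1);
    m.t_p0.push_back(tp[q]);    m.t_k2.push_back(tkf[q]);
    m.t_c0.push_back(std::cos(tp[q]));
    m.t_s0.push_back(std::sin(tp[q]));
    m.t_m.push_back(tm[q]);
  }
  IntegerVector ei = par["excl_i"], ej = par["excl_j"];
  for (int q = 0; q < ei.size(); ++q) m.excl.insert(m.key(ei[q] - 1, ej[q] - 1));
  return m;
}

// ---------------------------------------------------------------------------
// minimum image

// round-to-nearest via int cast: much cheaper than nearbyint on targets
// without SSE4 round instructions, identical away from exact half-integers
static inline double rnd(double t) {
  return (double)(long long)(t + (t >= 0 ? 0.5 : -0.5));
}

static inline void min_image(double* d, const double* box) {
  for (int k = 0; k < 3; ++k) d[k] -= box[k] * rnd(d[k] / box[k]);
}

// ---------------------------------------------------------------------------
// cell-list based candidate pair generation at a given list radius

struct PairList {
  std::vector<int> pi, pj;
  std::vector<double> eps;          // per-pair LJ epsilon (attraction rule baked in)
  std::vector<double> ref;          // coordinates at build time (for skin check)
  double rlist = 0;
};

static void build_pairs(const std::vector<double>& x, const double* box,
                        const Model& m, PairList& pl) {
  const double rlist = m.cutoff + m.skin;
  pl.rlist = rlist;
  pl.pi.clear(); pl.pj.clear(); pl.eps.clear();
  pl.ref = x;
  int nc[3]; double cs[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = std::max(1, (int)std::floor(box[k] / rlist));
    cs[k] = box[k] / nc[k];
  }
  const int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(m.n, -1), cellof(m.n);
  for (int i = 0; i < m.n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = x[3 * i + k] / box[k];
      w -= std::floor(w);               // wrap to [0,1)
      c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    cellof[i] = ci;
    nxt[i] = head[ci]; head[ci] = i;
  }
  const double r2 = rlist * rlist;
  std::vector<int> neigh;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        if (head[ci] < 0) continue;
        neigh.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = (cx + dx + nc[0]) % nc[0];
              int ey = (cy + dy + nc[1]) % nc[1];
              int ez = (cz + dz + nc[2]) % nc[2];
              neigh.push_back((ez * nc[1] + ey) * nc[0] + ex);
            }
        std::sort(neigh.begin(), neigh.end());
        neigh.erase(std::unique(neigh.begin(), neigh.end()), neigh.end());
        for (int cj : neigh) {
          if (cj < ci) continue;         // each cell pair once
          for (int i = head[ci]; i >= 0; i = nxt[i]) {
            int jstart = (cj == ci) ? nxt[i] : head[cj];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              double d[3] = { x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                              x[3 * i + 2] - x[3 * j + 2] };
              min_image(d, box);
              double dd = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
              if (dd >= r2) continue;
              if (m.excl.count(m.key(i, j))) continue;
              bool attract = m.itype[i] > 0 && m.itype[i] == m.itype[j] &&
                             m.chain[i] != m.chain[j];
              pl.pi.push_back(i); pl.pj.push_back(j);
              pl.eps.push_back(attract ? m.eps_attr : m.eps_rep);
            }
          }
        }
      }
}

// track max displacement since last list build; rebuild when any bead has
// moved more than half the skin (so no eligible pair can be missed)
static bool moved_too_far(const std::vector<double>& x, const PairList& pl,
                          double skin) {
  const double lim2 = 0.25 * skin * skin;
  for (size_t i = 0; i < x.size(); i += 3) {
    double dx = x[i] - pl.ref[i], dy = x[i + 1] - pl.ref[i + 1],
           dz = x[i + 2] - pl.ref[i + 2];
    if (dx * dx + dy * dy + dz * dz > lim2) return true;
  }
  return false;
}

// ---------------------------------------------------------------------------
// energy and forces

struct Energy {
  double bond = 0, angle = 0, torsion = 0, lj = 0;
  double total() const { return bond + angle + torsion + lj; }
};

static Energy energy_forces(const std::vector<double>& x, const double* box,
                            const Model& m, const PairList& pl,
                            std::vector<double>& f, int* ncapped = nullptr) {
  Energy e;
  std::fill(f.begin(), f.end(), 0.0);

  // bonds: V = 0.5 k (r - r0)^2  (no min-image: molecules stay whole)
  for (size_t q = 0; q < m.b_i.size(); ++q) {
    int i = m.b_i[q], j = m.b_j[q];
    double d[3] = { x[3 * i] - x[3 * j], x[3 * i + 1] - x[3 * j + 1],
                    x[3 * i + 2] - x[3 * j + 2] };
    double r = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double dr = r - m.b_r0[q];
    e.bond += 0.5 * m.b_k[q] * dr * dr;
    double fr = -m.b_k[q] * dr / std::max(r, 1e-12);
    for (int k = 0; k < 3; ++k) {
      f[3 * i + k] += fr * d[k];
      f[3 * j + k] -= fr * d[k];
    }
  }

  // angles: V = 0.5 k (theta - theta0)^2
  for (size_t q = 0; q < m.a_i.size(); ++q) {
    int i = m.a_i[q], j = m.a_j[q], k3 = m.a_k[q];
    double rij[3], rkj[3];
    for (int k = 0; k < 3; ++k) {
      rij[k] = x[3 * i + k] - x[3 * j + k];
      rkj[k] = x[3 * k3 + k] - x[3 * j + k];
    }
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    double cs = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij * nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dth = th - m.a_t0[q];
    e.angle += 0.5 * m.a_k2[q] * dth * dth;
    double sn = std::sqrt(std::max(1.0 - cs * cs, 1e-12));
    // F = -dV/dth * dth/dx; dth/dcos = -1/sin, so F = +k*dth/sin * dcos/dx
    double coef = m.a_k2[q] * dth / sn;
    // dcos/dri etc.
    for (int k = 0; k < 3; ++k) {
      double di = (rkj[k] / (nij * nkj)) - cs * rij[k] / (nij * nij);
      double dk = (rij[k] / (nij * nkj)) - cs * rkj[k] / (nkj * nkj);
      // F = -dV/dr = -dV/dth * dth/dcos * dcos/dr = coef * (-? ) ...
      // dth/dcos = -1/sin -> F_i = -dV/dth * (-1/sin) * dcos/dri
      f[3 * i + k] += coef * di;
      f[3 * k3 + k] += coef * dk;
      f[3 * j + k] -= coef * (di + dk);
    }
  }

  // torsions: V = k (1 - cos(mult (phi - phi0)))
  for (size_t q = 0; q < m.t_i.size(); ++q) {
    int i = m.t_i[q], j = m.t_j[q], k3 = m.t_k[q], l = m.t_l[q];
    double b1[3], b2[3], b3[3];
    for (int k = 0; k < 3; ++k) {
      b1[k] = x[3 * j + k] - x[3 * i + k];
      b2[k] = x[3 * k3 + k] - x[3 * j + k];
      b3[k] = x[3 * l + k] - x[3 * k3 + k];
    }
    double n1[3] = { b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                     b1[0]*b2[1]-b1[1]*b2[0] };
    double n2[3] = { b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                     b2[0]*b3[1]-b2[1]*b3[0] };
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    if (n1sq < 1e-14 || n2sq < 1e-14 || nb2 < 1e-12) continue;
    double m1[3] = { n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                     n1[0]*b2[1]-n1[1]*b2[0] };
    double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double yy = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
    int mult = m.t_m[q];
    double dVdphi;
    if (mult == 1) {
      // V = k (1 - cos(phi - phi0)) via cos/sin identities, no atan2
      double h = std::sqrt(xx * xx + yy * yy);
      if (h < 1e-14) continue;
      double cphi = xx / h, sphi = yy / h;
      double cosd = cphi * m.t_c0[q] + sphi * m.t_s0[q];
      double sind = sphi * m.t_c0[q] - cphi * m.t_s0[q];
      e.torsion += m.t_k2[q] * (1.0 - cosd);
      dVdphi = m.t_k2[q] * sind;
    } else {
      double phi = std::atan2(yy, xx);
      double dphi = mult * (phi - m.t_p0[q]);
      e.torsion += m.t_k2[q] * (1.0 - std::cos(dphi));
      dVdphi = m.t_k2[q] * mult * std::sin(dphi);
    }
    // gradient of phi wrt the four positions (validated against finite
    // differences): dphi/dri = |b2|/|n1|^2 n1, dphi/drl = -|b2|/|n2|^2 n2,
    // inner beads by the usual lever-arm combination
    double t1 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2 * nb2);
    double t2 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2 * nb2);
    for (int k = 0; k < 3; ++k) {
      double d1 = nb2 / n1sq * n1[k];
      double d4 = -nb2 / n2sq * n2[k];
      double d2 = -(1.0 + t1) * d1 + t2 * d4;
      double d3 = t1 * d1 - (1.0 + t2) * d4;
      f[3 * i + k] -= dVdphi * d1;
      f[3 * j + k] -= dVdphi * d2;
      f[3 * k3 + k] -= dVdphi * d3;
      f[3 * l + k] -= dVdphi * d4;
    }
  }

  // nonbonded truncated-shifted LJ
  const double rc2 = m.cutoff * m.cutoff;
  const double s6c = std::pow(m.sigma / m.cutoff, 6.0);
  const double vshift1 = m.shifted ? 4.0 * (s6c * s6c - s6c) : 0.0; // per unit eps
  const double sig2 = m.sigma * m.sigma;
  const double inv_sig2 = 1.0 / sig2;
  const double ibx = 1.0 / box[0], iby = 1.0 / box[1], ibz = 1.0 / box[2];
  const double fcap2 = m.fcap * m.fcap;
  int capped = 0;
  const int* RESTRICT pi = pl.pi.data();
  const int* RESTRICT pj = pl.pj.data();
  const double* RESTRICT pe = pl.eps.data();
  const size_t npair = pl.pi.size();
  for (size_t q = 0; q < npair; ++q) {
    const int i = pi[q], j = pj[q];
    double dx = x[3 * i] - x[3 * j];
    double dy = x[3 * i + 1] - x[3 * j + 1];
    double dz = x[3 * i + 2] - x[3 * j + 2];
    dx -= box[0] * rnd(dx * ibx);
    dy -= box[1] * rnd(dy * iby);
    dz -= box[2] * rnd(dz * ibz);
    const double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) continue;
    const double eps = pe[q];
    const double inv2 = sig2 / r2;
    const double s6 = inv2 * inv2 * inv2;
    const double s12 = s6 * s6;
    e.lj += 4.0 * eps * (s12 - s6) - eps * vshift1;
    double fr = 24.0 * eps * (2.0 * s12 - s6) * inv2 * inv_sig2; // F = fr * d
    if (fr * fr * r2 > fcap2) {
      fr = m.fcap / std::sqrt(r2) * (fr > 0 ? 1.0 : -1.0);
      ++capped;
    }
    f[3 * i] += fr * dx;     f[3 * j] -= fr * dx;
    f[3 * i + 1] += fr * dy; f[3 * j + 1] -= fr * dy;
    f[3 * i + 2] += fr * dz; f[3 * j + 2] -= fr * dz;
  }
  if (ncapped) *ncapped = capped;
  return e;
}

static double max_force(const std::vector<double>& f) {
  double mx = 0;
  for (size_t i = 0; i < f.size(); i += 3) {
    double m2 = f[i]*f[i] + f[i+1]*f[i+1] + f[i+2]*f[i+2];
    if (m2 > mx) mx = m2;
  }
  return std::sqrt(mx);
}

// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_energy_forces(NumericMatrix coords, NumericVector box, List params) {
  Model m = unpack_model(params);
  int n = coords.nrow();
  if (n != m.n) stop("coords/params size mismatch");
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double bx[3] = { box[0], box[1], box[2] };
  PairList pl;
  build_pairs(x, bx, m, pl);
  int ncap = 0;
  Energy e = energy_forces(x, bx, m, pl, f, &ncap);
  NumericMatrix fo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) fo(i, k) = f[3 * i + k];
  return List::create(_["potential"] = e.total(), _["forces"] = fo,
                      _["bond"] = e.bond, _["angle"] = e.angle,
                      _["torsion"] = e.torsion, _["lj"] = e.lj,
                      _["max_force"] = max_force(f),
                      _["n_capped"] = ncap);
}

// [[Rcpp::export]]
List cpp_minimize(NumericMatrix coords, NumericVector box, List params,
                  double force_tol, double step0, int max_steps) {
  Model m = unpack_model(params);
  int n = coords.nrow();
  std::vector<double> x(3 * n), f(3 * n), xt(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double bx[3] = { box[0], box[1], box[2] };
  PairList pl;
  build_pairs(x, bx, m, pl);
  Energy e = energy_forces(x, bx, m, pl, f);
  double E = e.total(), fmax = max_force(f);
  double h = step0;
  int it = 0, nrej = 0;
  bool converged = fmax < force_tol;
  while (!converged && it < max_steps) {
    ++it;
    // steepest-descent trial: scale so the largest bead displacement is h
    double sc = h / std::max(fmax, 1e-30);
    for (size_t q = 0; q < x.size(); ++q) xt[q] = x[q] + sc * f[q];
    if (moved_too_far(xt, pl, m.skin)) build_pairs(xt, bx, m, pl);
    std::vector<double> ft(3 * n);
    Energy et = energy_forces(xt, bx, m, pl, ft);
    if (et.total() < E) {
      x.swap(xt); f.swap(ft); E = et.total(); fmax = max_force(f);
      // grow the step on success but cap it: unbounded growth lets a
      // collective move tunnel single beads into deep overlaps that
      // then stall the descent
      h = std::min(h * 1.2, 0.05);
      nrej = 0;
    } else {
      h *= 0.2; ++nrej;
      if (nrej > 60) break; // step underflow: cannot descend further
    }
    if (fmax < force_tol) converged = true;
  }
  NumericMatrix xo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) xo(i, k) = x[3 * i + k];
  return List::create(_["coords"] = xo, _["converged"] = converged,
                      _["steps"] = it, _["max_force"] = fmax,
                      _["potential"] = E);
}

// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, NumericVector box, List params,
                      double dt, double friction, double temperature,
                      int com_interval, int n_steps, int sample_interval,
                      int seed, Nullable<NumericMatrix> vel0) {
  Model m = unpack_model(params);
  int n = coords.nrow();
  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double bx[3] = { box[0], box[1], box[2] };
  Gauss rng(static_cast<uint64_t>(seed) * 2654435761u + 1234567u);

  if (vel0.isNotNull()) {
    NumericMatrix v0(vel0);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) v[3 * i + k] = v0(i, k);
  } else {
    for (int i = 0; i < n; ++i) {
      double sdv = std::sqrt(KB * temperature / m.mass[i]);
      for (int k = 0; k < 3; ++k) v[3 * i + k] = sdv * rng();
    }
  }

  PairList pl;
  build_pairs(x, bx, m, pl);
  Energy e = energy_forces(x, bx, m, pl, f);

  const double c1 = (friction > 0) ? std::exp(-friction * dt) : 1.0;
  const double c2 = (friction > 0) ? std::sqrt(1.0 - c1 * c1) : 0.0;
  std::vector<double> c2sdv(n);
  for (int i = 0; i < n; ++i)
    c2sdv[i] = c2 * std::sqrt(KB * temperature / m.mass[i]);

  int n_samples = n_steps / sample_interval;
  NumericVector times(n_samples), tkin(n_samples), epot(n_samples);
  NumericVector frames(Dimension(n, 3, n_samples));
  double total_mass = 0;
  for (int i = 0; i < n; ++i) total_mass += m.mass[i];

  int isamp = 0;
  bool blew_up = false;
  double t_rebuild = 0, t_force = 0;
  long n_rebuilds = 0, n_capped_total = 0;
  for (int s = 1; s <= n_steps; ++s) {
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] / m.mass[i];
    // A
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    // O
    if (friction > 0) {
      for (int i = 0; i < n; ++i) {
        double a = c2sdv[i];
        for (int k = 0; k < 3; ++k)
          v[3 * i + k] = c1 * v[3 * i + k] + a * rng();
      }
    }
    // A
    for (size_t q = 0; q < x.size(); ++q) x[q] += 0.5 * dt * v[q];
    // force update
    {
      auto t0 = std::chrono::steady_clock::now();
      if (moved_too_far(x, pl, m.skin)) {
        build_pairs(x, bx, m, pl);
        ++n_rebuilds;
      }
      auto t1 = std::chrono::steady_clock::now();
      int nc_step = 0;
      e = energy_forces(x, bx, m, pl, f, &nc_step);
      n_capped_total += nc_step;
      auto t2 = std::chrono::steady_clock::now();
      t_rebuild += std::chrono::duration<double>(t1 - t0).count();
      t_force += std::chrono::duration<double>(t2 - t1).count();
    }
    // B
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k)
        v[3 * i + k] += 0.5 * dt * f[3 * i + k] / m.mass[i];

    if (com_interval > 0 && s % com_interval == 0) {
      double p[3] = { 0, 0, 0 };
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) p[k] += m.mass[i] * v[3 * i + k];
      for (int k = 0; k < 3; ++k) p[k] /= total_mass;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) v[3 * i + k] -= p[k];
    }

    if (s % sample_interval == 0 && isamp < n_samples) {
      double ke = 0;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          ke += 0.5 * m.mass[i] * v[3 * i + k] * v[3 * i + k];
      double T = 2.0 * ke / (3.0 * n * KB);
      times[isamp] = s * dt;
      tkin[isamp] = T;
      epot[isamp] = e.total();
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k)
          frames[(size_t)isamp * 3 * n + (size_t)k * n + i] = x[3 * i + k];
      if (!std::isfinite(e.total()) || !std::isfinite(ke)) { blew_up = true; }
      ++isamp;
      if (blew_up) break;
    }
    if (!std::isfinite(x[0])) { blew_up = true; break; }
  }

  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) {
      xo(i, k) = x[3 * i + k];
      vo(i, k) = v[3 * i + k];
    }
  return List::create(_["frames"] = frames, _["times"] = times,
                      _["T_K"] = tkin, _["E_pot"] = epot,
                      _["coords"] = xo, _["velocities"] = vo,
                      _["n_samples"] = isamp, _["blew_up"] = blew_up,
                      _["t_rebuild"] = t_rebuild, _["t_force"] = t_force,
                      _["n_rebuilds"] = n_rebuilds,
                      _["n_capped"] = (double)n_capped_total,
                      _["n_pairs"] = (double)pl.pi.size());
}

// ---------------------------------------------------------------------------
// random rigid-body packing with a tolerance contract

// [[Rcpp::export]]
List cpp_pack_box(List pool, IntegerVector assignment, NumericVector box,
                  double tolerance, int seed, int max_attempts) {
  int copies = assignment.size();
  std::vector<NumericMatrix> confs;
  for (int q = 0; q < pool.size(); ++q)
    confs.push_back(as<NumericMatrix>(pool[q]));
  int nb = confs[0].nrow();
  double bx[3] = { box[0], box[1], box[2] };
  Gauss rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 97531ULL);

  // grid for already-placed beads
  const double cell = std::max(tolerance, 0.5);
  int nc[3];
  for (int k = 0; k < 3; ++k) nc[k] = std::max(1, (int)std::floor(bx[k] / cell));
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<std::vector<int>> grid(ncell);
  std::vector<double> placed; placed.reserve((size_t)copies * nb * 3);
  const double tol2 = tolerance * tolerance;

  auto cell_of = [&](const double* p) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = p[k] / bx[k]; w -= std::floor(w);
      c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
    }
    return (c[2] * nc[1] + c[1]) * nc[0] + c[0];
  };

  std::vector<double> trial(3 * nb);
  int placed_copies = 0;
  for (int cp = 0; cp < copies; ++cp) {
    const NumericMatrix& cf = confs[assignment[cp] - 1];
    bool ok = false;
    for (int att = 0; att < max_attempts && !ok; ++att) {
      // uniform random rotation from a random unit quaternion
      double q0 = rng(), q1 = rng(), q2 = rng(), q3 = rng();
      double qn = std::sqrt(q0*q0 + q1*q1 + q2*q2 + q3*q3);
      q0 /= qn; q1 /= qn; q2 /= qn; q3 /= qn;
      double R[3][3] = {
        {1 - 2*(q2*q2 + q3*q3), 2*(q1*q2 - q0*q3), 2*(q1*q3 + q0*q2)},
        {2*(q1*q2 + q0*q3), 1 - 2*(q1*q1 + q3*q3), 2*(q2*q3 - q0*q1)},
        {2*(q1*q3 - q0*q2), 2*(q2*q3 + q0*q1), 1 - 2*(q1*q1 + q2*q2)}
      };
      double tr[3] = { rng.unif() * bx[0], rng.unif() * bx[1],
                       rng.unif() * bx[2] };
      bool clash = false;
      for (int i = 0; i < nb && !clash; ++i) {
        double p[3];
        for (int k = 0; k < 3; ++k)
          p[k] = R[k][0] * cf(i, 0) + R[k][1] * cf(i, 1) + R[k][2] * cf(i, 2)
               + tr[k];
        trial[3 * i] = p[0]; trial[3 * i + 1] = p[1]; trial[3 * i + 2] = p[2];
        // neighbour cells of p
        int c[3];
        for (int k = 0; k < 3; ++k) {
          double w = p[k] / bx[k]; w -= std::floor(w);
          c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
        }
        for (int dz = -1; dz <= 1 && !clash; ++dz)
          for (int dy = -1; dy <= 1 && !clash; ++dy)
            for (int dx = -1; dx <= 1 && !clash; ++dx) {
              int ex = (c[0] + dx + nc[0]) % nc[0];
              int ey = (c[1] + dy + nc[1]) % nc[1];
              int ez = (c[2] + dz + nc[2]) % nc[2];
              int ci = (ez * nc[1] + ey) * nc[0] + ex;
              for (int idx : grid[ci]) {
                double d[3] = { p[0] - placed[3 * idx],
                                p[1] - placed[3 * idx + 1],
                                p[2] - placed[3 * idx + 2] };
                min_image(d, bx);
                if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] < tol2) {
                  clash = true; break;
                }
              }
            }
      }
      // self-image check: a molecule longer than a box edge can clash
      // with its own periodic image — flag pairs whose minimum-image
      // distance violates the tolerance even though their direct
      // (unwrapped) distance does not
      if (!clash) {
        for (int i = 0; i < nb && !clash; ++i)
          for (int j = i + 1; j < nb; ++j) {
            double ddir[3] = { trial[3*i] - trial[3*j],
                               trial[3*i+1] - trial[3*j+1],
                               trial[3*i+2] - trial[3*j+2] };
            double d2dir = ddir[0]*ddir[0] + ddir[1]*ddir[1] +
                           ddir[2]*ddir[2];
            if (d2dir <= tol2) continue; // genuine intra-chain proximity
            double dmi[3] = { ddir[0], ddir[1], ddir[2] };
            min_image(dmi, bx);
            if (dmi[0]*dmi[0] + dmi[1]*dmi[1] + dmi[2]*dmi[2] < tol2) {
              clash = true; break;
            }
          }
      }
      if (!clash) ok = true;
    }
    if (!ok) {
      return List::create(_["ok"] = false, _["placed"] = placed_copies,
                          _["coords"] = R_NilValue);
    }
    // commit
    for (int i = 0; i < nb; ++i) {
      int idx = (int)(placed.size() / 3);
      placed.push_back(trial[3 * i]);
      placed.push_back(trial[3 * i + 1]);
      placed.push_back(trial[3 * i + 2]);
      grid[cell_of(&placed[3 * idx])].push_back(idx);
    }
    ++placed_copies;
  }
  int ntot = (int)(placed.size() / 3);
  NumericMatrix out(ntot, 3);
  for (int i = 0; i < ntot; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = placed[3 * i + k];
  return List::create(_["ok"] = true, _["placed"] = placed_copies,
                      _["coords"] = out);
}

// ---------------------------------------------------------------------------
// contact graph between bead groups (molecules or coil instances) under
// minimum-image PBC; returns pair contact counts for groups within cutoff

// [[Rcpp::export]]
List cpp_contact_graph(NumericMatrix coords, NumericVector box,
                       IntegerVector group, IntegerVector chain,
                       double cutoff, bool require_diff_chain) {
  int n = coords.nrow();
  double bx[3] = { box[0], box[1], box[2] };
  const double rc2 = cutoff * cutoff;
  int nc[3];
  for (int k = 0; k < 3; ++k)
    nc[k] = std::max(1, (int)std::floor(bx[k] / cutoff));
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1);
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    if (group[i] <= 0) continue; // group 0: bead not participating
    keep.push_back(i);
  }
  for (int idx : keep) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = coords(idx, k) / bx[k]; w -= std::floor(w);
      c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[idx] = head[ci]; head[ci] = idx;
  }
  std::unordered_map<uint64_t, int> counts;
  std::vector<int> neigh;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        if (head[ci] < 0) continue;
        neigh.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = (cx + dx + nc[0]) % nc[0];
              int ey = (cy + dy + nc[1]) % nc[1];
              int ez = (cz + dz + nc[2]) % nc[2];
              neigh.push_back((ez * nc[1] + ey) * nc[0] + ex);
            }
        std::sort(neigh.begin(), neigh.end());
        neigh.erase(std::unique(neigh.begin(), neigh.end()), neigh.end());
        for (int cj : neigh) {
          if (cj < ci) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i]) {
            int jstart = (cj == ci) ? nxt[i] : head[cj];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              if (group[i] == group[j]) continue;
              if (require_diff_chain && chain[i] == chain[j]) continue;
              double d[3] = { coords(i,0) - coords(j,0),
                              coords(i,1) - coords(j,1),
                              coords(i,2) - coords(j,2) };
              min_image(d, bx);
              if (d[0]*d[0] + d[1]*d[1] + d[2]*d[2] >= rc2) continue;
              int gi = group[i], gj = group[j];
              if (gi > gj) std::swap(gi, gj);
              uint64_t key = ((uint64_t)gi << 32) | (uint64_t)gj;
              counts[key] += 1;
            }
          }
        }
      }
  int ne = (int)counts.size();
  IntegerVector gi(ne), gj(ne), cnt(ne);
  int q = 0;
  for (auto& kv : counts) {
    gi[q] = (int)(kv.first >> 32);
    gj[q] = (int)(kv.first & 0xffffffffu);
    cnt[q] = kv.second;
    ++q;
  }
  return List::create(_["gi"] = gi, _["gj"] = gj, _["count"] = cnt);
}

// [[Rcpp::export]]
double cpp_min_interchain_dist(NumericMatrix coords, NumericVector box,
                               IntegerVector chain, double search_radius) {
  int n = coords.nrow();
  double bx[3] = { box[0], box[1], box[2] };
  int nc[3];
  for (int k = 0; k < 3; ++k)
    nc[k] = std::max(1, (int)std::floor(bx[k] / search_radius));
  int ncell = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncell, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int c[3];
    for (int k = 0; k < 3; ++k) {
      double w = coords(i, k) / bx[k]; w -= std::floor(w);
      c[k] = std::min(nc[k] - 1, (int)(w * nc[k]));
    }
    int ci = (c[2] * nc[1] + c[1]) * nc[0] + c[0];
    nxt[i] = head[ci]; head[ci] = i;
  }
  double best = std::numeric_limits<double>::infinity();
  std::vector<int> neigh;
  for (int cz = 0; cz < nc[2]; ++cz)
    for (int cy = 0; cy < nc[1]; ++cy)
      for (int cx = 0; cx < nc[0]; ++cx) {
        int ci = (cz * nc[1] + cy) * nc[0] + cx;
        if (head[ci] < 0) continue;
        neigh.clear();
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int ex = (cx + dx + nc[0]) % nc[0];
              int ey = (cy + dy + nc[1]) % nc[1];
              int ez = (cz + dz + nc[2]) % nc[2];
              neigh.push_back((ez * nc[1] + ey) * nc[0] + ex);
            }
        std::sort(neigh.begin(), neigh.end());
        neigh.erase(std::unique(neigh.begin(), neigh.end()), neigh.end());
        for (int cj : neigh) {
          if (cj < ci) continue;
          for (int i = head[ci]; i >= 0; i = nxt[i]) {
            int jstart = (cj == ci) ? nxt[i] : head[cj];
            for (int j = jstart; j >= 0; j = nxt[j]) {
              if (chain[i] == chain[j]) continue;
              double d[3] = { coords(i,0) - coords(j,0),
                              coords(i,1) - coords(j,1),
                              coords(i,2) - coords(j,2) };
              min_image(d, bx);
              double dd = std::sqrt(d[0]*d[0] + d[1]*d[1] + d[2]*d[2]);
              if (dd < best) best = dd;
            }
          }
        }
      }
  return best;
}
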