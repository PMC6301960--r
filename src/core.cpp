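// Center-based off-lattice epidermis core: membrane geometry queries,
// pairwise/membrane forces with a uniform spatial hash grid, and the
// overdamped Euler-Maruyama stepping loop with the keratinocyte lifecycle.
//
// All randomness flows through R's RNG (RNGScope via Rcpp attributes), cells
// are processed in id order, so runs are bitwise reproducible from set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// state codes shared with R (see R/cell.R)
enum CellState { ST_STEM = 0, ST_PROLIF = 1, ST_SPINOUS = 2,
                 ST_GRANULAR = 3, ST_CORNEOCYTE = 4 };

// ---------------------------------------------------------------- membrane

struct Membrane {
  int kind;            // 0 flat, 1 sinusoidal, 2 fiber_grid
  double A, lambda;    // sinusoidal: peak-to-trough amplitude, wavelength
  bool grooves;        // 1D sinusoid variant (grooves along y)
  double fib_t, fib_p; // fiber grid: fiber thickness, lateral period
  double Lx, Ly;       // lateral domain extents
};

static Membrane membrane_from_list(List m) {
  Membrane mb;
  mb.kind = as<int>(m["kind_code"]);
  mb.A = m.containsElementNamed("amplitude_um") && !Rf_isNull(m["amplitude_um"])
           ? as<double>(m["amplitude_um"]) : 0.0;
  mb.lambda = m.containsElementNamed("wavelength_um") && !Rf_isNull(m["wavelength_um"])
           ? as<double>(m["wavelength_um"]) : 1.0;
  mb.grooves = m.containsElementNamed("grooves") ? as<bool>(m["grooves"]) : false;
  double ft = 0.0, fi = 0.0;
  if (m.containsElementNamed("fiber_thickness_um") && !Rf_isNull(m["fiber_thickness_um"]))
    ft = as<double>(m["fiber_thickness_um"]);
  if (m.containsElementNamed("fiber_interval_um") && !Rf_isNull(m["fiber_interval_um"]))
    fi = as<double>(m["fiber_interval_um"]);
  mb.fib_t = ft;
  mb.fib_p = ft + fi;
  mb.Lx = as<double>(m["domain_x_um"]);
  mb.Ly = as<double>(m["domain_y_um"]);
  return mb;
}

static inline double wrap0(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x = 0.0;   // guard the x/L rounding edge
  return x;
}

// minimum-image separation component
static inline double min_image(double dx, double L) {
  return dx - L * std::round(dx / L);
}

static double mem_height(const Membrane& mb, double x, double y) {
  x = wrap0(x, mb.Lx);
  y = wrap0(y, mb.Ly);
  if (mb.kind == 0) return 0.0;
  if (mb.kind == 1) {
    double sx = std::sin(2.0 * M_PI * x / mb.lambda);
    if (mb.grooves) return 0.5 * mb.A * sx;
    return 0.5 * mb.A * sx * std::sin(2.0 * M_PI * y / mb.lambda);
  }
  // fiber grid: orthogonal cylinders of radius R resting on z = 0,
  // axes at lateral multiples of the period (fibers along both x and y)
  double R = 0.5 * mb.fib_t;
  double dx = x - mb.fib_p * std::round(x / mb.fib_p);
  double dy = y - mb.fib_p * std::round(y / mb.fib_p);
  double h = 0.0;
  if (std::fabs(dx) < R) h = std::max(h, R + std::sqrt(R * R - dx * dx));
  if (std::fabs(dy) < R) h = std::max(h, R + std::sqrt(R * R - dy * dy));
  return h;
}

// outward unit normal from the height gradient (analytic where smooth,
// central finite difference with step 1e-3 um for the fiber envelope)
static void mem_normal(const Membrane& mb, double x, double y, double n[3]) {
  double hx = 0.0, hy = 0.0;
  if (mb.kind == 1) {
    double w = 2.0 * M_PI / mb.lambda;
    double xx = wrap0(x, mb.Lx), yy = wrap0(y, mb.Ly);
    if (mb.grooves) {
      hx = 0.5 * mb.A * w * std::cos(w * xx);
      hy = 0.0;
    } else {
      hx = 0.5 * mb.A * w * std::cos(w * xx) * std::sin(w * yy);
      hy = 0.5 * mb.A * w * std::sin(w * xx) * std::cos(w * yy);
    }
  } else if (mb.kind == 2) {
    const double eps = 1e-3;
    hx = (mem_height(mb, x + eps, y) - mem_height(mb, x - eps, y)) / (2 * eps);
    hy = (mem_height(mb, x, y + eps) - mem_height(mb, x, y - eps)) / (2 * eps);
  }
  double nrm = std::sqrt(hx * hx + hy * hy + 1.0);
  n[0] = -hx / nrm;
  n[1] = -hy / nrm;
  n[2] = 1.0 / nrm;
}

// [[Rcpp::export]]
NumericVector cpp_membrane_height(List mem, NumericVector x, NumericVector y) {
  Membrane mb = membrane_from_list(mem);
  R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mem_height(mb, x[i], y[i]);
  return out;
}

// [[Rcpp::export]]
List cpp_membrane_gap(List mem, NumericVector x, NumericVector y, NumericVector z) {
  Membrane mb = membrane_from_list(mem);
  R_xlen_t n = x.size();
  NumericVector gap(n);
  NumericMatrix nrm(n, 3);
  double nv[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    gap[i] = z[i] - mem_height(mb, x[i], y[i]);
    mem_normal(mb, x[i], y[i], nv);
    nrm(i, 0) = nv[0]; nrm(i, 1) = nv[1]; nrm(i, 2) = nv[2];
  }
  return List::create(_["gap"] = gap, _["normal"] = nrm);
}

// ------------------------------------------------------------------ params

struct ForceP {
  double k_rep, k_adh, adh_range, k_mem, k_anchor, gamma, noise_amp, dt;
};
struct LifeP {
  double division_period, division_jitter, diff_height, spinous_dur,
         granular_dur, flatten_tau, target_aspect, desquam_dur,
         daughter_offset, r0, ca_tau;
  int crowding_cap;
  bool calcium_on;
};

static ForceP forcep_from_list(List fp) {
  ForceP p;
  p.k_rep = fp["k_rep"]; p.k_adh = fp["k_adh"]; p.adh_range = fp["adh_range_um"];
  p.k_mem = fp["k_mem"]; p.k_anchor = fp["k_anchor"]; p.gamma = fp["gamma"];
  p.noise_amp = fp["noise_amp"]; p.dt = fp["dt_h"];
  return p;
}
static LifeP lifep_from_list(List lp) {
  LifeP p;
  p.division_period = lp["division_period_h"];
  p.division_jitter = lp["division_jitter"];
  p.diff_height = lp["diff_height_um"];
  p.spinous_dur = lp["spinous_dur_h"];
  p.granular_dur = lp["granular_dur_h"];
  p.flatten_tau = lp["flatten_tau_h"];
  p.target_aspect = lp["target_aspect"];
  p.desquam_dur = lp["desquam_dur_h"];
  p.daughter_offset = lp["daughter_offset_um"];
  p.r0 = lp["r0_um"];
  p.ca_tau = lp["ca_tau_h"];
  p.crowding_cap = as<int>(lp["crowding_cap"]);
  p.calcium_on = as<bool>(lp["calcium_on"]);
  return p;
}

// ------------------------------------------------------------- force model

// direction-dependent ellipsoid radius along unit vector u (uz vertical)
static inline double dir_radius(double a, double c, double uz) {
  double s2 = 1.0 - uz * uz;       // sin^2(theta from vertical)
  return a * c / std::sqrt(c * c * s2 + a * a * uz * uz);
}

// deterministic unit direction from an (i, j) id pair, for the coincident-
// center tie-break; never returns NaN
static void hash_direction(int idi, int idj, double u[3]) {
  unsigned int h = (unsigned int)(std::min(idi, idj) * 73856093u) ^
                   (unsigned int)(std::max(idi, idj) * 19349663u);
  double phi = 2.0 * M_PI * ((h & 0xffffu) / 65536.0);
  double cz = 2.0 * (((h >> 16) & 0xffffu) / 65536.0) - 1.0;
  double sz = std::sqrt(std::max(0.0, 1.0 - cz * cz));
  u[0] = sz * std::cos(phi); u[1] = sz * std::sin(phi); u[2] = cz;
  if (idi < idj) { u[0] = -u[0]; u[1] = -u[1]; u[2] = -u[2]; } // antisymmetric
}

// force exerted on cell i by cell j; returns number of tie-breaks applied
static int pair_force(double dx, double dy, double dz, int idi, int idj,
                      double ai, double ci, double aj, double cj,
                      const ForceP& fp, double F[3]) {
  F[0] = F[1] = F[2] = 0.0;
  double d = std::sqrt(dx * dx + dy * dy + dz * dz);
  int ties = 0;
  double u[3];
  if (d < 1e-6) {                 // coincident centers: hash-seeded tie-break
    hash_direction(idi, idj, u);
    d = 1e-6;
    ties = 1;
  } else {
    u[0] = dx / d; u[1] = dy / d; u[2] = dz / d;
  }
  double R = dir_radius(ai, ci, u[2]) + dir_radius(aj, cj, u[2]);
  if (d < R) {
    double f = fp.k_rep * (R - d);
    F[0] = f * u[0]; F[1] = f * u[1]; F[2] = f * u[2];
  } else if (d < R + fp.adh_range) {
    double f = -fp.k_adh * (1.0 - (d - R) / fp.adh_range);
    F[0] = f * u[0]; F[1] = f * u[1]; F[2] = f * u[2];
  }
  return ties;
}

// [[Rcpp::export]]
NumericVector cpp_pairwise_force(NumericVector xi, NumericVector xj,
                                 double ai, double ci, double aj, double cj,
                                 int idi, int idj, List fp_list,
                                 double Lx, double Ly) {
  ForceP fp = forcep_from_list(fp_list);
  double dx = min_image(xi[0] - xj[0], Lx);
  double dy = min_image(xi[1] - xj[1], Ly);
  double dz = xi[2] - xj[2];
  double F[3];
  pair_force(dx, dy, dz, idi, idj, ai, ci, aj, cj, fp, F);
  return NumericVector::create(F[0], F[1], F[2]);
}

// ---------------------------------------------------------- spatial hashing

struct Grid {
  int nx, ny, nz;
  double csx, csy, csz, z0;
  double Lx, Ly;
  std::vector<std::vector<int>> bins;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<double>& z, double Lx_, double Ly_,
             double target_cs) {
    Lx = Lx_; Ly = Ly_;
    nx = std::max(1, (int)std::floor(Lx / target_cs));
    ny = std::max(1, (int)std::floor(Ly / target_cs));
    csx = Lx / nx; csy = Ly / ny;
    double zmin = 0.0, zmax = 1.0;
    if (!z.empty()) {
      zmin = *std::min_element(z.begin(), z.end());
      zmax = *std::max_element(z.begin(), z.end());
    }
    z0 = zmin - 1e-9;
    csz = target_cs;
    nz = std::max(1, (int)std::ceil((zmax - z0 + 1e-6) / csz));
    bins.assign((size_t)nx * ny * nz, {});
    for (size_t i = 0; i < x.size(); ++i)
      bins[index_of(x[i], y[i], z[i])].push_back((int)i);
  }

  size_t index_of(double x, double y, double z) const {
    int ix = (int)(wrap0(x, Lx) / csx); if (ix >= nx) ix = nx - 1;
    int iy = (int)(wrap0(y, Ly) / csy); if (iy >= ny) iy = ny - 1;
    int iz = (int)((z - z0) / csz);
    if (iz < 0) iz = 0;
    if (iz >= nz) iz = nz - 1;
    return ((size_t)iz * ny + iy) * nx + ix;
  }

  // visit every candidate neighbour index of position (x,y,z), deduplicated
  // when the grid has < 3 bins along a periodic axis
  template <typename FUN>
  void for_neighbours(double x, double y, double z, FUN fun) const {
    int ix = (int)(wrap0(x, Lx) / csx); if (ix >= nx) ix = nx - 1;
    int iy = (int)(wrap0(y, Ly) / csy); if (iy >= ny) iy = ny - 1;
    int iz = (int)((z - z0) / csz);
    if (iz < 0) iz = 0;
    if (iz >= nz) iz = nz - 1;
    int xs[3], ys[3], nxs = 0, nys = 0;
    for (int d = -1; d <= 1; ++d) {
      int v = (ix + d + nx) % nx;
      bool seen = false;
      for (int k = 0; k < nxs; ++k) if (xs[k] == v) seen = true;
      if (!seen) xs[nxs++] = v;
      int w = (iy + d + ny) % ny;
      seen = false;
      for (int k = 0; k < nys; ++k) if (ys[k] == w) seen = true;
      if (!seen) ys[nys++] = w;
    }
    for (int dz = -1; dz <= 1; ++dz) {
      int zz = iz + dz;
      if (zz < 0 || zz >= nz) continue;
      for (int a = 0; a < nys; ++a)
        for (int b = 0; b < nxs; ++b) {
          const std::vector<int>& bin = bins[((size_t)zz * ny + ys[a]) * nx + xs[b]];
          for (int j : bin) fun(j);
        }
    }
  }
};

// ----------------------------------------------------------------- the sim

struct Sim {
  std::vector<int> id, state;
  std::vector<double> x, y, z, a, c, age, ax, ay, ca;
  int births = 0, removals = 0, next_id = 0, tie_breaks = 0;
  double t = 0.0;
  Membrane mb;
  ForceP fp;
  LifeP lp;
  Grid grid;

  size_t n() const { return x.size(); }

  double grid_cellsize() const {
    double amax = lp.r0;
    for (size_t i = 0; i < n(); ++i) amax = std::max(amax, a[i]);
    double cs = 2.0 * amax + fp.adh_range;
    cs = std::max(cs, 3.0 * lp.r0 + 1e-9);   // exposure-cone query radius
    cs = std::max(cs, 2.0 * lp.r0 + 1e-9);   // crowding query radius
    return cs;
  }

  void rebuild_grid() { grid.build(x, y, z, mb.Lx, mb.Ly, grid_cellsize()); }

  // total mechanical force on cell i (pairwise + membrane + anchoring)
  void force_on(size_t i, double F[3]) {
    F[0] = F[1] = F[2] = 0.0;
    double Fij[3];
    grid.for_neighbours(x[i], y[i], z[i], [&](int j) {
      if ((size_t)j == i) return;
      double dx = min_image(x[i] - x[j], mb.Lx);
      double dy = min_image(y[i] - y[j], mb.Ly);
      double dz = z[i] - z[j];
      tie_breaks += pair_force(dx, dy, dz, id[i], id[j],
                               a[i], c[i], a[j], c[j], fp, Fij);
      F[0] += Fij[0]; F[1] += Fij[1]; F[2] += Fij[2];
    });
    // membrane contact (stems are attached to the membrane and held by
    // their anchor spring instead of being pushed off the surface)
    double gap = z[i] - mem_height(mb, x[i], y[i]);
    if (state[i] != ST_STEM && gap < c[i]) {
      double nv[3];
      mem_normal(mb, x[i], y[i], nv);
      double f = fp.k_mem * (c[i] - gap);
      F[0] += f * nv[0]; F[1] += f * nv[1]; F[2] += f * nv[2];
    }
    // stem anchoring spring to the on-surface anchor point
    if (state[i] == ST_STEM) {
      double azp = mem_height(mb, ax[i], ay[i]);
      F[0] += -fp.k_anchor * min_image(x[i] - ax[i], mb.Lx);
      F[1] += -fp.k_anchor * min_image(y[i] - ay[i], mb.Ly);
      F[2] += -fp.k_anchor * (z[i] - azp);
    }
  }

  int count_crowding(size_t i) const {
    double rad = 2.0 * lp.r0;
    int cnt = 0;
    grid.for_neighbours(x[i], y[i], z[i], [&](int j) {
      if ((size_t)j == i) return;
      double dx = min_image(x[i] - x[j], mb.Lx);
      double dy = min_image(y[i] - y[j], mb.Ly);
      double dz = z[i] - z[j];
      if (dx * dx + dy * dy + dz * dz <= rad * rad) ++cnt;
    });
    return cnt;
  }

  // surface exposure: no other cell center within the 45-degree upward cone
  // of height 3*r0 above cell i
  bool is_exposed(size_t i) const {
    double H = 3.0 * lp.r0;
    bool exposed = true;
    grid.for_neighbours(x[i], y[i], z[i], [&](int j) {
      if ((size_t)j == i || !exposed) return;
      double dz = z[j] - z[i];
      if (dz <= 0.0 || dz > H) return;
      double dx = min_image(x[j] - x[i], mb.Lx);
      double dy = min_image(y[j] - y[i], mb.Ly);
      if (dx * dx + dy * dy <= dz * dz) exposed = false;
    });
    return exposed;
  }

  // one Euler-Maruyama displacement pass at timestep dt_eff; returns false
  // (without moving anything) if any cell would exceed the guard
  // total forces on every cell via a half-pair sweep (each pair visited
  // once) with a squared-distance early reject, plus membrane/anchor terms
  void all_forces(std::vector<double>& FX, std::vector<double>& FY,
                  std::vector<double>& FZ) {
    size_t N = n();
    FX.assign(N, 0.0); FY.assign(N, 0.0); FZ.assign(N, 0.0);
    std::vector<double> mr(N);
    for (size_t i = 0; i < N; ++i) mr[i] = std::max(a[i], c[i]);
    double Fij[3];
    for (size_t i = 0; i < N; ++i) {
      grid.for_neighbours(x[i], y[i], z[i], [&](int j) {
        if ((size_t)j <= i) return;
        double dx = min_image(x[i] - x[j], mb.Lx);
        double dy = min_image(y[i] - y[j], mb.Ly);
        double dz = z[i] - z[j];
        double reach = mr[i] + mr[j] + fp.adh_range;
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 >= reach * reach) return;
        tie_breaks += pair_force(dx, dy, dz, id[i], id[j],
                                 a[i], c[i], a[j], c[j], fp, Fij);
        FX[i] += Fij[0]; FY[i] += Fij[1]; FZ[i] += Fij[2];
        FX[j] -= Fij[0]; FY[j] -= Fij[1]; FZ[j] -= Fij[2];
      });
      double gap = z[i] - mem_height(mb, x[i], y[i]);
      if (state[i] != ST_STEM && gap < c[i]) {
        double nv[3];
        mem_normal(mb, x[i], y[i], nv);
        double f = fp.k_mem * (c[i] - gap);
        FX[i] += f * nv[0]; FY[i] += f * nv[1]; FZ[i] += f * nv[2];
      }
      if (state[i] == ST_STEM) {
        double azp = mem_height(mb, ax[i], ay[i]);
        FX[i] += -fp.k_anchor * min_image(x[i] - ax[i], mb.Lx);
        FY[i] += -fp.k_anchor * min_image(y[i] - ay[i], mb.Ly);
        FZ[i] += -fp.k_anchor * (z[i] - azp);
      }
    }
  }

  bool try_displace(double dt_eff) {
    size_t N = n();
    rebuild_grid();
    std::vector<double> DX(N), DY(N), DZ(N);
    std::vector<double> FXv, FYv, FZv;
    all_forces(FXv, FYv, FZv);
    double max_step = 0.5 * lp.r0;
    double sq = std::sqrt(dt_eff);
    bool ok = true;
    int worst = -1;
    double worst_len = 0.0;
    for (size_t i = 0; i < N; ++i) {
      double dxv = FXv[i] / fp.gamma * dt_eff;
      double dyv = FYv[i] / fp.gamma * dt_eff;
      double dzv = FZv[i] / fp.gamma * dt_eff;
      // thermal noise only for living, non-anchored, non-cornified cells
      if (fp.noise_amp > 0.0 &&
          (state[i] == ST_PROLIF || state[i] == ST_SPINOUS || state[i] == ST_GRANULAR)) {
        dxv += fp.noise_amp * sq * norm_rand();
        dyv += fp.noise_amp * sq * norm_rand();
        dzv += fp.noise_amp * sq * norm_rand();
      }
      double steplen = std::sqrt(dxv * dxv + dyv * dyv + dzv * dzv);
      if (steplen >= max_step) {
        ok = false;
        if (steplen > worst_len) { worst_len = steplen; worst = (int)i; }
      }
      DX[i] = dxv; DY[i] = dyv; DZ[i] = dzv;
    }
    if (!ok) {
      last_overflow_id = worst >= 0 ? id[worst] : -1;
      last_overflow_len = worst_len;
      return false;
    }
    for (size_t i = 0; i < N; ++i) {
      x[i] = wrap0(x[i] + DX[i], mb.Lx);
      y[i] = wrap0(y[i] + DY[i], mb.Ly);
      z[i] += DZ[i];
    }
    return true;
  }

  int last_overflow_id = -1;
  double last_overflow_len = 0.0;

  void one_step() {
    double dt = fp.dt;
    // --- mechanics: full step, with adaptive halving on the rare force
    // spikes (e.g. two daughters placed almost coincidentally); the
    // displacement guard aborts only if even dt/16 overflows
    {
      double remaining = dt;
      int halvings = 0;
      while (remaining > 1e-12 * dt) {
        double dt_try = dt / (1 << halvings);
        if (dt_try > remaining) dt_try = remaining;
        if (try_displace(dt_try)) {
          remaining -= dt_try;
        } else if (++halvings > 4) {
          stop("displacement overflow at t=%f h: cell id %d moved %f um in one step (limit %f); reduce dt_h",
               t, last_overflow_id, last_overflow_len, 0.5 * lp.r0);
        }
      }
    }
    // --- lifecycle (cells in id order; arrays are kept id-sorted)
    size_t N = n();
    rebuild_grid();
    std::vector<size_t> dead;
    struct Daughter { double x, y, z, ca; };
    std::vector<Daughter> born;
    for (size_t i = 0; i < N; ++i) {
      double gap = z[i] - mem_height(mb, x[i], y[i]);
      if (lp.calcium_on) {
        double target = gap / (lp.diff_height + 2.0 * lp.r0);
        target = std::min(1.0, std::max(0.0, target));
        ca[i] += (target - ca[i]) * (1.0 - std::exp(-dt / lp.ca_tau));
      }
      switch (state[i]) {
      case ST_STEM: {
        double rate = 1.0 / lp.division_period;
        if (lp.division_jitter > 0.0)
          rate /= (1.0 + lp.division_jitter * (2.0 * unif_rand() - 1.0));
        double u = unif_rand();
        if (u < 1.0 - std::exp(-rate * dt) && count_crowding(i) <= lp.crowding_cap) {
          // uniform upward-hemisphere placement of the PROLIF daughter
          double uz = unif_rand();
          double phi = 2.0 * M_PI * unif_rand();
          double s = std::sqrt(std::max(0.0, 1.0 - uz * uz));
          Daughter d;
          d.x = wrap0(x[i] + lp.daughter_offset * s * std::cos(phi), mb.Lx);
          d.y = wrap0(y[i] + lp.daughter_offset * s * std::sin(phi), mb.Ly);
          d.z = z[i] + lp.daughter_offset * uz;
          d.ca = 0.0;
          born.push_back(d);
          ++births;
          age[i] = 0.0;          // stem resets its clock
        } else {
          age[i] += dt;
        }
        break;
      }
      case ST_PROLIF:
        if (gap > lp.diff_height) { state[i] = ST_SPINOUS; age[i] = 0.0; }
        else age[i] += dt;
        break;
      case ST_SPINOUS: {
        double rate = 1.0 / lp.spinous_dur;
        if (lp.calcium_on) rate *= ca[i];
        if (unif_rand() < 1.0 - std::exp(-rate * dt)) {
          state[i] = ST_GRANULAR; age[i] = 0.0;
        } else age[i] += dt;
        break;
      }
      case ST_GRANULAR:
        if (unif_rand() < 1.0 - std::exp(-dt / lp.granular_dur)) {
          state[i] = ST_CORNEOCYTE; age[i] = 0.0;
        } else age[i] += dt;
        break;
      case ST_CORNEOCYTE: {
        // volume-preserving flattening: aspect q = c/a relaxes to target
        double q = c[i] / a[i];
        q = lp.target_aspect + (q - lp.target_aspect) * std::exp(-dt / lp.flatten_tau);
        a[i] = lp.r0 * std::pow(q, -1.0 / 3.0);
        c[i] = lp.r0 * std::pow(q, 2.0 / 3.0);
        // desquamation: exponential clock gated on surface exposure
        if (unif_rand() < 1.0 - std::exp(-dt / lp.desquam_dur) && is_exposed(i)) {
          dead.push_back(i);
          ++removals;
        } else age[i] += dt;
        break;
      }
      }
    }
    // compact removed cells (order preserved, so ids stay sorted)
    if (!dead.empty()) {
      std::vector<bool> rm(N, false);
      for (size_t i : dead) rm[i] = true;
      size_t k = 0;
      for (size_t i = 0; i < N; ++i) {
        if (rm[i]) continue;
        if (k != i) {
          id[k] = id[i]; state[k] = state[i];
          x[k] = x[i]; y[k] = y[i]; z[k] = z[i];
          a[k] = a[i]; c[k] = c[i]; age[k] = age[i];
          ax[k] = ax[i]; ay[k] = ay[i]; ca[k] = ca[i];
        }
        ++k;
      }
      size_t nn = N - dead.size();
      id.resize(nn); state.resize(nn);
      x.resize(nn); y.resize(nn); z.resize(nn);
      a.resize(nn); c.resize(nn); age.resize(nn);
      ax.resize(nn); ay.resize(nn); ca.resize(nn);
    }
    for (const auto& d : born) {
      id.push_back(next_id++);
      state.push_back(ST_PROLIF);
      x.push_back(d.x); y.push_back(d.y); z.push_back(d.z);
      a.push_back(lp.r0); c.push_back(lp.r0);
      age.push_back(0.0);
      ax.push_back(NA_REAL); ay.push_back(NA_REAL);
      ca.push_back(d.ca);
    }
    t += dt;
  }

  List snapshot() const {
    size_t N = n();
    NumericVector X(N), Y(N), Z(N), A(N), C(N), AGE(N), AX(N), AY(N), CA(N);
    IntegerVector ID(N), STv(N);
    for (size_t i = 0; i < N; ++i) {
      ID[i] = id[i]; STv[i] = state[i];
      X[i] = x[i]; Y[i] = y[i]; Z[i] = z[i];
      A[i] = a[i]; C[i] = c[i]; AGE[i] = age[i];
      AX[i] = ax[i]; AY[i] = ay[i]; CA[i] = ca[i];
    }
    return List::create(_["id"] = ID, _["x"] = X, _["y"] = Y, _["z"] = Z,
                        _["a"] = A, _["c"] = C, _["state"] = STv,
                        _["age_in_state"] = AGE,
                        _["anchor_x"] = AX, _["anchor_y"] = AY, _["ca"] = CA,
                        _["t"] = t, _["births"] = births,
                        _["removals"] = removals, _["next_id"] = next_id);
  }

  void check_finite() const {
    for (size_t i = 0; i < n(); ++i)
      if (!std::isfinite(x[i]) || !std::isfinite(y[i]) || !std::isfinite(z[i]) ||
          !std::isfinite(a[i]) || !std::isfinite(c[i]))
        stop("non-finite cell coordinates at t=%f (cell id %d)", t, id[i]);
  }
};

static Sim sim_from_args(NumericVector x, NumericVector y, NumericVector z,
                         NumericVector a, NumericVector c_, IntegerVector state,
                         NumericVector age, NumericVector ax, NumericVector ay,
                         NumericVector ca, IntegerVector id,
                         List mem, List fp, List lp,
                         double t0, int births0, int removals0, int next_id) {
  Sim s;
  s.mb = membrane_from_list(mem);
  s.fp = forcep_from_list(fp);
  s.lp = lifep_from_list(lp);
  size_t N = x.size();
  s.x.assign(x.begin(), x.end());
  s.y.assign(y.begin(), y.end());
  s.z.assign(z.begin(), z.end());
  s.a.assign(a.begin(), a.end());
  s.c.assign(c_.begin(), c_.end());
  s.age.assign(age.begin(), age.end());
  s.ax.assign(ax.begin(), ax.end());
  s.ay.assign(ay.begin(), ay.end());
  s.ca.assign(ca.begin(), ca.end());
  s.id.assign(id.begin(), id.end());
  s.state.assign(state.begin(), state.end());
  s.t = t0; s.births = births0; s.removals = removals0;
  s.next_id = next_id;
  for (size_t i = 0; i < N; ++i)
    if (id[i] >= s.next_id) s.next_id = id[i] + 1;
  return s;
}

// [[Rcpp::export]]
List cpp_run(NumericVector x, NumericVector y, NumericVector z,
             NumericVector a, NumericVector c_, IntegerVector state,
             NumericVector age, NumericVector ax, NumericVector ay,
             NumericVector ca, IntegerVector id,
             List mem, List fp, List lp,
             int n_steps, int record_every,
             double t0, int births0, int removals0, int next_id) {
  Sim s = sim_from_args(x, y, z, a, c_, state, age, ax, ay, ca, id,
                        mem, fp, lp, t0, births0, removals0, next_id);
  List snaps;
  for (int k = 1; k <= n_steps; ++k) {
    s.one_step();
    if (k % 500 == 0) Rcpp::checkUserInterrupt();
    if (record_every > 0 && k % record_every == 0) {
      s.check_finite();
      snaps.push_back(s.snapshot());
    }
  }
  s.check_finite();
  return List::create(_["final"] = s.snapshot(), _["snapshots"] = snaps,
                      _["tie_breaks"] = s.tie_breaks);
}

// grid-accelerated total force on every cell of a static configuration
// (same code path the stepping loop uses)
// [[Rcpp::export]]
NumericMatrix cpp_total_forces(NumericVector x, NumericVector y, NumericVector z,
                               NumericVector a, NumericVector c_,
                               IntegerVector state,
                               NumericVector ax, NumericVector ay,
                               IntegerVector id,
                               List mem, List fp, List lp) {
  NumericVector age(x.size()), ca(x.size());
  Sim s = sim_from_args(x, y, z, a, c_, state, age, ax, ay, ca, id,
                        mem, fp, lp, 0.0, 0, 0, 0);
  s.rebuild_grid();
  NumericMatrix F(x.size(), 3);
  for (size_t i = 0; i < s.n(); ++i) {
    double f[3];
    s.force_on(i, f);
    F(i, 0) = f[0]; F(i, 1) = f[1]; F(i, 2) = f[2];
  }
  return F;
}
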