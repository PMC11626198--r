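#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Langevin dynamics of one or two coarse-grained molecules in a cubic
// periodic box. Flexible chains: per-bead BAOAB Langevin. A rigid chain is
// propagated as one rigid body (BAOAB on the center of mass plus an
// isotropic-inertia angular velocity). Nonbonded: Wang-Frenkel (cutoff
// 3*sigma_ij) + Debye-Hueckel shifted at elec_cutoff; directly bonded and
// intra-rigid pairs are excluded. All randomness comes from R's RNG so runs
// are bitwise reproducible under set.seed().

static inline double wf_alpha(double mu, double nu) {
  double rs = std::pow(3.0, 2.0 * mu);
  return 2.0 * nu * rs *
         std::pow((1.0 + 2.0 * nu) / (2.0 * nu * (rs - 1.0)), 2.0 * nu + 1.0);
}

struct Params {
  std::vector<double> sig, eps, mu, nu, q, m;
  double box, lam, diel, ecut, kC;
};

// pair force magnitude/r (i.e. dU/dr / r, to scale the displacement vector)
// and accumulate energy
static inline double pair_fr(const Params &P, int i, int j, double r2,
                             double &energy) {
  double r = std::sqrt(r2);
  double sig = 0.5 * (P.sig[i] + P.sig[j]);
  double rc = 3.0 * sig;
  double fr = 0.0;
  if (r < rc) {
    double eps = std::sqrt(P.eps[i] * P.eps[j]);
    double mu = 0.5 * (P.mu[i] + P.mu[j]);
    double nu = 0.5 * (P.nu[i] + P.nu[j]);
    double al = wf_alpha(mu, nu);
    double s = std::pow(sig / r, 2.0 * mu);
    double c = std::pow(rc / r, 2.0 * mu);
    double cm1 = c - 1.0;
    double p2n = std::pow(cm1, 2.0 * nu);
    energy += eps * al * (s - 1.0) * p2n;
    // dU/dr = eps*al*(-2mu/r) * [ s*(c-1)^2nu + 2nu*c*(s-1)*(c-1)^(2nu-1) ]
    double dudr = eps * al * (-2.0 * mu / r) *
                  (s * p2n + 2.0 * nu * c * (s - 1.0) * p2n / cm1);
    fr += dudr / r;
  }
  double qq = P.q[i] * P.q[j];
  if (qq != 0.0 && r < P.ecut) {
    double pref = P.kC * qq / P.diel;
    double ex = std::exp(-r / P.lam);
    double ucut = pref * std::exp(-P.ecut / P.lam) / P.ecut;
    energy += pref * ex / r - ucut;
    double dudr = -pref * ex * (1.0 / (r * r) + 1.0 / (r * P.lam));
    fr += dudr / r;
  }
  return fr;  // multiply by dx to get -dF ... caller applies sign
}

static inline double mimg(double d, double box) {
  return d - box * std::round(d / box);
}

static void rotate_about(double axx, double axy, double axz, double angle,
                         double &x, double &y, double &z) {
  double n = std::sqrt(axx * axx + axy * axy + axz * axz);
  if (n < 1e-300 || angle == 0.0) return;
  double ux = axx / n, uy = axy / n, uz = axz / n;
  double c = std::cos(angle), s = std::sin(angle);
  double dot = ux * x + uy * y + uz * z;
  double cx = uy * z - uz * y, cy = uz * x - ux * z, cz = ux * y - uy * x;
  double nx = x * c + cx * s + ux * dot * (1.0 - c);
  double ny = y * c + cy * s + uy * dot * (1.0 - c);
  double nz = z * c + cz * s + uz * dot * (1.0 - c);
  x = nx; y = ny; z = nz;
}

// [[Rcpp::export(name = ".langevin_run")]]
List langevin_run(NumericMatrix x0, NumericVector mass, NumericVector charge,
                  NumericVector sigma, NumericVector eps, NumericVector mu,
                  NumericVector nu, IntegerVector bond_i, IntegerVector bond_j,
                  NumericVector bond_k, NumericVector bond_r0,
                  IntegerVector rigid_idx, NumericMatrix rigid_body,
                  double box, double dt, double gamma, double kT,
                  double lambdaD, double dielectric, double elec_cutoff,
                  int n_steps, int save_every, int equil_steps) {
  const int n = x0.nrow();
  const double kB = 0.0083144626, kC = 138.935458;
  Params P;
  P.sig.assign(sigma.begin(), sigma.end());
  P.eps.assign(eps.begin(), eps.end());
  P.mu.assign(mu.begin(), mu.end());
  P.nu.assign(nu.begin(), nu.end());
  P.q.assign(charge.begin(), charge.end());
  P.m.assign(mass.begin(), mass.end());
  P.box = box; P.lam = lambdaD; P.diel = dielectric; P.ecut = elec_cutoff;
  P.kC = kC;

  std::vector<double> x(n), y(n), z(n), vx(n), vy(n), vz(n);
  std::vector<double> fx(n), fy(n), fz(n);
  std::vector<bool> is_rigid(n, false);
  for (int k = 0; k < rigid_idx.size(); ++k) is_rigid[rigid_idx[k]] = true;
  for (int i = 0; i < n; ++i) {
    x[i] = x0(i, 0); y[i] = x0(i, 1); z[i] = x0(i, 2);
  }

  // nonbonded exclusions: directly bonded pairs
  std::vector<std::pair<int, int>> excl;
  for (int b = 0; b < bond_i.size(); ++b)
    excl.push_back({std::min(bond_i[b], bond_j[b]),
                    std::max(bond_i[b], bond_j[b])});
  std::sort(excl.begin(), excl.end());
  auto excluded = [&](int i, int j) {
    if (is_rigid[i] && is_rigid[j]) return true;
    return std::binary_search(excl.begin(), excl.end(),
                              std::make_pair(std::min(i, j), std::max(i, j)));
  };

  // rigid-body state
  const int nr = rigid_idx.size();
  double Xc = 0, Yc = 0, Zc = 0, Mr = 0, Iso = 1.0;
  double Vx = 0, Vy = 0, Vz = 0, Wx = 0, Wy = 0, Wz = 0;
  std::vector<double> bx(nr), by(nr), bz(nr);  // body-frame (rotated, current)
  if (nr > 0) {
    for (int k = 0; k < nr; ++k) Mr += P.m[rigid_idx[k]];
    for (int k = 0; k < nr; ++k) {
      int i = rigid_idx[k];
      Xc += P.m[i] * x[i]; Yc += P.m[i] * y[i]; Zc += P.m[i] * z[i];
    }
    Xc /= Mr; Yc /= Mr; Zc /= Mr;
    Iso = 0.0;
    for (int k = 0; k < nr; ++k) {
      int i = rigid_idx[k];
      bx[k] = x[i] - Xc; by[k] = y[i] - Yc; bz[k] = z[i] - Zc;
      Iso += P.m[i] * (bx[k] * bx[k] + by[k] * by[k] + bz[k] * bz[k]);
    }
    Iso *= 2.0 / 3.0;
    if (Iso <= 0) Iso = Mr * 0.01;
    (void)rigid_body;  // body coordinates already embedded in x0
  }

  GetRNGstate();
  // Maxwell-Boltzmann initial velocities
  for (int i = 0; i < n; ++i) {
    double sd = std::sqrt(kT / P.m[i]);
    vx[i] = sd * norm_rand(); vy[i] = sd * norm_rand();
    vz[i] = sd * norm_rand();
  }
  if (nr > 0) {
    double sdV = std::sqrt(kT / Mr), sdW = std::sqrt(kT / Iso);
    Vx = sdV * norm_rand(); Vy = sdV * norm_rand(); Vz = sdV * norm_rand();
    Wx = sdW * norm_rand(); Wy = sdW * norm_rand(); Wz = sdW * norm_rand();
  }

  double energy = 0.0;
  auto compute_forces = [&]() {
    energy = 0.0;
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    for (int i = 0; i < n - 1; ++i)
      for (int j = i + 1; j < n; ++j) {
        if (excluded(i, j)) continue;
        double dx = mimg(x[i] - x[j], box);
        double dy = mimg(y[i] - y[j], box);
        double dz = mimg(z[i] - z[j], box);
        double r2 = dx * dx + dy * dy + dz * dz;
        double rcmax = std::max(3.0 * 0.5 * (P.sig[i] + P.sig[j]), P.ecut);
        if (r2 >= rcmax * rcmax) continue;
        double fr = pair_fr(P, i, j, r2, energy);
        // force on i = -dU/dr * rhat = -(fr)*dvec
        fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
        fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
      }
    for (int b = 0; b < bond_i.size(); ++b) {
      int i = bond_i[b], j = bond_j[b];
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r < 1e-12) continue;
      energy += 0.5 * bond_k[b] * (r - bond_r0[b]) * (r - bond_r0[b]);
      double fr = bond_k[b] * (r - bond_r0[b]) / r;
      fx[i] -= fr * dx; fy[i] -= fr * dy; fz[i] -= fr * dz;
      fx[j] += fr * dx; fy[j] += fr * dy; fz[j] += fr * dz;
    }
  };
  compute_forces();

  const double cfac = std::exp(-gamma * dt);
  const double nfac = std::sqrt(1.0 - cfac * cfac);
  int n_save = 0;
  for (int s = equil_steps; s < n_steps; s += save_every) ++n_save;
  NumericVector frames(static_cast<R_xlen_t>(n_save) * n * 3);
  NumericVector temps(n_save), energies(n_save), times(n_save);
  frames.attr("dim") = IntegerVector::create(n_save, n, 3);

  int nflex = 0;
  for (int i = 0; i < n; ++i) if (!is_rigid[i]) ++nflex;

  auto apply_rigid = [&]() {
    for (int k = 0; k < nr; ++k) {
      int i = rigid_idx[k];
      x[i] = Xc + bx[k]; y[i] = Yc + by[k]; z[i] = Zc + bz[k];
    }
  };

  int save_slot = 0;
  for (int step = 0; step < n_steps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (is_rigid[i]) continue;
      double h = 0.5 * dt / P.m[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }
    double Tqx = 0, Tqy = 0, Tqz = 0;
    if (nr > 0) {
      double Fx = 0, Fy = 0, Fz = 0;
      for (int k = 0; k < nr; ++k) {
        int i = rigid_idx[k];
        Fx += fx[i]; Fy += fy[i]; Fz += fz[i];
        Tqx += by[k] * fz[i] - bz[k] * fy[i];
        Tqy += bz[k] * fx[i] - bx[k] * fz[i];
        Tqz += bx[k] * fy[i] - by[k] * fx[i];
      }
      Vx += 0.5 * dt * Fx / Mr; Vy += 0.5 * dt * Fy / Mr;
      Vz += 0.5 * dt * Fz / Mr;
      Wx += 0.5 * dt * Tqx / Iso; Wy += 0.5 * dt * Tqy / Iso;
      Wz += 0.5 * dt * Tqz / Iso;
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (is_rigid[i]) continue;
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    if (nr > 0) {
      Xc += 0.5 * dt * Vx; Yc += 0.5 * dt * Vy; Zc += 0.5 * dt * Vz;
      double wmag = std::sqrt(Wx * Wx + Wy * Wy + Wz * Wz);
      if (wmag > 0)
        for (int k = 0; k < nr; ++k)
          rotate_about(Wx, Wy, Wz, wmag * 0.5 * dt, bx[k], by[k], bz[k]);
    }
    // O: thermostat
    for (int i = 0; i < n; ++i) {
      if (is_rigid[i]) continue;
      double sd = std::sqrt(kT / P.m[i]) * nfac;
      vx[i] = cfac * vx[i] + sd * norm_rand();
      vy[i] = cfac * vy[i] + sd * norm_rand();
      vz[i] = cfac * vz[i] + sd * norm_rand();
    }
    if (nr > 0) {
      double sdV = std::sqrt(kT / Mr) * nfac, sdW = std::sqrt(kT / Iso) * nfac;
      Vx = cfac * Vx + sdV * norm_rand();
      Vy = cfac * Vy + sdV * norm_rand();
      Vz = cfac * Vz + sdV * norm_rand();
      Wx = cfac * Wx + sdW * norm_rand();
      Wy = cfac * Wy + sdW * norm_rand();
      Wz = cfac * Wz + sdW * norm_rand();
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (is_rigid[i]) continue;
      x[i] += 0.5 * dt * vx[i]; y[i] += 0.5 * dt * vy[i];
      z[i] += 0.5 * dt * vz[i];
    }
    if (nr > 0) {
      Xc += 0.5 * dt * Vx; Yc += 0.5 * dt * Vy; Zc += 0.5 * dt * Vz;
      double wmag = std::sqrt(Wx * Wx + Wy * Wy + Wz * Wz);
      if (wmag > 0)
        for (int k = 0; k < nr; ++k)
          rotate_about(Wx, Wy, Wz, wmag * 0.5 * dt, bx[k], by[k], bz[k]);
      apply_rigid();
    }
    compute_forces();
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (is_rigid[i]) continue;
      double h = 0.5 * dt / P.m[i];
      vx[i] += h * fx[i]; vy[i] += h * fy[i]; vz[i] += h * fz[i];
    }
    if (nr > 0) {
      double Fx = 0, Fy = 0, Fz = 0;
      Tqx = Tqy = Tqz = 0;
      for (int k = 0; k < nr; ++k) {
        int i = rigid_idx[k];
        Fx += fx[i]; Fy += fy[i]; Fz += fz[i];
        Tqx += by[k] * fz[i] - bz[k] * fy[i];
        Tqy += bz[k] * fx[i] - bx[k] * fz[i];
        Tqz += bx[k] * fy[i] - by[k] * fx[i];
      }
      Vx += 0.5 * dt * Fx / Mr; Vy += 0.5 * dt * Fy / Mr;
      Vz += 0.5 * dt * Fz / Mr;
      Wx += 0.5 * dt * Tqx / Iso; Wy += 0.5 * dt * Tqy / Iso;
      Wz += 0.5 * dt * Tqz / Iso;
    }

    if (!std::isfinite(x[0]) || !std::isfinite(energy)) {
      PutRNGstate();
      stop("numerical blow-up at step %d: non-finite coordinate or energy",
           step + 1);
    }

    if (step >= equil_steps && (step - equil_steps) % save_every == 0) {
      for (int i = 0; i < n; ++i) {
        frames[save_slot + (R_xlen_t)n_save * (0L * n + i)] = x[i];
        frames[save_slot + (R_xlen_t)n_save * (1L * n + i)] = y[i];
        frames[save_slot + (R_xlen_t)n_save * (2L * n + i)] = z[i];
      }
      double ke = 0.0;
      for (int i = 0; i < n; ++i) {
        if (is_rigid[i]) continue;
        ke += 0.5 * P.m[i] *
              (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      }
      temps[save_slot] = (nflex > 0) ? 2.0 * ke / (3.0 * nflex * kB) : NA_REAL;
      energies[save_slot] = energy;
      times[save_slot] = (step + 1) * dt;
      ++save_slot;
    }
  }
  PutRNGstate();
  return List::create(_["frames"] = frames, _["kinetic_temperature"] = temps,
                      _["potential_energy"] = energies, _["time_ps"] = times);
}

// Brute-force-style helpers used by the bound-state and contact analyses.

// [[Rcpp::export(name = ".min_image_counts")]]
List min_image_counts(NumericVector frames, IntegerVector chain_a,
                      IntegerVector chain_b, double box,
                      NumericMatrix cut_pair) {
  IntegerVector dims = frames.attr("dim");
  int nf = dims[0], n = dims[1];
  int na = chain_a.size(), nb = chain_b.size();
  IntegerVector counts(nf);
  NumericVector mindist(nf);
  NumericMatrix freq(na, nb);
  for (int f = 0; f < nf; ++f) {
    int cnt = 0; double mind = R_PosInf;
    for (int ia = 0; ia < na; ++ia) {
      int i = chain_a[ia];
      double xi = frames[f + (R_xlen_t)nf * (0L * n + i)];
      double yi = frames[f + (R_xlen_t)nf * (1L * n + i)];
      double zi = frames[f + (R_xlen_t)nf * (2L * n + i)];
      for (int jb = 0; jb < nb; ++jb) {
        int j = chain_b[jb];
        double dx = mimg(xi - frames[f + (R_xlen_t)nf * (0L * n + j)], box);
        double dy = mimg(yi - frames[f + (R_xlen_t)nf * (1L * n + j)], box);
        double dz = mimg(zi - frames[f + (R_xlen_t)nf * (2L * n + j)], box);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r < mind) mind = r;
        if (r < cut_pair(ia, jb)) {
          ++cnt;
          freq(ia, jb) += 1.0;
        }
      }
    }
    counts[f] = cnt;
    mindist[f] = mind;
  }
  for (int ia = 0; ia < na; ++ia)
    for (int jb = 0; jb < nb; ++jb) freq(ia, jb) /= nf;
  return List::create(_["contacts_per_frame"] = counts,
                      _["min_distance"] = mindist,
                      _["contact_frequency"] = freq);
}
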