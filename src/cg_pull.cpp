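// Constant-speed pulling of a coarse-grained bead model.
//
// Potential terms: harmonic springs (backbone, intra-molecular contacts,
// disulphides), 12-6 Lennard-Jones wells for inter-molecular contacts,
// r^-12 repulsion for all non-excluded pairs, and the two pulling springs.
// Integrators: overdamped Euler-Maruyama Brownian dynamics (default) and
// underdamped Langevin BAOAB, which reduces to velocity Verlet when both
// friction and temperature are zero.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Forces {
  std::vector<double> fx, fy, fz;
  double energy;
  void reset(int n) {
    fx.assign(n, 0.0);
    fy.assign(n, 0.0);
    fz.assign(n, 0.0);
    energy = 0.0;
  }
};

inline void add_pair(Forces &f, int i, int j, double dx, double dy, double dz,
                     double f_over_r) {
  // f_over_r = dU/dr / r; force on i is -dU/dx_i = -f_over_r * dx
  f.fx[i] -= f_over_r * dx; f.fy[i] -= f_over_r * dy; f.fz[i] -= f_over_r * dz;
  f.fx[j] += f_over_r * dx; f.fy[j] += f_over_r * dy; f.fz[j] += f_over_r * dz;
}

} // namespace

// [[Rcpp::export]]
List cg_pull_cpp(NumericMatrix xyz0,
                 IntegerVector bond_i, IntegerVector bond_j,
                 NumericVector bond_k, NumericVector bond_r0,
                 IntegerVector lj_i, IntegerVector lj_j,
                 NumericVector lj_eps, NumericVector lj_r0,
                 IntegerMatrix excl,
                 double rep_sigma, double rep_eps,
                 int fixed_idx, int mov_idx,
                 NumericVector dir, double kappa, double v,
                 double dt, double gamma, double kBT, double mass,
                 int n_steps, int stride, int seed, bool langevin) {
  const int n = xyz0.nrow();
  const int nb = bond_i.size();
  const int nl = lj_i.size();
  const double rep_cut2 = 4.0 * rep_sigma * rep_sigma;

  std::vector<double> x(n), y(n), z(n), vx(n, 0.0), vy(n, 0.0), vz(n, 0.0);
  for (int i = 0; i < n; ++i) { x[i] = xyz0(i, 0); y[i] = xyz0(i, 1); z[i] = xyz0(i, 2); }

  const double ax0 = x[fixed_idx], ay0 = y[fixed_idx], az0 = z[fixed_idx];
  const double mx0 = x[mov_idx], my0 = y[mov_idx], mz0 = z[mov_idx];
  const double ux = dir[0], uy = dir[1], uz = dir[2];

  (void)seed;  // seeding happens on the R side before the call

  Forces f;
  auto compute_forces = [&](double t) {
    f.reset(n);
    // harmonic springs
    for (int b = 0; b < nb; ++b) {
      const int i = bond_i[b], j = bond_j[b];
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      f.energy += 0.5 * bond_k[b] * (r - bond_r0[b]) * (r - bond_r0[b]);
      add_pair(f, i, j, dx, dy, dz, bond_k[b] * (r - bond_r0[b]) / r);
    }
    // inter-molecular LJ contacts
    for (int c = 0; c < nl; ++c) {
      const int i = lj_i[c], j = lj_j[c];
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      const double r2 = dx * dx + dy * dy + dz * dz;
      const double s2 = lj_r0[c] * lj_r0[c] / r2;
      const double s6 = s2 * s2 * s2;
      f.energy += lj_eps[c] * (s6 * s6 - 2.0 * s6);
      add_pair(f, i, j, dx, dy, dz, -12.0 * lj_eps[c] * (s6 * s6 - s6) / r2);
    }
    // generic short-range repulsion for non-excluded pairs
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (excl(i, j)) continue;
        const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
        const double r2 = dx * dx + dy * dy + dz * dz;
        if (r2 >= rep_cut2) continue;
        const double s2 = rep_sigma * rep_sigma / r2;
        const double s6 = s2 * s2 * s2;
        const double s12 = s6 * s6;
        f.energy += rep_eps * s12;
        add_pair(f, i, j, dx, dy, dz, -12.0 * rep_eps * s12 / r2);
      }
    }
    // pulling springs: fixed anchor, and anchor moving at speed v along dir
    {
      const double dx = x[fixed_idx] - ax0, dy = y[fixed_idx] - ay0,
                   dz = z[fixed_idx] - az0;
      f.energy += 0.5 * kappa * (dx * dx + dy * dy + dz * dz);
      f.fx[fixed_idx] -= kappa * dx;
      f.fy[fixed_idx] -= kappa * dy;
      f.fz[fixed_idx] -= kappa * dz;
    }
    const double axt = mx0 + v * t * ux, ayt = my0 + v * t * uy,
                 azt = mz0 + v * t * uz;
    const double dxm = axt - x[mov_idx], dym = ayt - y[mov_idx],
                 dzm = azt - z[mov_idx];
    f.energy += 0.5 * kappa * (dxm * dxm + dym * dym + dzm * dzm);
    f.fx[mov_idx] += kappa * dxm;
    f.fy[mov_idx] += kappa * dym;
    f.fz[mov_idx] += kappa * dzm;
    // response force: pulling-spring extension projected on dir
    return kappa * (dxm * ux + dym * uy + dzm * uz);
  };

  const int n_rec = n_steps / stride + 1;
  NumericVector rec_t(n_rec), rec_F(n_rec), rec_E(n_rec);
  IntegerVector rec_intact(n_rec);
  int rec = 0;

  auto count_intact = [&]() {
    int m = 0;
    for (int c = 0; c < nl; ++c) {
      const int i = lj_i[c], j = lj_j[c];
      const double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      if (std::sqrt(dx * dx + dy * dy + dz * dz) < 1.5 * lj_r0[c]) ++m;
    }
    return m;
  };

  double Fpull = compute_forces(0.0);
  const double c_baoab = (gamma > 0.0) ? std::exp(-gamma * dt) : 1.0;
  const double noise_baoab =
      (gamma > 0.0) ? std::sqrt(kBT * (1.0 - c_baoab * c_baoab) / mass) : 0.0;
  const double mob = dt / gamma;
  const double noise_bd = std::sqrt(2.0 * kBT * dt / gamma);

  for (int step = 0; step <= n_steps; ++step) {
    const double t = step * dt;
    if (step % stride == 0 && rec < n_rec) {
      double ke = 0.0;
      if (langevin)
        for (int i = 0; i < n; ++i)
          ke += 0.5 * mass * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      rec_t[rec] = t;
      rec_F[rec] = Fpull;
      rec_E[rec] = f.energy + ke;
      rec_intact[rec] = count_intact();
      ++rec;
    }
    if (step == n_steps) break;

    if (!langevin) {
      for (int i = 0; i < n; ++i) {
        x[i] += mob * f.fx[i] + noise_bd * R::norm_rand();
        y[i] += mob * f.fy[i] + noise_bd * R::norm_rand();
        z[i] += mob * f.fz[i] + noise_bd * R::norm_rand();
      }
      Fpull = compute_forces(t + dt);
    } else {
      // BAOAB: B (half kick) A (half drift) O (friction+noise) A B
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * f.fx[i] / mass;
        vy[i] += 0.5 * dt * f.fy[i] / mass;
        vz[i] += 0.5 * dt * f.fz[i] / mass;
        x[i] += 0.5 * dt * vx[i];
        y[i] += 0.5 * dt * vy[i];
        z[i] += 0.5 * dt * vz[i];
      }
      if (gamma > 0.0 && kBT > 0.0) {
        for (int i = 0; i < n; ++i) {
          vx[i] = c_baoab * vx[i] + noise_baoab * R::norm_rand();
          vy[i] = c_baoab * vy[i] + noise_baoab * R::norm_rand();
          vz[i] = c_baoab * vz[i] + noise_baoab * R::norm_rand();
        }
      } else if (gamma > 0.0) {
        for (int i = 0; i < n; ++i) {
          vx[i] *= c_baoab; vy[i] *= c_baoab; vz[i] *= c_baoab;
        }
      }
      for (int i = 0; i < n; ++i) {
        x[i] += 0.5 * dt * vx[i];
        y[i] += 0.5 * dt * vy[i];
        z[i] += 0.5 * dt * vz[i];
      }
      Fpull = compute_forces(t + dt);
      for (int i = 0; i < n; ++i) {
        vx[i] += 0.5 * dt * f.fx[i] / mass;
        vy[i] += 0.5 * dt * f.fy[i] / mass;
        vz[i] += 0.5 * dt * f.fz[i] / mass;
      }
    }
    if (!std::isfinite(f.energy) || f.energy > 1e8)
      stop("energy blow-up at step %d (E = %g): reduce dt", step, f.energy);
  }

  NumericMatrix xyz_final(n, 3);
  for (int i = 0; i < n; ++i) {
    xyz_final(i, 0) = x[i]; xyz_final(i, 1) = y[i]; xyz_final(i, 2) = z[i];
  }
  return List::create(_["t"] = rec_t, _["F"] = rec_F,
                      _["n_intact"] = rec_intact, _["energy"] = rec_E,
                      _["xyz_final"] = xyz_final);
}
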