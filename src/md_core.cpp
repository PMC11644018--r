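#include <Rcpp.h>
#include <cmath>
#include <complex>
#include <vector>
using namespace Rcpp;

// Internal MD units: nm, ps, amu, kJ/mol, elementary charge.
// kJ/mol == amu nm^2 / ps^2, so accelerations are F/m directly.
static const double KE_COUL = 138.935458;   // kJ mol^-1 nm e^-2
static const double TWO_OVER_SQRTPI = 1.1283791670955126;

static inline double min_img(double x, double L) {
  return x - L * std::round(x / L);
}

struct FFParams {
  double qO, qH, kb, r0, ka, theta0, eps, sigma, c_ohrep, cutoff, alpha;
  int kmax;
};

static FFParams unpack(const List& p) {
  FFParams f;
  f.qO = p["q_o"]; f.qH = p["q_h"];
  f.kb = p["k_bond"]; f.r0 = p["r_bond"];
  f.ka = p["k_angle"]; f.theta0 = p["theta0"];
  f.eps = p["lj_eps"]; f.sigma = p["lj_sigma"];
  f.c_ohrep = p["c_ohrep"];
  f.cutoff = p["cutoff"]; f.alpha = p["ewald_alpha"];
  f.kmax = p["ewald_kmax"];
  return f;
}

// Full force/energy evaluation for O,H,H-ordered flexible water.
// Coulomb: Ewald with shifted-force real-space damping, reciprocal sum,
// self term and intramolecular exclusion corrections.  LJ O-O shifted-force.
static double forces_impl(const std::vector<double>& x,
                          std::vector<double>& F,
                          int natoms, double L, const FFParams& p,
                          double* e_parts /* len 4: coul, lj, bond, angle */) {
  const int nmol = natoms / 3;
  std::fill(F.begin(), F.end(), 0.0);
  double e_coul = 0.0, e_lj = 0.0, e_bond = 0.0, e_angle = 0.0;

  std::vector<double> q(natoms);
  for (int m = 0; m < nmol; ++m) {
    q[3 * m] = p.qO; q[3 * m + 1] = p.qH; q[3 * m + 2] = p.qH;
  }

  const double rc = p.cutoff, rc2 = rc * rc, a = p.alpha;
  // shifted-force constants at the cutoff
  const double erfc_rc = std::erfc(a * rc);
  const double uc = erfc_rc / rc;
  const double duc = -(erfc_rc / rc2 + a * TWO_OVER_SQRTPI * std::exp(-a * a * rc2) / rc);
  const double s6c = std::pow(p.sigma / rc, 6), s12c = s6c * s6c;
  const double ulj_c = 4.0 * p.eps * (s12c - s6c);
  const double dulj_c = 4.0 * p.eps * (-12.0 * s12c + 6.0 * s6c) / rc;
  const double rc16 = std::pow(rc, 16);
  const double uoh_c = p.c_ohrep / rc16;
  const double duoh_c = -16.0 * p.c_ohrep / (rc16 * rc);

  // real-space intermolecular pairs
  for (int i = 0; i < natoms; ++i) {
    for (int j = i + 1; j < natoms; ++j) {
      if (i / 3 == j / 3) continue;
      double dx = min_img(x[3 * i] - x[3 * j], L);
      double dy = min_img(x[3 * i + 1] - x[3 * j + 1], L);
      double dz = min_img(x[3 * i + 2] - x[3 * j + 2], L);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= rc2) continue;
      double r = std::sqrt(r2);
      if (r < 0.01) stop("site overlap: intermolecular distance below 0.01 nm");
      double fr = 0.0;  // dE/dr with sign folded: force = fr * (dx,dy,dz)/r
      double qq = KE_COUL * q[i] * q[j];
      double erfc_r = std::erfc(a * r);
      double gauss = a * TWO_OVER_SQRTPI * std::exp(-a * a * r2);
      e_coul += qq * (erfc_r / r - uc - duc * (r - rc));
      fr += qq * (erfc_r / r2 + gauss / r + duc);
      if (i % 3 == 0 && j % 3 == 0) {
        double s6 = std::pow(p.sigma / r, 6), s12 = s6 * s6;
        e_lj += 4.0 * p.eps * (s12 - s6) - ulj_c - dulj_c * (r - rc);
        fr += -(4.0 * p.eps * (-12.0 * s12 + 6.0 * s6) / r) + dulj_c;
      } else if ((i % 3 == 0) != (j % 3 == 0)) {
        // steep O-H repulsion: shields the bare Coulomb attraction between
        // unlike intermolecular sites (central-force-family stabilizer)
        double r16 = std::pow(r, 16);
        e_lj += p.c_ohrep / r16 - uoh_c - duoh_c * (r - rc);
        fr += 16.0 * p.c_ohrep / (r16 * r) + duoh_c;
      }
      double inv_r = 1.0 / r;
      F[3 * i] += fr * dx * inv_r;     F[3 * j] -= fr * dx * inv_r;
      F[3 * i + 1] += fr * dy * inv_r; F[3 * j + 1] -= fr * dy * inv_r;
      F[3 * i + 2] += fr * dz * inv_r; F[3 * j + 2] -= fr * dz * inv_r;
    }
  }

  // reciprocal-space sum with per-dimension phase recursion
  {
    const int kmax = p.kmax;
    const double V = L * L * L;
    const double twopi_L = 2.0 * M_PI / L;
    const double pref = 2.0 * M_PI * KE_COUL / V;
    typedef std::complex<double> cplx;
    std::vector<cplx> ex((kmax + 1) * natoms), ey((kmax + 1) * natoms),
        ez((kmax + 1) * natoms);
    for (int i = 0; i < natoms; ++i) {
      ex[i] = ey[i] = ez[i] = cplx(1.0, 0.0);
      cplx px(std::cos(twopi_L * x[3 * i]), std::sin(twopi_L * x[3 * i]));
      cplx py(std::cos(twopi_L * x[3 * i + 1]), std::sin(twopi_L * x[3 * i + 1]));
      cplx pz(std::cos(twopi_L * x[3 * i + 2]), std::sin(twopi_L * x[3 * i + 2]));
      for (int n = 1; n <= kmax; ++n) {
        ex[n * natoms + i] = ex[(n - 1) * natoms + i] * px;
        ey[n * natoms + i] = ey[(n - 1) * natoms + i] * py;
        ez[n * natoms + i] = ez[(n - 1) * natoms + i] * pz;
      }
    }
    std::vector<cplx> eik(natoms);
    const int k2max = kmax * kmax;
    for (int nx = -kmax; nx <= kmax; ++nx) {
      for (int ny = -kmax; ny <= kmax; ++ny) {
        for (int nz = -kmax; nz <= kmax; ++nz) {
          int n2 = nx * nx + ny * ny + nz * nz;
          if (n2 == 0 || n2 > k2max) continue;
          double kx = twopi_L * nx, ky = twopi_L * ny, kz = twopi_L * nz;
          double k2 = kx * kx + ky * ky + kz * kz;
          double Ak = std::exp(-k2 / (4.0 * a * a)) / k2;
          cplx S(0.0, 0.0);
          for (int i = 0; i < natoms; ++i) {
            cplx cx = nx >= 0 ? ex[nx * natoms + i] : std::conj(ex[-nx * natoms + i]);
            cplx cy = ny >= 0 ? ey[ny * natoms + i] : std::conj(ey[-ny * natoms + i]);
            cplx cz = nz >= 0 ? ez[nz * natoms + i] : std::conj(ez[-nz * natoms + i]);
            eik[i] = cx * cy * cz;
            S += q[i] * eik[i];
          }
          e_coul += pref * Ak * std::norm(S);
          cplx Sc = std::conj(S);
          for (int i = 0; i < natoms; ++i) {
            double im = std::imag(Sc * eik[i]);
            double f = 2.0 * pref * Ak * q[i] * im;
            F[3 * i] += f * kx; F[3 * i + 1] += f * ky; F[3 * i + 2] += f * kz;
          }
        }
      }
    }
    // self energy
    double sumq2 = 0.0;
    for (int i = 0; i < natoms; ++i) sumq2 += q[i] * q[i];
    e_coul -= KE_COUL * a / std::sqrt(M_PI) * sumq2;
    // intramolecular exclusion correction: remove erf(ar)/r added by the
    // reciprocal sum for bonded site pairs
    for (int m = 0; m < nmol; ++m) {
      int s[3] = {3 * m, 3 * m + 1, 3 * m + 2};
      for (int ii = 0; ii < 3; ++ii) {
        for (int jj = ii + 1; jj < 3; ++jj) {
          int i = s[ii], j = s[jj];
          double dx = x[3 * i] - x[3 * j];
          double dy = x[3 * i + 1] - x[3 * j + 1];
          double dz = x[3 * i + 2] - x[3 * j + 2];
          double r2 = dx * dx + dy * dy + dz * dz;
          double r = std::sqrt(r2);
          double qq = KE_COUL * q[i] * q[j];
          double erf_r = std::erf(a * r);
          double gauss = a * TWO_OVER_SQRTPI * std::exp(-a * a * r2);
          e_coul -= qq * erf_r / r;
          double fr = -qq * (erf_r / r2 - gauss / r);  // force magnitude on i along +d
          double inv_r = 1.0 / r;
          F[3 * i] += fr * dx * inv_r;     F[3 * j] -= fr * dx * inv_r;
          F[3 * i + 1] += fr * dy * inv_r; F[3 * j + 1] -= fr * dy * inv_r;
          F[3 * i + 2] += fr * dz * inv_r; F[3 * j + 2] -= fr * dz * inv_r;
        }
      }
    }
  }

  // intramolecular bonds and angle
  for (int m = 0; m < nmol; ++m) {
    int O = 3 * m, H1 = 3 * m + 1, H2 = 3 * m + 2;
    for (int h : {H1, H2}) {
      double dx = x[3 * h] - x[3 * O], dy = x[3 * h + 1] - x[3 * O + 1],
             dz = x[3 * h + 2] - x[3 * O + 2];
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double dev = r - p.r0;
      e_bond += 0.5 * p.kb * dev * dev;
      double fr = -p.kb * dev / r;
      F[3 * h] += fr * dx; F[3 * h + 1] += fr * dy; F[3 * h + 2] += fr * dz;
      F[3 * O] -= fr * dx; F[3 * O + 1] -= fr * dy; F[3 * O + 2] -= fr * dz;
    }
    double ux = x[3 * H1] - x[3 * O], uy = x[3 * H1 + 1] - x[3 * O + 1],
           uz = x[3 * H1 + 2] - x[3 * O + 2];
    double vx = x[3 * H2] - x[3 * O], vy = x[3 * H2 + 1] - x[3 * O + 1],
           vz = x[3 * H2 + 2] - x[3 * O + 2];
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    double c = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    c = std::max(-1.0, std::min(1.0, c));
    double th = std::acos(c);
    double s = std::sqrt(std::max(1e-12, 1.0 - c * c));
    double dev = th - p.theta0;
    e_angle += 0.5 * p.ka * dev * dev;
    double coef = p.ka * dev / s;
    double f1x = coef * (vx / (nu * nv) - c * ux / (nu * nu));
    double f1y = coef * (vy / (nu * nv) - c * uy / (nu * nu));
    double f1z = coef * (vz / (nu * nv) - c * uz / (nu * nu));
    double f2x = coef * (ux / (nu * nv) - c * vx / (nv * nv));
    double f2y = coef * (uy / (nu * nv) - c * vy / (nv * nv));
    double f2z = coef * (uz / (nu * nv) - c * vz / (nv * nv));
    F[3 * H1] += f1x; F[3 * H1 + 1] += f1y; F[3 * H1 + 2] += f1z;
    F[3 * H2] += f2x; F[3 * H2 + 1] += f2y; F[3 * H2 + 2] += f2z;
    F[3 * O] -= f1x + f2x; F[3 * O + 1] -= f1y + f2y; F[3 * O + 2] -= f1z + f2z;
  }

  if (e_parts) {
    e_parts[0] = e_coul; e_parts[1] = e_lj;
    e_parts[2] = e_bond; e_parts[3] = e_angle;
  }
  return e_coul + e_lj + e_bond + e_angle;
}

// [[Rcpp::export]]
List md_forces_cpp(NumericMatrix xyz, double box_length, List params) {
  int natoms = xyz.nrow();
  if (natoms % 3 != 0) stop("atom count must be a multiple of 3 (O,H,H)");
  FFParams p = unpack(params);
  std::vector<double> x(3 * natoms), F(3 * natoms);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  double parts[4];
  double e = forces_impl(x, F, natoms, box_length, p, parts);
  NumericMatrix Fm(natoms, 3);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) Fm(i, d) = F[3 * i + d];
  return List::create(_["forces"] = Fm, _["e_pot"] = e,
                      _["e_coulomb"] = parts[0], _["e_lj"] = parts[1],
                      _["e_bond"] = parts[2], _["e_angle"] = parts[3]);
}

// Velocity-Verlet NVE integrator. Stores coordinates/energies every `stride`
// steps (step multiples, including step 0). Optional velocity rescaling to
// target_T every rescale_every steps (equilibration mode; target_T < 0 = NVE).
// [[Rcpp::export]]
List md_run_cpp(NumericMatrix xyz, NumericMatrix vel, NumericVector masses,
                double box_length, List params, int n_steps, double dt_ps,
                int stride, double target_T, int rescale_every) {
  int natoms = xyz.nrow();
  FFParams p = unpack(params);
  const double kB = 0.0083144621;  // kJ mol^-1 K^-1
  int ndof = 3 * natoms - 3;
  std::vector<double> x(3 * natoms), v(3 * natoms), F(3 * natoms);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) {
      x[3 * i + d] = xyz(i, d);
      v[3 * i + d] = vel(i, d);
    }
  double e_pot = forces_impl(x, F, natoms, box_length, p, nullptr);
  int n_store = n_steps / stride + 1;
  NumericVector frames(n_store * natoms * 3);
  NumericVector epot_out(n_store), ekin_out(n_store), temp_out(n_store);
  IntegerVector step_out(n_store);
  int istore = 0;
  auto store = [&](int step) {
    for (int i = 0; i < natoms; ++i)
      for (int d = 0; d < 3; ++d)
        frames[(R_xlen_t)istore * natoms * 3 + (R_xlen_t)i * 3 + d] = x[3 * i + d];
    double ke = 0.0;
    for (int i = 0; i < natoms; ++i) {
      double m = masses[i];
      ke += 0.5 * m * (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
                       v[3 * i + 2] * v[3 * i + 2]);
    }
    epot_out[istore] = e_pot;
    ekin_out[istore] = ke;
    temp_out[istore] = 2.0 * ke / (kB * ndof);
    step_out[istore] = step;
    ++istore;
  };
  store(0);
  for (int step = 1; step <= n_steps; ++step) {
    for (int i = 0; i < natoms; ++i) {
      double inv_m = 1.0 / masses[i];
      for (int d = 0; d < 3; ++d) {
        v[3 * i + d] += 0.5 * dt_ps * F[3 * i + d] * inv_m;
        x[3 * i + d] += dt_ps * v[3 * i + d];
      }
    }
    e_pot = forces_impl(x, F, natoms, box_length, p, nullptr);
    for (int i = 0; i < natoms; ++i) {
      double inv_m = 1.0 / masses[i];
      for (int d = 0; d < 3; ++d) v[3 * i + d] += 0.5 * dt_ps * F[3 * i + d] * inv_m;
    }
    for (int i = 0; i < 3 * natoms; ++i)
      if (!std::isfinite(x[i]))
        stop("integration blow-up: non-finite coordinate at step %d", step);
    if (target_T > 0 && rescale_every > 0 && step % rescale_every == 0) {
      double ke = 0.0;
      for (int i = 0; i < natoms; ++i)
        ke += 0.5 * masses[i] *
              (v[3 * i] * v[3 * i] + v[3 * i + 1] * v[3 * i + 1] +
               v[3 * i + 2] * v[3 * i + 2]);
      double Tnow = 2.0 * ke / (kB * ndof);
      if (Tnow > 0) {
        double lam = std::sqrt(target_T / Tnow);
        for (double& vv : v) vv *= lam;
      }
    }
    if (step % stride == 0) store(step);
  }
  NumericMatrix xout(natoms, 3), vout(natoms, 3);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) {
      xout(i, d) = x[3 * i + d];
      vout(i, d) = v[3 * i + d];
    }
  frames.attr("dim") = IntegerVector::create(3, natoms, n_store);
  return List::create(_["frames"] = frames, _["e_pot"] = epot_out,
                      _["e_kin"] = ekin_out, _["temperature"] = temp_out,
                      _["step"] = step_out, _["xyz"] = xout, _["vel"] = vout);
}

// Capped steepest-descent relaxation (removes hot contacts after random packing).
// [[Rcpp::export]]
NumericMatrix md_relax_cpp(NumericMatrix xyz, double box_length, List params,
                           int n_steps, double max_disp) {
  int natoms = xyz.nrow();
  FFParams p = unpack(params);
  std::vector<double> x(3 * natoms), F(3 * natoms);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) x[3 * i + d] = xyz(i, d);
  for (int it = 0; it < n_steps; ++it) {
    forces_impl(x, F, natoms, box_length, p, nullptr);
    double fmax = 1e-30;
    for (double f : F) fmax = std::max(fmax, std::fabs(f));
    double scale = std::min(max_disp / fmax, 1e-5);
    for (int i = 0; i < 3 * natoms; ++i) x[i] += scale * F[i];
  }
  NumericMatrix out(natoms, 3);
  for (int i = 0; i < natoms; ++i)
    for (int d = 0; d < 3; ++d) out(i, d) = x[3 * i + d];
  return out;
}

// Plain (unshifted) Ewald Coulomb energy of an arbitrary charge set, for
// validation against direct lattice summation.  Real space via minimum image
// (valid when alpha * L / 2 is large), full reciprocal sphere, self term.
// [[Rcpp::export]]
double ewald_energy_cpp(NumericMatrix xyz, NumericVector q, double box_length,
                        double alpha, int kmax) {
  int n = xyz.nrow();
  double L = box_length, a = alpha, e = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_img(xyz(i, 0) - xyz(j, 0), L);
      double dy = min_img(xyz(i, 1) - xyz(j, 1), L);
      double dz = min_img(xyz(i, 2) - xyz(j, 2), L);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      e += KE_COUL * q[i] * q[j] * std::erfc(a * r) / r;
    }
  double V = L * L * L, twopi_L = 2.0 * M_PI / L;
  double pref = 2.0 * M_PI * KE_COUL / V;
  for (int nx = -kmax; nx <= kmax; ++nx)
    for (int ny = -kmax; ny <= kmax; ++ny)
      for (int nz = -kmax; nz <= kmax; ++nz) {
        int n2 = nx * nx + ny * ny + nz * nz;
        if (n2 == 0 || n2 > kmax * kmax) continue;
        double kx = twopi_L * nx, ky = twopi_L * ny, kz = twopi_L * nz;
        double k2 = kx * kx + ky * ky + kz * kz;
        double sr = 0.0, si = 0.0;
        for (int i = 0; i < n; ++i) {
          double ph = kx * xyz(i, 0) + ky * xyz(i, 1) + kz * xyz(i, 2);
          sr += q[i] * std::cos(ph);
          si += q[i] * std::sin(ph);
        }
        e += pref * std::exp(-k2 / (4.0 * a * a)) / k2 * (sr * sr + si * si);
      }
  double sumq2 = 0.0;
  for (int i = 0; i < n; ++i) sumq2 += q[i] * q[i];
  e -= KE_COUL * a / std::sqrt(M_PI) * sumq2;
  return e;
}
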