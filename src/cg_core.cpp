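// Coarse-grained chain energetics and Langevin dynamics.
//
// Units: lengths in Angstrom, bead mass 1, energies in reduced units
// (thermal energy at the 300 K reference = 0.45). The electrostatic
// prefactor passed from R already contains B(kappa) * K_coulomb / eps_r
// and the kcal/mol -> reduced-unit conversion, so the pair energy is
// pref * q_i * q_j * exp(-kappa r) / r.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct System {
  int n;
  std::vector<double> eps;    // n*n pair contact strengths
  std::vector<double> sig2;   // n*n squared pair distances sigma_ij^2
  std::vector<double> cut2;   // n*n squared contact cutoffs (<0: none)
  std::vector<int> pi_, pj_;  // nonbonded pair list (|i-j| > min_seq_sep)
  std::vector<int> ci_, cj_;  // charged nonbonded pairs
  std::vector<double> qq_;    // charge products for charged pairs
  // bonded terms
  std::vector<int> bi, bj; std::vector<double> bk, bd0;
  std::vector<int> ai, aj, ak; std::vector<double> aka, ath0;
  std::vector<int> di, dj, dk, dl; std::vector<double> dK, dphi0;
  double kappa, pref, ecut2;  // electrostatics; ecut2 < 0 means no cutoff
};

System build_system(const NumericMatrix& coords, const IntegerVector& type0,
                    const NumericVector& charges, const NumericMatrix& eps,
                    const NumericMatrix& sig, const NumericMatrix& bonds,
                    const NumericMatrix& angles, const NumericMatrix& dihedrals,
                    int min_seq_sep, double contact_cutoff_factor,
                    double elec_cutoff, double kappa, double elec_pref) {
  System s;
  s.n = coords.nrow();
  const int n = s.n;
  s.eps.resize(n * n); s.sig2.resize(n * n); s.cut2.resize(n * n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double e = eps(type0[i], type0[j]);
      double sg = sig(type0[i], type0[j]);
      s.eps[i * n + j] = e;
      s.sig2[i * n + j] = sg * sg;
      s.cut2[i * n + j] = contact_cutoff_factor > 0
        ? std::pow(contact_cutoff_factor * sg, 2) : -1.0;
    }
  }
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_seq_sep + 1; j < n; ++j) {
      s.pi_.push_back(i); s.pj_.push_back(j);
      double qq = charges[i] * charges[j];
      if (qq != 0.0) {
        s.ci_.push_back(i); s.cj_.push_back(j); s.qq_.push_back(qq);
      }
    }
  }
  for (int b = 0; b < bonds.nrow(); ++b) {
    s.bi.push_back((int)bonds(b, 0)); s.bj.push_back((int)bonds(b, 1));
    s.bk.push_back(bonds(b, 2)); s.bd0.push_back(bonds(b, 3));
  }
  for (int a = 0; a < angles.nrow(); ++a) {
    s.ai.push_back((int)angles(a, 0)); s.aj.push_back((int)angles(a, 1));
    s.ak.push_back((int)angles(a, 2));
    s.aka.push_back(angles(a, 3)); s.ath0.push_back(angles(a, 4));
  }
  for (int d = 0; d < dihedrals.nrow(); ++d) {
    s.di.push_back((int)dihedrals(d, 0)); s.dj.push_back((int)dihedrals(d, 1));
    s.dk.push_back((int)dihedrals(d, 2)); s.dl.push_back((int)dihedrals(d, 3));
    s.dK.push_back(dihedrals(d, 4)); s.dphi0.push_back(dihedrals(d, 5));
  }
  s.kappa = kappa; s.pref = elec_pref;
  s.ecut2 = elec_cutoff > 0 ? elec_cutoff * elec_cutoff : -1.0;
  return s;
}

// Computes forces (accumulated into f, length 3n, zeroed here) and the
// five-term energy breakdown: bonded, angular, dihedral, contacts, elec.
void forces_energy(const System& s, const double* x, double* f, double* en) {
  const int n = s.n;
  std::fill(f, f + 3 * n, 0.0);
  std::fill(en, en + 5, 0.0);

  // bonds: k (d - d0)^2
  for (size_t b = 0; b < s.bi.size(); ++b) {
    const int i = s.bi[b], j = s.bj[b];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r = std::sqrt(dx*dx + dy*dy + dz*dz);
    double dr = r - s.bd0[b];
    en[0] += s.bk[b] * dr * dr;
    double fp = -2.0 * s.bk[b] * dr / r;
    f[3*i] += fp * dx; f[3*i+1] += fp * dy; f[3*i+2] += fp * dz;
    f[3*j] -= fp * dx; f[3*j+1] -= fp * dy; f[3*j+2] -= fp * dz;
  }

  // angles: k (theta - theta0)^2
  for (size_t a = 0; a < s.ai.size(); ++a) {
    const int i = s.ai[a], j = s.aj[a], k = s.ak[a];
    double rij[3] = {x[3*i]-x[3*j], x[3*i+1]-x[3*j+1], x[3*i+2]-x[3*j+2]};
    double rkj[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
    double nij = std::sqrt(rij[0]*rij[0]+rij[1]*rij[1]+rij[2]*rij[2]);
    double nkj = std::sqrt(rkj[0]*rkj[0]+rkj[1]*rkj[1]+rkj[2]*rkj[2]);
    double cs = (rij[0]*rkj[0]+rij[1]*rkj[1]+rij[2]*rkj[2]) / (nij * nkj);
    cs = std::max(-1.0, std::min(1.0, cs));
    double th = std::acos(cs);
    double dth = th - s.ath0[a];
    en[1] += s.aka[a] * dth * dth;
    double dEdth = 2.0 * s.aka[a] * dth;
    double sn = std::sqrt(std::max(1.0 - cs * cs, 1e-16));
    double coef = dEdth / sn; // F = (dE/dth / sin) * grad(cos)
    for (int c = 0; c < 3; ++c) {
      double gi = rkj[c] / (nij * nkj) - cs * rij[c] / (nij * nij);
      double gk = rij[c] / (nij * nkj) - cs * rkj[c] / (nkj * nkj);
      f[3*i+c] += coef * gi;
      f[3*k+c] += coef * gk;
      f[3*j+c] -= coef * (gi + gk);
    }
  }

  // proline dihedrals: K (1 - cos(phi - phi0))
  for (size_t d = 0; d < s.di.size(); ++d) {
    const int i = s.di[d], j = s.dj[d], k = s.dk[d], l = s.dl[d];
    double b1[3] = {x[3*j]-x[3*i], x[3*j+1]-x[3*i+1], x[3*j+2]-x[3*i+2]};
    double b2[3] = {x[3*k]-x[3*j], x[3*k+1]-x[3*j+1], x[3*k+2]-x[3*j+2]};
    double b3[3] = {x[3*l]-x[3*k], x[3*l+1]-x[3*k+1], x[3*l+2]-x[3*k+2]};
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    double b1sq = b1[0]*b1[0]+b1[1]*b1[1]+b1[2]*b1[2];
    double b2sq = b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2];
    double b3sq = b3[0]*b3[0]+b3[1]*b3[1]+b3[2]*b3[2];
    // floor the normals (sin^2 >= 1e-4) so the torsion force stays
    // bounded when three beads pass through collinearity
    n1sq = std::max(n1sq, 1e-4 * b1sq * b2sq);
    n2sq = std::max(n2sq, 1e-4 * b2sq * b3sq);
    double nb2 = std::sqrt(b2sq);
    double m1[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2],
                    n1[0]*n2[1]-n1[1]*n2[0]};
    double y = (m1[0]*b2[0]+m1[1]*b2[1]+m1[2]*b2[2]) / nb2;
    double xx = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double phi = std::atan2(y, xx);
    en[2] += s.dK[d] * (1.0 - std::cos(phi - s.dphi0[d]));
    double dEdphi = s.dK[d] * std::sin(phi - s.dphi0[d]);
    double gi[3], gl[3];
    for (int c = 0; c < 3; ++c) {
      gi[c] = -nb2 / n1sq * n1[c];          // d(phi)/d(r_i)
      gl[c] =  nb2 / n2sq * n2[c];          // d(phi)/d(r_l)
    }
    double d12 = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2 * nb2);
    double d32 = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2 * nb2);
    for (int c = 0; c < 3; ++c) {
      double gj = -(1.0 + d12) * gi[c] + d32 * gl[c];
      double gk = d12 * gi[c] - (1.0 + d32) * gl[c];
      f[3*i+c] -= dEdphi * gi[c];
      f[3*j+c] -= dEdphi * gj;
      f[3*k+c] -= dEdphi * gk;
      f[3*l+c] -= dEdphi * gl[c];
    }
  }

  // short-range contacts: LJ 10-12, eps (5 s^12 - 6 s^10), s = sigma/r
  for (size_t p = 0; p < s.pi_.size(); ++p) {
    const int i = s.pi_[p], j = s.pj_[p];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    const int ij = i * n + j;
    double c2 = s.cut2[ij];
    if (c2 > 0 && r2 > c2) continue;
    double e = s.eps[ij];
    if (e == 0.0) continue;
    double s2 = s.sig2[ij] / r2;
    double s4 = s2 * s2, s8 = s4 * s4;
    double s10 = s8 * s2, s12 = s8 * s4;
    en[3] += e * (5.0 * s12 - 6.0 * s10);
    double fp = 60.0 * e * (s12 - s10) / r2;
    f[3*i] += fp * dx; f[3*i+1] += fp * dy; f[3*i+2] += fp * dz;
    f[3*j] -= fp * dx; f[3*j+1] -= fp * dy; f[3*j+2] -= fp * dz;
  }

  // screened electrostatics: pref * qq * exp(-kappa r) / r
  for (size_t p = 0; p < s.ci_.size(); ++p) {
    const int i = s.ci_[p], j = s.cj_[p];
    double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1], dz = x[3*i+2] - x[3*j+2];
    double r2 = dx*dx + dy*dy + dz*dz;
    if (s.ecut2 > 0 && r2 > s.ecut2) continue;
    double r = std::sqrt(r2);
    double u = s.pref * s.qq_[p] * std::exp(-s.kappa * r) / r;
    en[4] += u;
    double fp = u * (s.kappa + 1.0 / r) / r;
    f[3*i] += fp * dx; f[3*i+1] += fp * dy; f[3*i+2] += fp * dz;
    f[3*j] -= fp * dx; f[3*j+1] -= fp * dy; f[3*j+2] -= fp * dz;
  }
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_energy(NumericMatrix coords, IntegerVector type0,
                         NumericVector charges, NumericMatrix eps,
                         NumericMatrix sig, NumericMatrix bonds,
                         NumericMatrix angles, NumericMatrix dihedrals,
                         int min_seq_sep, double contact_cutoff_factor,
                         double elec_cutoff, double kappa, double elec_pref) {
  System s = build_system(coords, type0, charges, eps, sig, bonds, angles,
                          dihedrals, min_seq_sep, contact_cutoff_factor,
                          elec_cutoff, kappa, elec_pref);
  const int n = s.n;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = coords(i, c);
  double en[5];
  forces_energy(s, x.data(), f.data(), en);
  NumericVector out = NumericVector::create(
    _["bonded"] = en[0], _["angular"] = en[1], _["dihedral"] = en[2],
    _["contacts"] = en[3], _["electrostatic"] = en[4]);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix coords, IntegerVector type0,
                         NumericVector charges, NumericMatrix eps,
                         NumericMatrix sig, NumericMatrix bonds,
                         NumericMatrix angles, NumericMatrix dihedrals,
                         int min_seq_sep, double contact_cutoff_factor,
                         double elec_cutoff, double kappa, double elec_pref) {
  System s = build_system(coords, type0, charges, eps, sig, bonds, angles,
                          dihedrals, min_seq_sep, contact_cutoff_factor,
                          elec_cutoff, kappa, elec_pref);
  const int n = s.n;
  std::vector<double> x(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) x[3*i+c] = coords(i, c);
  double en[5];
  forces_energy(s, x.data(), f.data(), en);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) out(i, c) = f[3*i+c];
  return out;
}

// Langevin dynamics with the BAOAB velocity-Verlet splitting. With
// friction = 0 the scheme reduces exactly to plain velocity Verlet
// (no thermostat), which is used by the energy-conservation checks.
// [[Rcpp::export]]
List cpp_run_langevin(NumericMatrix coords, NumericMatrix vel,
                      IntegerVector type0, NumericVector charges,
                      NumericMatrix eps, NumericMatrix sig,
                      NumericMatrix bonds, NumericMatrix angles,
                      NumericMatrix dihedrals, int min_seq_sep,
                      double contact_cutoff_factor, double elec_cutoff,
                      double kappa, double elec_pref, double n_steps_d,
                      double dt, double friction, double kT,
                      double seed, double output_every_d) {
  if (dt <= 0) stop("dt must be positive");
  System s = build_system(coords, type0, charges, eps, sig, bonds, angles,
                          dihedrals, min_seq_sep, contact_cutoff_factor,
                          elec_cutoff, kappa, elec_pref);
  const int n = s.n;
  const long long n_steps = (long long)n_steps_d;
  const long long output_every = (long long)output_every_d;
  const long long n_frames = n_steps / output_every;

  std::vector<double> x(3 * n), v(3 * n), f(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) {
      x[3*i+c] = coords(i, c);
      v[3*i+c] = vel(i, c);
    }
  }

  const double c1 = std::exp(-friction * dt);
  const double c2 = (friction > 0 && kT > 0)
    ? std::sqrt(kT * (1.0 - c1 * c1)) : 0.0;
  const double half_dt = 0.5 * dt;

  std::mt19937_64 rng((uint64_t)seed);
  // explicit Box-Muller so the stream is implementation-independent
  bool have_spare = false;
  double spare = 0.0;
  auto gauss = [&]() {
    if (have_spare) { have_spare = false; return spare; }
    double u1, u2;
    do { u1 = (rng() >> 11) * (1.0 / 9007199254740992.0); } while (u1 <= 0.0);
    u2 = (rng() >> 11) * (1.0 / 9007199254740992.0);
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    have_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  };

  double en[5];
  forces_energy(s, x.data(), f.data(), en);

  NumericVector frames(n_frames * n * 3);
  NumericVector frame_steps(n_frames);
  NumericVector kinetic(n_frames);
  long long fidx = 0;

  for (long long step = 1; step <= n_steps; ++step) {
    for (int q = 0; q < 3 * n; ++q) v[q] += half_dt * f[q];
    for (int q = 0; q < 3 * n; ++q) x[q] += half_dt * v[q];
    if (c2 > 0.0) {
      for (int q = 0; q < 3 * n; ++q) v[q] = c1 * v[q] + c2 * gauss();
    } else if (friction > 0.0) {
      for (int q = 0; q < 3 * n; ++q) v[q] = c1 * v[q];
    }
    for (int q = 0; q < 3 * n; ++q) x[q] += half_dt * v[q];
    forces_energy(s, x.data(), f.data(), en);
    for (int q = 0; q < 3 * n; ++q) v[q] += half_dt * f[q];

    if (step % output_every == 0) {
      double ke = 0.0;
      bool ok = true;
      for (int q = 0; q < 3 * n; ++q) {
        ke += 0.5 * v[q] * v[q];
        if (!std::isfinite(x[q])) ok = false;
      }
      if (!ok) stop("non-finite coordinates at step %s (reduce dt)",
                    std::to_string(step));
      for (int i = 0; i < n; ++i) {
        for (int c = 0; c < 3; ++c) {
          frames[fidx * 3LL * n + (long long)c * n + i] = x[3*i+c];
        }
      }
      frame_steps[fidx] = (double)step;
      kinetic[fidx] = ke;
      ++fidx;
      if (fidx % 64 == 0) Rcpp::checkUserInterrupt();
    }
  }

  frames.attr("dim") = IntegerVector::create(n, 3, (int)n_frames);
  NumericMatrix xout(n, 3), vout(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < 3; ++c) { xout(i, c) = x[3*i+c]; vout(i, c) = v[3*i+c]; }
  }
  return List::create(_["frames"] = frames, _["steps"] = frame_steps,
                      _["kinetic"] = kinetic, _["coords"] = xout,
                      _["velocities"] = vout);
}

// Contact-count accumulation over frames: for each nonbonded pair,
// the number of frames with distance <= cutoff.
// [[Rcpp::export]]
NumericMatrix cpp_contact_counts(NumericVector frames, int n, double cutoff,
                                 int min_seq_sep) {
  IntegerVector dim = frames.attr("dim");
  const int nf = dim[2];
  NumericMatrix counts(n, n);
  const double cut2 = cutoff * cutoff;
  for (int fr = 0; fr < nf; ++fr) {
    const double* base = &frames[(long long)fr * 3LL * n];
    for (int i = 0; i < n; ++i) {
      for (int j = i + min_seq_sep + 1; j < n; ++j) {
        double dx = base[i] - base[j];
        double dy = base[n + i] - base[n + j];
        double dz = base[2 * n + i] - base[2 * n + j];
        if (dx*dx + dy*dy + dz*dz <= cut2) {
          counts(i, j) += 1.0;
          counts(j, i) += 1.0;
        }
      }
    }
  }
  return counts;
}

// Per-frame summed LJ 10-12 energy over an explicit pair list (1-based
// indices), used for class-resolved pair energetics.
// [[Rcpp::export]]
NumericVector cpp_pair_energy_series(NumericVector frames, int n,
                                     IntegerVector pair_i, IntegerVector pair_j,
                                     NumericVector pair_eps, NumericVector pair_sig) {
  IntegerVector dim = frames.attr("dim");
  const int nf = dim[2];
  NumericVector out(nf);
  for (int fr = 0; fr < nf; ++fr) {
    const double* base = &frames[(long long)fr * 3LL * n];
    double acc = 0.0;
    for (int p = 0; p < pair_i.size(); ++p) {
      const int i = pair_i[p] - 1, j = pair_j[p] - 1;
      double dx = base[i] - base[j];
      double dy = base[n + i] - base[n + j];
      double dz = base[2 * n + i] - base[2 * n + j];
      double r2 = dx*dx + dy*dy + dz*dz;
      double s2 = pair_sig[p] * pair_sig[p] / r2;
      double s4 = s2 * s2, s8 = s4 * s4;
      acc += pair_eps[p] * (5.0 * s8 * s4 - 6.0 * s8 * s2);
    }
    out[fr] = acc;
  }
  return out;
}
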