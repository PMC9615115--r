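// Rigid-body Metropolis Monte Carlo for a slab of rigid 3/4-site water
// in the NVT ensemble.  Pair energy is molecule-based: if the O-O
// minimum-image distance is inside the cutoff, the pair contributes an
// O-O Lennard-Jones term plus Coulomb terms over all charged sites,
// evaluated with the same image shift.  Orthorhombic boxes only.
// Deterministic for a given seed (own mt19937 stream, no R RNG).

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>

using namespace Rcpp;

static const double COULOMB = 332.0637133;  // kcal/mol * A / e^2

struct Mol {
  double o[3];   // oxygen position
  double R[9];   // rotation matrix (row-major), local -> lab
};

struct Model {
  std::vector<std::array<double, 4>> q;  // charged sites: local xyz + charge
  double sigma, eps;
};

static inline void rot_apply(const double R[9], const double v[3], double out[3]) {
  out[0] = R[0] * v[0] + R[1] * v[1] + R[2] * v[2];
  out[1] = R[3] * v[0] + R[4] * v[1] + R[5] * v[2];
  out[2] = R[6] * v[0] + R[7] * v[1] + R[8] * v[2];
}

static double pair_energy(const Mol &a, const Mol &b, const Model &m,
                          const double L[3], double rc2) {
  double d[3];
  for (int k = 0; k < 3; ++k) {
    d[k] = b.o[k] - a.o[k];
    d[k] -= L[k] * std::round(d[k] / L[k]);
  }
  double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (r2 > rc2) return 0.0;
  double u = 0.0;
  double s6 = m.sigma * m.sigma / r2;
  s6 = s6 * s6 * s6;
  u += 4.0 * m.eps * (s6 * s6 - s6);
  // site-site Coulomb with the O-O image shift
  const size_t ns = m.q.size();
  for (size_t ia = 0; ia < ns; ++ia) {
    double sa[3], pa[3];
    double la[3] = {m.q[ia][0], m.q[ia][1], m.q[ia][2]};
    rot_apply(a.R, la, sa);
    for (int k = 0; k < 3; ++k) pa[k] = sa[k];  // relative to a.o
    for (size_t ib = 0; ib < ns; ++ib) {
      double sb[3];
      double lb[3] = {m.q[ib][0], m.q[ib][1], m.q[ib][2]};
      rot_apply(b.R, lb, sb);
      double rr = 0.0;
      for (int k = 0; k < 3; ++k) {
        double dd = d[k] + sb[k] - pa[k];
        rr += dd * dd;
      }
      u += COULOMB * m.q[ia][3] * m.q[ib][3] / std::sqrt(rr);
    }
  }
  return u;
}

static double mol_energy(const std::vector<Mol> &mols, int i, const Mol &mi,
                         const Model &m, const double L[3], double rc2) {
  double u = 0.0;
  const int n = (int)mols.size();
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    u += pair_energy(mi, mols[j], m, L, rc2);
  }
  return u;
}

static void axis_angle_rot(const double ax[3], double ang, double R[9]) {
  double c = std::cos(ang), s = std::sin(ang), t = 1 - c;
  double x = ax[0], y = ax[1], z = ax[2];
  R[0] = t * x * x + c;     R[1] = t * x * y - s * z; R[2] = t * x * z + s * y;
  R[3] = t * x * y + s * z; R[4] = t * y * y + c;     R[5] = t * y * z - s * x;
  R[6] = t * x * z - s * y; R[7] = t * y * z + s * x; R[8] = t * z * z + c;
}

static void mat_mul(const double A[9], const double B[9], double C[9]) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      C[3 * r + c] = A[3 * r] * B[c] + A[3 * r + 1] * B[3 + c] +
                     A[3 * r + 2] * B[6 + c];
}

// [[Rcpp::export]]
List mc_water_cpp(NumericMatrix centers, NumericMatrix rotations,
                  NumericMatrix charged_sites, double sigma, double eps,
                  NumericVector box, double cutoff, double temperature,
                  int equil_sweeps, int n_frames, int sample_every,
                  double max_trans, double max_rot_deg, int seed) {
  const int n = centers.nrow();
  Model model;
  model.sigma = sigma;
  model.eps = eps;
  for (int s = 0; s < charged_sites.nrow(); ++s)
    model.q.push_back({charged_sites(s, 0), charged_sites(s, 1),
                       charged_sites(s, 2), charged_sites(s, 3)});
  double L[3] = {box[0], box[1], box[2]};
  double rc2 = cutoff * cutoff;
  double beta = 1.0 / (0.001987204259 * temperature);

  std::vector<Mol> mols(n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) mols[i].o[k] = centers(i, k);
    for (int k = 0; k < 9; ++k) mols[i].R[k] = rotations(i, k);
  }

  std::mt19937_64 rng(seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const double max_rot = max_rot_deg * M_PI / 180.0;

  long accepted = 0, attempted = 0;
  List frames(n_frames);
  NumericVector energies(n_frames);
  int total_sweeps = equil_sweeps + n_frames * sample_every;
  int frame_idx = 0;

  for (int sweep = 1; sweep <= total_sweeps; ++sweep) {
    for (int mv = 0; mv < n; ++mv) {
      int i = (int)(U(rng) * n);
      if (i == n) i = n - 1;
      Mol trial = mols[i];
      for (int k = 0; k < 3; ++k)
        trial.o[k] += (2.0 * U(rng) - 1.0) * max_trans;
      // wrap into the box
      for (int k = 0; k < 3; ++k)
        trial.o[k] -= L[k] * std::floor(trial.o[k] / L[k]);
      // random axis (marsaglia) and angle
      double ax[3];
      double s2;
      do {
        ax[0] = 2 * U(rng) - 1; ax[1] = 2 * U(rng) - 1; ax[2] = 2 * U(rng) - 1;
        s2 = ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2];
      } while (s2 > 1.0 || s2 < 1e-8);
      double inv = 1.0 / std::sqrt(s2);
      for (int k = 0; k < 3; ++k) ax[k] *= inv;
      double ang = (2.0 * U(rng) - 1.0) * max_rot;
      double dR[9], Rnew[9];
      axis_angle_rot(ax, ang, dR);
      mat_mul(dR, mols[i].R, Rnew);
      for (int k = 0; k < 9; ++k) trial.R[k] = Rnew[k];

      double u_old = mol_energy(mols, i, mols[i], model, L, rc2);
      double u_new = mol_energy(mols, i, trial, model, L, rc2);
      ++attempted;
      if (u_new <= u_old || U(rng) < std::exp(-beta * (u_new - u_old))) {
        mols[i] = trial;
        ++accepted;
      }
    }
    if (sweep > equil_sweeps && (sweep - equil_sweeps) % sample_every == 0 &&
        frame_idx < n_frames) {
      NumericMatrix c_out(n, 3), r_out(n, 9);
      for (int i = 0; i < n; ++i) {
        for (int k = 0; k < 3; ++k) c_out(i, k) = mols[i].o[k];
        for (int k = 0; k < 9; ++k) r_out(i, k) = mols[i].R[k];
      }
      double utot = 0.0;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          utot += pair_energy(mols[i], mols[j], model, L, rc2);
      energies[frame_idx] = utot;
      frames[frame_idx] = List::create(Named("centers") = c_out,
                                       Named("rotations") = r_out);
      ++frame_idx;
    }
    if (sweep % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(Named("frames") = frames,
                      Named("energies") = energies,
                      Named("acceptance") = (double)accepted / attempted);
}
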