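#include <Rcpp.h>
using namespace Rcpp;

static const double COULOMB_K = 332.0636; // kcal mol^-1 Angstrom e^-2

// Monte-Carlo projected areas of a union of disks, one value per orientation.
// coords: n x 3; rot: 9*n_orient column-major 3x3 rotation matrices.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericVector cpp_pa_areas(const NumericMatrix& coords,
                           const NumericVector& radii,
                           const NumericVector& rot,
                           const int n_hits) {
  const int n = coords.nrow();
  const int n_orient = rot.size() / 9;
  NumericVector areas(n_orient);
  std::vector<double> px(n), py(n);
  for (int o = 0; o < n_orient; ++o) {
    const double* R = &rot[9 * o];
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      const double x = coords(i, 0), y = coords(i, 1), z = coords(i, 2);
      // project rotated coordinates onto the xy plane
      px[i] = R[0] * x + R[3] * y + R[6] * z;
      py[i] = R[1] * x + R[4] * y + R[7] * z;
      xmin = std::min(xmin, px[i] - radii[i]);
      xmax = std::max(xmax, px[i] + radii[i]);
      ymin = std::min(ymin, py[i] - radii[i]);
      ymax = std::max(ymax, py[i] + radii[i]);
    }
    const double box = (xmax - xmin) * (ymax - ymin);
    int hits = 0;
    for (int k = 0; k < n_hits; ++k) {
      const double sx = xmin + unif_rand() * (xmax - xmin);
      const double sy = ymin + unif_rand() * (ymax - ymin);
      for (int i = 0; i < n; ++i) {
        const double dx = sx - px[i], dy = sy - py[i];
        if (dx * dx + dy * dy <= radii[i] * radii[i]) { ++hits; break; }
      }
    }
    areas[o] = box * (double)hits / (double)n_hits;
  }
  return areas;
}

// Nonbonded (LJ 12-6 + Coulomb) energy over a precomputed pair list, with
// optional Cartesian gradient. Pairs with r < 0.1 A contribute a large
// finite penalty; the count of such clashes is returned for the caller to
// warn on. sig/eps/qq are per-pair (combined in R once per topology).
// [[Rcpp::export]]
List cpp_pair_energy(const NumericMatrix& coords,
                     const IntegerVector& pi_, const IntegerVector& pj_,
                     const NumericVector& sig, const NumericVector& eps,
                     const NumericVector& qq, const bool want_grad) {
  const int np = pi_.size();
  double e = 0.0;
  int n_clash = 0;
  NumericMatrix grad;
  if (want_grad) grad = NumericMatrix(coords.nrow(), 3);
  for (int p = 0; p < np; ++p) {
    const int i = pi_[p], j = pj_[p];
    double dx = coords(i, 0) - coords(j, 0);
    double dy = coords(i, 1) - coords(j, 1);
    double dz = coords(i, 2) - coords(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    if (r < 0.1) { e += 1e6; ++n_clash; r = 0.1; r2 = 0.01; }
    const double sr2 = sig[p] * sig[p] / r2;
    const double sr6 = sr2 * sr2 * sr2;
    const double sr12 = sr6 * sr6;
    e += 4.0 * eps[p] * (sr12 - sr6) + qq[p] / r;
    if (want_grad) {
      // dE/dr
      const double dEdr = 4.0 * eps[p] * (-12.0 * sr12 + 6.0 * sr6) / r -
                          qq[p] / r2;
      const double f = dEdr / r;
      grad(i, 0) += f * dx; grad(i, 1) += f * dy; grad(i, 2) += f * dz;
      grad(j, 0) -= f * dx; grad(j, 1) -= f * dy; grad(j, 2) -= f * dz;
    }
  }
  if (want_grad)
    return List::create(_["energy"] = e, _["n_clash"] = n_clash,
                        _["grad"] = grad);
  return List::create(_["energy"] = e, _["n_clash"] = n_clash);
}

// Backbone hydrogen-bond term: a Gaussian distance well on N...O modulated
// by the squared cosine of the C=O...N angle (active only when the angle
// exceeds 90 degrees). Indices are 0-based triplets (N, O, carbonyl C).
// [[Rcpp::export]]
List cpp_hbond_energy(const NumericMatrix& coords,
                      const IntegerVector& ni, const IntegerVector& oi,
                      const IntegerVector& ci,
                      const double depth, const double r0, const double w,
                      const bool want_grad) {
  const int np = ni.size();
  double e = 0.0;
  NumericMatrix grad;
  if (want_grad) grad = NumericMatrix(coords.nrow(), 3);
  for (int p = 0; p < np; ++p) {
    const int N = ni[p], O = oi[p], C = ci[p];
    double ux = coords(N, 0) - coords(O, 0);
    double uy = coords(N, 1) - coords(O, 1);
    double uz = coords(N, 2) - coords(O, 2);
    double vx = coords(C, 0) - coords(O, 0);
    double vy = coords(C, 1) - coords(O, 1);
    double vz = coords(C, 2) - coords(O, 2);
    const double ru = std::sqrt(ux * ux + uy * uy + uz * uz);
    const double rv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (ru < 1e-8 || rv < 1e-8 || ru > r0 + 6.0 * w) continue;
    const double c = (ux * vx + uy * vy + uz * vz) / (ru * rv);
    if (c >= 0.0) continue;  // angle below 90 degrees: no hydrogen bond
    const double dr = ru - r0;
    const double g = std::exp(-dr * dr / (2.0 * w * w));
    e += -depth * g * c * c;
    if (want_grad) {
      const double gp = g * (-dr / (w * w));  // dg/dr
      // dc/du and dc/dv
      const double inv = 1.0 / (ru * rv);
      double dcux = vx * inv - c * ux / (ru * ru);
      double dcuy = vy * inv - c * uy / (ru * ru);
      double dcuz = vz * inv - c * uz / (ru * ru);
      double dcvx = ux * inv - c * vx / (rv * rv);
      double dcvy = uy * inv - c * vy / (rv * rv);
      double dcvz = uz * inv - c * vz / (rv * rv);
      const double a1 = -depth * gp * c * c;   // times d r/d N = u/ru
      const double a2 = -depth * g * 2.0 * c;  // times dc/d(...)
      const double gNx = a1 * ux / ru + a2 * dcux;
      const double gNy = a1 * uy / ru + a2 * dcuy;
      const double gNz = a1 * uz / ru + a2 * dcuz;
      const double gCx = a2 * dcvx, gCy = a2 * dcvy, gCz = a2 * dcvz;
      grad(N, 0) += gNx; grad(N, 1) += gNy; grad(N, 2) += gNz;
      grad(C, 0) += gCx; grad(C, 1) += gCy; grad(C, 2) += gCz;
      grad(O, 0) -= gNx + gCx; grad(O, 1) -= gNy + gCy; grad(O, 2) -= gNz + gCz;
    }
  }
  if (want_grad) return List::create(_["energy"] = e, _["grad"] = grad);
  return List::create(_["energy"] = e);
}

// Interaction energy (LJ + Coulomb, Lorentz-Berthelot combining) between two
// disjoint atom sets; used for probe-solute scoring.
// [[Rcpp::export]]
double cpp_inter_energy(const NumericMatrix& ca, const NumericVector& qa,
                        const NumericVector& siga, const NumericVector& epsa,
                        const NumericMatrix& cb, const NumericVector& qb,
                        const NumericVector& sigb, const NumericVector& epsb) {
  double e = 0.0;
  for (int i = 0; i < ca.nrow(); ++i) {
    for (int j = 0; j < cb.nrow(); ++j) {
      const double dx = ca(i, 0) - cb(j, 0);
      const double dy = ca(i, 1) - cb(j, 1);
      const double dz = ca(i, 2) - cb(j, 2);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 < 1e-4) r2 = 1e-4;
      const double s = 0.5 * (siga[i] + sigb[j]);
      const double sr6 = std::pow(s * s / r2, 3.0);
      e += 4.0 * std::sqrt(epsa[i] * epsb[j]) * (sr6 * sr6 - sr6) +
           COULOMB_K * qa[i] * qb[j] / std::sqrt(r2);
    }
  }
  return e;
}

// Solvation grid: minimum probe-solute interaction energy per voxel over a
// fixed set of probe orientations. offsets: k x 3 probe-site offsets from the
// probe centre; rot: 9*n_orient rotation matrices. Orientations in which any
// probe site sits inside 0.7 * (vdw_i + vdw_j) of a solute atom are clamped
// to +50 kcal/mol. Returns per-voxel minimum and the argmin orientation
// (1-based; 0 when all orientations clash).
// [[Rcpp::export]]
List cpp_grid_map(const NumericMatrix& vox, const NumericMatrix& sc,
                  const NumericVector& sq, const NumericVector& ssig,
                  const NumericVector& seps, const NumericVector& svdw,
                  const NumericMatrix& offsets, const NumericVector& pq,
                  const NumericVector& psig, const NumericVector& peps,
                  const NumericVector& pvdw, const NumericVector& rot,
                  const double clamp_energy) {
  const int nv = vox.nrow(), na = sc.nrow(), ns = offsets.nrow();
  const int n_orient = rot.size() / 9;
  NumericVector emin(nv);
  IntegerVector which_o(nv);
  // precompute rotated site offsets per orientation
  std::vector<double> ro(n_orient * ns * 3);
  for (int o = 0; o < n_orient; ++o) {
    const double* R = &rot[9 * o];
    for (int s = 0; s < ns; ++s) {
      const double x = offsets(s, 0), y = offsets(s, 1), z = offsets(s, 2);
      ro[(o * ns + s) * 3 + 0] = R[0] * x + R[3] * y + R[6] * z;
      ro[(o * ns + s) * 3 + 1] = R[1] * x + R[4] * y + R[7] * z;
      ro[(o * ns + s) * 3 + 2] = R[2] * x + R[5] * y + R[8] * z;
    }
  }
  for (int v = 0; v < nv; ++v) {
    double best = clamp_energy;
    int besto = 0;
    for (int o = 0; o < n_orient; ++o) {
      double e = 0.0;
      bool clash = false;
      for (int s = 0; s < ns && !clash; ++s) {
        const double sx = vox(v, 0) + ro[(o * ns + s) * 3 + 0];
        const double sy = vox(v, 1) + ro[(o * ns + s) * 3 + 1];
        const double sz = vox(v, 2) + ro[(o * ns + s) * 3 + 2];
        for (int i = 0; i < na; ++i) {
          const double dx = sx - sc(i, 0);
          const double dy = sy - sc(i, 1);
          const double dz = sz - sc(i, 2);
          const double r2 = dx * dx + dy * dy + dz * dz;
          const double rcl = 0.7 * (pvdw[s] + svdw[i]);
          if (r2 < rcl * rcl) { clash = true; break; }
          const double sg = 0.5 * (psig[s] + ssig[i]);
          const double sr6 = std::pow(sg * sg / r2, 3.0);
          e += 4.0 * std::sqrt(peps[s] * seps[i]) * (sr6 * sr6 - sr6) +
               COULOMB_K * pq[s] * sq[i] / std::sqrt(r2);
        }
      }
      if (!clash && e < best) { best = e; besto = o + 1; }
    }
    emin[v] = best;
    which_o[v] = besto;
  }
  return List::create(_["energy"] = emin, _["orientation"] = which_o);
}

// ---- annealing cycle --------------------------------------------------

static double total_energy_raw(const NumericMatrix& X,
                               const IntegerVector& pi_,
                               const IntegerVector& pj_,
                               const NumericVector& sig,
                               const NumericVector& eps,
                               const NumericVector& qq,
                               const IntegerVector& hbN,
                               const IntegerVector& hbO,
                               const IntegerVector& hbC,
                               const double depth, const double r0,
                               const double w) {
  double e = 0.0;
  const int np = pi_.size();
  for (int p = 0; p < np; ++p) {
    const int i = pi_[p], j = pj_[p];
    const double dx = X(i, 0) - X(j, 0);
    const double dy = X(i, 1) - X(j, 1);
    const double dz = X(i, 2) - X(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double r = std::sqrt(r2);
    if (r < 0.1) { e += 1e6; r = 0.1; r2 = 0.01; }
    const double sr2 = sig[p] * sig[p] / r2;
    const double sr6 = sr2 * sr2 * sr2;
    e += 4.0 * eps[p] * (sr6 * sr6 - sr6) + qq[p] / r;
  }
  for (int p = 0; p < hbN.size(); ++p) {
    const int N = hbN[p], O = hbO[p], C = hbC[p];
    const double ux = X(N, 0) - X(O, 0), uy = X(N, 1) - X(O, 1),
                 uz = X(N, 2) - X(O, 2);
    const double ru = std::sqrt(ux * ux + uy * uy + uz * uz);
    if (ru < 1e-8 || ru > r0 + 6.0 * w) continue;
    const double vx = X(C, 0) - X(O, 0), vy = X(C, 1) - X(O, 1),
                 vz = X(C, 2) - X(O, 2);
    const double rv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (rv < 1e-8) continue;
    const double c = (ux * vx + uy * vy + uz * vz) / (ru * rv);
    if (c >= 0.0) continue;
    const double dr = ru - r0;
    e += -depth * std::exp(-dr * dr / (2.0 * w * w)) * c * c;
  }
  return e;
}

// One Metropolis annealing cycle over torsion moves. Torsions are given in
// CSR layout (moved_idx / moved_ptr, 0-based); temps is the per-step
// temperature profile. Uses R's RNG (set.seed-reproducible).
// [[Rcpp::export]]
List cpp_anneal_cycle(const NumericMatrix& coords,
                      const IntegerVector& pi_, const IntegerVector& pj_,
                      const NumericVector& sig, const NumericVector& eps,
                      const NumericVector& qq, const IntegerVector& hbN,
                      const IntegerVector& hbO, const IntegerVector& hbC,
                      const double hb_depth, const double hb_r0,
                      const double hb_w, const IntegerVector& tor_a,
                      const IntegerVector& tor_b,
                      const IntegerVector& moved_idx,
                      const IntegerVector& moved_ptr,
                      const NumericVector& temps, const double sigma0,
                      const double t_max, const int heat_steps,
                      const int plateau_steps) {
  NumericMatrix X = clone(coords);
  const double kB = 0.0019872;
  const int ntor = tor_a.size();
  double e = total_energy_raw(X, pi_, pj_, sig, eps, qq, hbN, hbO, hbC,
                              hb_depth, hb_r0, hb_w);
  int n_plateau_acc = 0;
  std::vector<double> backup(3 * X.nrow());
  for (int s = 0; s < temps.size(); ++s) {
    const double T = temps[s];
    double sg = sigma0 * std::sqrt(std::max(T, 0.0) / t_max);
    if (sg < 0.01) sg = 0.01;
    const int k = std::min((int)(unif_rand() * ntor), ntor - 1);
    const double ang = norm_rand() * sg;
    const int a = tor_a[k], b = tor_b[k];
    double ax = X(b, 0) - X(a, 0), ay = X(b, 1) - X(a, 1),
           az = X(b, 2) - X(a, 2);
    const double an = std::sqrt(ax * ax + ay * ay + az * az);
    ax /= an; ay /= an; az /= an;
    const double c0 = std::cos(ang), s0 = std::sin(ang), mc = 1.0 - c0;
    // Rodrigues rotation matrix about (ax, ay, az)
    const double R00 = c0 + ax * ax * mc, R01 = ax * ay * mc - az * s0,
                 R02 = ax * az * mc + ay * s0;
    const double R10 = ay * ax * mc + az * s0, R11 = c0 + ay * ay * mc,
                 R12 = ay * az * mc - ax * s0;
    const double R20 = az * ax * mc - ay * s0,
                 R21 = az * ay * mc + ax * s0, R22 = c0 + az * az * mc;
    const double cx = X(b, 0), cy = X(b, 1), cz = X(b, 2);
    for (int m = moved_ptr[k]; m < moved_ptr[k + 1]; ++m) {
      const int i = moved_idx[m];
      backup[3 * i] = X(i, 0); backup[3 * i + 1] = X(i, 1);
      backup[3 * i + 2] = X(i, 2);
      const double px = X(i, 0) - cx, py = X(i, 1) - cy, pz = X(i, 2) - cz;
      X(i, 0) = cx + R00 * px + R01 * py + R02 * pz;
      X(i, 1) = cy + R10 * px + R11 * py + R12 * pz;
      X(i, 2) = cz + R20 * px + R21 * py + R22 * pz;
    }
    const double et = total_energy_raw(X, pi_, pj_, sig, eps, qq, hbN, hbO,
                                       hbC, hb_depth, hb_r0, hb_w);
    bool accept = et <= e;
    if (!accept && T > 0) accept = unif_rand() < std::exp(-(et - e) / (kB * T));
    if (accept) {
      e = et;
      if (s >= heat_steps && s < heat_steps + plateau_steps)
        ++n_plateau_acc;
    } else {
      for (int m = moved_ptr[k]; m < moved_ptr[k + 1]; ++m) {
        const int i = moved_idx[m];
        X(i, 0) = backup[3 * i]; X(i, 1) = backup[3 * i + 1];
        X(i, 2) = backup[3 * i + 2];
      }
    }
  }
  return List::create(_["coords"] = X, _["energy"] = e,
                      _["plateau_acceptance"] =
                        (double)n_plateau_acc / (double)plateau_steps);
}
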