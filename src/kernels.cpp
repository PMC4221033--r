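// Inner computational kernels: flux-limited upwind advection, explicit
// diffusion, detritus sinking, and the RK4 biological sub-step. All
// tracer arrays are [nx, ny, nz] column-major with x fastest; velocities
// are C-staggered (u on x-faces, v on y-faces, w on z-interfaces with
// interface 0 at the surface, positive upward, m/s). z is positive down,
// layer 0 at the surface. Columns may be truncated by kmax (wet layers);
// the all-wet case takes branch-free fast paths.
//
// The four tracers share one geometry sweep per direction so face
// velocities, donor logic and limiter ratios are evaluated once per face.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double superbee(double r) {
  double a = std::min(2.0 * r, 1.0);
  double b = std::min(r, 2.0);
  return std::max(0.0, std::max(a, b));
}

// One conservative advection update applied in place to ntr tracers.
static void adv_core(double **c, double **cn, int ntr,
                     const double *up, const double *vp, const double *wp,
                     int nx, int ny, int nz, double dx, double dy,
                     const double *dz, const int *km, bool allwet,
                     double dt, int limiter) {
  const long nxy = (long)nx * ny;
  std::vector<double> F((size_t)(nx + 1) * ntr);

  // --- x sweep (i contiguous) ------------------------------------------
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const long row = (long)nx * j + nxy * k;
      const double *urow = up + (long)(nx + 1) * j + (long)(nx + 1) * ny * k;
      for (int t = 0; t < ntr; ++t) { F[t] = 0.0; F[(size_t)nx * ntr + t] = 0.0; }
      for (int i = 1; i < nx; ++i) {
        double *Fi = F.data() + (size_t)i * ntr;
        if (!allwet && (km[i - 1 + (long)nx * j] <= k || km[i + (long)nx * j] <= k)) {
          for (int t = 0; t < ntr; ++t) Fi[t] = 0.0;
          continue;
        }
        const double uf = urow[i];
        const double af = std::fabs(uf);
        const double cc = 0.5 * af * (1.0 - af * dt / dx);
        if (uf > 0) {
          const bool ok = limiter == 1 && i >= 2 &&
            (allwet || km[i - 2 + (long)nx * j] > k);
          for (int t = 0; t < ntr; ++t) {
            const double *cr = c[t] + row;
            const double dc = cr[i] - cr[i - 1];
            double corr = 0.0;
            if (ok && dc != 0.0)
              corr = cc * superbee((cr[i - 1] - cr[i - 2]) / dc) * dc;
            Fi[t] = uf * cr[i - 1] + corr;
          }
        } else {
          const bool ok = limiter == 1 && i + 1 < nx &&
            (allwet || km[i + 1 + (long)nx * j] > k);
          for (int t = 0; t < ntr; ++t) {
            const double *cr = c[t] + row;
            const double dc = cr[i] - cr[i - 1];
            double corr = 0.0;
            if (ok && dc != 0.0)
              corr = cc * superbee((cr[i + 1] - cr[i]) / dc) * (-dc);
            Fi[t] = uf * cr[i] + corr;
          }
        }
      }
      for (int i = 0; i < nx; ++i) {
        if (!allwet && km[i + (long)nx * j] <= k) continue;
        for (int t = 0; t < ntr; ++t)
          cn[t][row + i] -= dt * (F[(size_t)(i + 1) * ntr + t] -
                                  F[(size_t)i * ntr + t]) / dx;
      }
    }
  }

  // --- y sweep (flux rows over i, i contiguous) ------------------------
  std::vector<double> G((size_t)nx * ntr);
  for (int k = 0; k < nz; ++k) {
    for (int j = 1; j < ny; ++j) {
      const long rS = (long)nx * (j - 1) + nxy * k; // south cells
      const long rN = (long)nx * j + nxy * k;       // north cells
      const double *vrow = vp + (long)nx * j + (long)nx * (ny + 1) * k;
      for (int i = 0; i < nx; ++i) {
        double *Gi = G.data() + (size_t)i * ntr;
        if (!allwet && (km[i + (long)nx * (j - 1)] <= k ||
                        km[i + (long)nx * j] <= k)) {
          for (int t = 0; t < ntr; ++t) Gi[t] = 0.0;
          continue;
        }
        const double vf = vrow[i];
        const double af = std::fabs(vf);
        const double cc = 0.5 * af * (1.0 - af * dt / dy);
        if (vf > 0) {
          const bool ok = limiter == 1 && j >= 2 &&
            (allwet || km[i + (long)nx * (j - 2)] > k);
          for (int t = 0; t < ntr; ++t) {
            const double dc = c[t][rN + i] - c[t][rS + i];
            double corr = 0.0;
            if (ok && dc != 0.0)
              corr = cc * superbee((c[t][rS + i] -
                                    c[t][rS - nx + i]) / dc) * dc;
            Gi[t] = vf * c[t][rS + i] + corr;
          }
        } else {
          const bool ok = limiter == 1 && j + 1 < ny &&
            (allwet || km[i + (long)nx * (j + 1)] > k);
          for (int t = 0; t < ntr; ++t) {
            const double dc = c[t][rN + i] - c[t][rS + i];
            double corr = 0.0;
            if (ok && dc != 0.0)
              corr = cc * superbee((c[t][rN + nx + i] -
                                    c[t][rN + i]) / dc) * (-dc);
            Gi[t] = vf * c[t][rN + i] + corr;
          }
        }
        // apply to both neighbours immediately (each interior face once)
        for (int t = 0; t < ntr; ++t) {
          cn[t][rS + i] -= dt * Gi[t] / dy;
          cn[t][rN + i] += dt * Gi[t] / dy;
        }
      }
    }
  }

  // --- z sweep (w positive up; interface m sits atop layer m) ----------
  for (int m = 1; m < nz; ++m) {
    const long rA = nxy * (m - 1); // layer above
    const long rB = nxy * m;       // layer below
    const double dzf = 0.5 * (dz[m - 1] + dz[m]);
    for (int j = 0; j < ny; ++j) {
      const long off = (long)nx * j;
      const double *wrow = wp + off + nxy * m;
      for (int i = 0; i < nx; ++i) {
        if (!allwet && km[i + off] <= m) continue;
        const double wf = wrow[i];
        const double af = std::fabs(wf);
        const double cc = 0.5 * af * (1.0 - af * dt / dzf);
        for (int t = 0; t < ntr; ++t) {
          const double ca = c[t][rA + off + i], cb = c[t][rB + off + i];
          double Fz; // upward flux
          const double dcf = ca - cb; // change along +w
          if (wf > 0) {
            Fz = wf * cb;
            if (limiter == 1 && dcf != 0.0 &&
                (m + 1 < nz && (allwet || km[i + off] > m + 1)))
              Fz += cc * superbee((cb - c[t][rB + nxy + off + i]) / dcf) * dcf;
          } else {
            Fz = wf * ca;
            if (limiter == 1 && dcf != 0.0 && m >= 2)
              Fz += cc * superbee((c[t][rA - nxy + off + i] - ca) / dcf) * dcf;
          }
          // upward flux through interface m leaves the layer below (m)
          // and enters the layer above (m-1)
          cn[t][rA + off + i] += dt * Fz / dz[m - 1];
          cn[t][rB + off + i] -= dt * Fz / dz[m];
        }
      }
    }
  }
}

static bool all_wet(const IntegerVector &kmax, int nz) {
  for (int v : kmax) if (v < nz) return false;
  return true;
}

// [[Rcpp::export]]
NumericVector adv_step_cpp(NumericVector C, NumericVector u,
                           NumericVector v, NumericVector w,
                           int nx, int ny, int nz,
                           double dx, double dy, NumericVector dz,
                           IntegerVector kmax, double dt, int limiter) {
  NumericVector Cn = clone(C);
  double *cs[1] = { C.begin() };
  double *cns[1] = { Cn.begin() };
  adv_core(cs, cns, 1, u.begin(), v.begin(), w.begin(), nx, ny, nz,
           dx, dy, dz.begin(), kmax.begin(), all_wet(kmax, nz), dt,
           limiter);
  Cn.attr("dim") = C.attr("dim");
  return Cn;
}

// [[Rcpp::export]]
List adv4_step_cpp(NumericVector N, NumericVector P, NumericVector Z,
                   NumericVector D, NumericVector u, NumericVector v,
                   NumericVector w, int nx, int ny, int nz,
                   double dx, double dy, NumericVector dz,
                   IntegerVector kmax, double dt, int limiter, int nrep) {
  NumericVector Nn = clone(N), Pn = clone(P), Zn = clone(Z), Dn = clone(D);
  std::vector<double> bufN, bufP, bufZ, bufD;
  double *cns[4] = { Nn.begin(), Pn.begin(), Zn.begin(), Dn.begin() };
  const bool aw = all_wet(kmax, nz);
  const long n = (long)nx * ny * nz;
  bufN.resize(n); bufP.resize(n); bufZ.resize(n); bufD.resize(n);
  double *cs[4] = { bufN.data(), bufP.data(), bufZ.data(), bufD.data() };
  for (int r = 0; r < nrep; ++r) {
    for (long q = 0; q < n; ++q) {
      bufN[q] = cns[0][q]; bufP[q] = cns[1][q];
      bufZ[q] = cns[2][q]; bufD[q] = cns[3][q];
    }
    adv_core(cs, cns, 4, u.begin(), v.begin(), w.begin(), nx, ny, nz,
             dx, dy, dz.begin(), kmax.begin(), aw, dt, limiter);
  }
  Nn.attr("dim") = N.attr("dim"); Pn.attr("dim") = P.attr("dim");
  Zn.attr("dim") = Z.attr("dim"); Dn.attr("dim") = D.attr("dim");
  return List::create(_["N"] = Nn, _["P"] = Pn, _["Z"] = Zn, _["D"] = Dn);
}

static void diff_core(double **c, double **cn, int ntr, int nx, int ny,
                      int nz, double dx, double dy, const double *dz,
                      const double *z_mid, const int *km, bool allwet,
                      double kh, double kv, double dt) {
  const long nxy = (long)nx * ny;
  const double rx = kh / (dx * dx), ry = kh / (dy * dy);
  for (int k = 0; k < nz; ++k) {
    const double dzu = k > 0 ? kv / ((z_mid[k] - z_mid[k - 1]) * dz[k]) : 0.0;
    const double dzd = k + 1 < nz ?
      kv / ((z_mid[k + 1] - z_mid[k]) * dz[k]) : 0.0;
    for (int j = 0; j < ny; ++j) {
      const long row = (long)nx * j + nxy * k;
      for (int i = 0; i < nx; ++i) {
        if (!allwet && km[i + (long)nx * j] <= k) continue;
        const bool e = i + 1 < nx && (allwet || km[i + 1 + (long)nx * j] > k);
        const bool wst = i > 0 && (allwet || km[i - 1 + (long)nx * j] > k);
        const bool nn = j + 1 < ny && (allwet || km[i + (long)nx * (j + 1)] > k);
        const bool ss = j > 0 && (allwet || km[i + (long)nx * (j - 1)] > k);
        const bool dn = k + 1 < nz && (allwet || km[i + (long)nx * j] > k + 1);
        for (int t = 0; t < ntr; ++t) {
          const double *cf = c[t];
          const double v0 = cf[row + i];
          double acc = 0.0;
          if (e)  acc += rx * (cf[row + i + 1] - v0);
          if (wst) acc += rx * (cf[row + i - 1] - v0);
          if (nn) acc += ry * (cf[row + nx + i] - v0);
          if (ss) acc += ry * (cf[row - nx + i] - v0);
          if (dn) acc += dzd * (cf[row + nxy + i] - v0);
          if (k > 0) acc += dzu * (cf[row - nxy + i] - v0);
          cn[t][row + i] = v0 + dt * acc;
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector diff_step_cpp(NumericVector C, int nx, int ny, int nz,
                            double dx, double dy, NumericVector dz,
                            NumericVector z_mid, IntegerVector kmax,
                            double kh, double kv, double dt) {
  NumericVector Cn = clone(C);
  double *cs[1] = { C.begin() };
  double *cns[1] = { Cn.begin() };
  diff_core(cs, cns, 1, nx, ny, nz, dx, dy, dz.begin(), z_mid.begin(),
            kmax.begin(), all_wet(kmax, nz), kh, kv, dt);
  Cn.attr("dim") = C.attr("dim");
  return Cn;
}

// [[Rcpp::export]]
List diff4_step_cpp(NumericVector N, NumericVector P, NumericVector Z,
                    NumericVector D, int nx, int ny, int nz,
                    double dx, double dy, NumericVector dz,
                    NumericVector z_mid, IntegerVector kmax,
                    double kh, double kv, double dt, int nrep) {
  NumericVector Nn = clone(N), Pn = clone(P), Zn = clone(Z), Dn = clone(D);
  double *cns[4] = { Nn.begin(), Pn.begin(), Zn.begin(), Dn.begin() };
  const bool aw = all_wet(kmax, nz);
  const long n = (long)nx * ny * nz;
  std::vector<double> bufN(n), bufP(n), bufZ(n), bufD(n);
  double *cs[4] = { bufN.data(), bufP.data(), bufZ.data(), bufD.data() };
  for (int r = 0; r < nrep; ++r) {
    for (long q = 0; q < n; ++q) {
      bufN[q] = cns[0][q]; bufP[q] = cns[1][q];
      bufZ[q] = cns[2][q]; bufD[q] = cns[3][q];
    }
    diff_core(cs, cns, 4, nx, ny, nz, dx, dy, dz.begin(), z_mid.begin(),
              kmax.begin(), aw, kh, kv, dt);
  }
  Nn.attr("dim") = N.attr("dim"); Pn.attr("dim") = P.attr("dim");
  Zn.attr("dim") = Z.attr("dim"); Dn.attr("dim") = D.attr("dim");
  return List::create(_["N"] = Nn, _["P"] = Pn, _["Z"] = Zn, _["D"] = Dn);
}

// [[Rcpp::export]]
List sink_step_cpp(NumericVector D, int nx, int ny, int nz,
                   NumericVector dz, IntegerVector kmax,
                   double S_D, double w_Dmax_ms, double dt) {
  NumericVector Dn = clone(D);
  NumericVector expo(nx * ny); // bottom export this step, mmol N m^-2
  const double *d = D.begin();
  double *dn = Dn.begin();
  const int *km = kmax.begin();
  const long nxy = (long)nx * ny;
  std::vector<double> F((size_t)(nz + 1)); // downward flux at interfaces

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      int kc = km[i + (long)nx * j];
      if (kc <= 0) continue;
      const long cell = i + (long)nx * j;
      F[0] = 0.0;
      for (int m = 1; m <= kc; ++m) {
        double dd = d[cell + nxy * (m - 1)]; // donor: layer above
        double ws = dd > 0 ? w_Dmax_ms * dd / (S_D + dd) : 0.0;
        F[m] = ws * dd;
      }
      for (int k = 0; k < kc; ++k)
        dn[cell + nxy * k] += dt * (F[k] - F[k + 1]) / dz[k];
      expo[cell] = dt * F[kc];
    }
  }
  Dn.attr("dim") = D.attr("dim");
  return List::create(_["D"] = Dn, _["export"] = expo);
}

// --- biology ------------------------------------------------------------

struct BioP {
  double r_P, m_P, m_Z, mu_Z, gamma, beta, eps, K_N, alpha_I, k_w, k_b,
         I_s, r_Z, K_Z, a1, a2, S_D, w_Dmax;
};

// limited process fluxes and tendencies for one cell; dt_days sets the
// scaled-tendency positivity limiter. Returns closure loss rate.
static inline double bio_rates(double N, double P, double Z, double D,
                               double I, const BioP &p, double dt_days,
                               double out[4]) {
  N = std::max(N, 0.0); P = std::max(P, 0.0);
  Z = std::max(Z, 0.0); D = std::max(D, 0.0);
  double U = 0.0;
  if (P > 0.0 && N > 0.0 && I > 0.0) {
    double fN = N / (p.K_N + N);
    double fI = 1.0 - std::exp(-p.alpha_I * I);
    U = p.r_P * fN * fI * P;
  }
  double GP = 0.0, GD = 0.0;
  if (Z > 0.0 && (P > 0.0 || D > 0.0)) {
    double q = p.r_Z * Z / (p.K_Z + p.a1 * P + p.a2 * D);
    GP = q * p.a1 * P;
    GD = q * p.a2 * D;
  }
  double MP = p.m_P * P;
  double MZ = p.m_Z * Z * Z;
  double EX = p.mu_Z * Z;
  double RM = p.eps * D;
  // scaled-tendency limiter: shrink a pool's outgoing fluxes so it cannot
  // cross zero within the sub-step (keeps the budget identity exact)
  double outN = U, outP = GP + MP, outZ = EX + MZ, outD = GD + RM;
  if (outN * dt_days > N && outN > 0) {
    double l = N / (outN * dt_days); U *= l;
  }
  if (outP * dt_days > P && outP > 0) {
    double l = P / (outP * dt_days); GP *= l; MP *= l;
  }
  if (outZ * dt_days > Z && outZ > 0) {
    double l = Z / (outZ * dt_days); EX *= l; MZ *= l;
  }
  if (outD * dt_days > D && outD > 0) {
    double l = D / (outD * dt_days); GD *= l; RM *= l;
  }
  out[0] = -U + EX + RM;                                   // dN
  out[1] = U - GP - MP;                                    // dP
  out[2] = p.gamma * (GP + GD) - EX - MZ;                  // dZ
  out[3] = MP + (1.0 - p.gamma) * (GP + GD) + p.beta * MZ - GD - RM; // dD
  return (1.0 - p.beta) * MZ; // permanent loss rate, mmol m^-3 day^-1
}

// [[Rcpp::export]]
List bio_step_cpp(NumericVector N, NumericVector P, NumericVector Z,
                  NumericVector D, int nx, int ny, int nz,
                  NumericVector dz, IntegerVector kmax,
                  NumericVector pvec, double dt_days, int nsub,
                  double cell_area) {
  BioP p;
  p.r_P = pvec[0]; p.m_P = pvec[1]; p.m_Z = pvec[2]; p.mu_Z = pvec[3];
  p.gamma = pvec[4]; p.beta = pvec[5]; p.eps = pvec[6]; p.K_N = pvec[7];
  p.alpha_I = pvec[8]; p.k_w = pvec[9]; p.k_b = pvec[10]; p.I_s = pvec[11];
  p.r_Z = pvec[12]; p.K_Z = pvec[13]; p.a1 = pvec[14]; p.a2 = pvec[15];
  p.S_D = pvec[16]; p.w_Dmax = pvec[17];

  NumericVector Nn = clone(N), Pn = clone(P), Zn = clone(Z), Dn = clone(D);
  NumericVector closure_map(nx * ny); // mmol N m^-2 lost this call
  double clamp_mass = 0.0;            // mmol N added by clamping negatives
  const int *km = kmax.begin();
  const long nxy = (long)nx * ny;
  const double h = dt_days / nsub;

  std::vector<double> yN(nz), yP(nz), yZ(nz), yD(nz);
  std::vector<double> sN(nz), sP(nz), sZ(nz), sD(nz);
  std::vector<double> k1(4 * nz), k2(4 * nz), k3(4 * nz), k4(4 * nz);
  std::vector<double> l1(nz), l2(nz), l3(nz), l4(nz);

  auto eval = [&](std::vector<double> &kk, std::vector<double> &ll,
                  int kc) {
    // light profile from the stage phytoplankton column (midpoint rule)
    double cum = 0.0;
    for (int k = 0; k < kc; ++k) {
      double Pk = std::max(sP[k], 0.0);
      double a = p.k_w + p.k_b * Pk;
      double I = Pk > 0.0 ?
        p.I_s * std::exp(-(cum + 0.5 * a * dz[k])) : 0.0; // I unused if P=0
      cum += a * dz[k];
      double o[4];
      ll[k] = bio_rates(sN[k], Pk, sZ[k], sD[k], I, p, h, o);
      kk[4 * k] = o[0]; kk[4 * k + 1] = o[1];
      kk[4 * k + 2] = o[2]; kk[4 * k + 3] = o[3];
    }
  };

  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const int kc = km[i + (long)nx * j];
      if (kc <= 0) continue;
      const long cell = i + (long)nx * j;
      // cells with no biology at all (N-only deep water) have zero
      // tendencies; skip the whole column if it carries no P, Z or D
      double live = 0.0;
      for (int k = 0; k < kc; ++k)
        live += Pn[cell + nxy * k] + Zn[cell + nxy * k] + Dn[cell + nxy * k];
      if (live == 0.0) continue;
      for (int k = 0; k < kc; ++k) {
        yN[k] = Nn[cell + nxy * k]; yP[k] = Pn[cell + nxy * k];
        yZ[k] = Zn[cell + nxy * k]; yD[k] = Dn[cell + nxy * k];
      }
      double col_loss = 0.0; // mmol m^-2
      for (int s = 0; s < nsub; ++s) {
        for (int k = 0; k < kc; ++k) {
          sN[k] = yN[k]; sP[k] = yP[k]; sZ[k] = yZ[k]; sD[k] = yD[k];
        }
        eval(k1, l1, kc);
        for (int k = 0; k < kc; ++k) {
          sN[k] = yN[k] + 0.5 * h * k1[4 * k];
          sP[k] = yP[k] + 0.5 * h * k1[4 * k + 1];
          sZ[k] = yZ[k] + 0.5 * h * k1[4 * k + 2];
          sD[k] = yD[k] + 0.5 * h * k1[4 * k + 3];
        }
        eval(k2, l2, kc);
        for (int k = 0; k < kc; ++k) {
          sN[k] = yN[k] + 0.5 * h * k2[4 * k];
          sP[k] = yP[k] + 0.5 * h * k2[4 * k + 1];
          sZ[k] = yZ[k] + 0.5 * h * k2[4 * k + 2];
          sD[k] = yD[k] + 0.5 * h * k2[4 * k + 3];
        }
        eval(k3, l3, kc);
        for (int k = 0; k < kc; ++k) {
          sN[k] = yN[k] + h * k3[4 * k];
          sP[k] = yP[k] + h * k3[4 * k + 1];
          sZ[k] = yZ[k] + h * k3[4 * k + 2];
          sD[k] = yD[k] + h * k3[4 * k + 3];
        }
        eval(k4, l4, kc);
        const double w1 = h / 6.0;
        for (int k = 0; k < kc; ++k) {
          yN[k] += w1 * (k1[4 * k] + 2 * k2[4 * k] + 2 * k3[4 * k] + k4[4 * k]);
          yP[k] += w1 * (k1[4 * k + 1] + 2 * k2[4 * k + 1] +
                         2 * k3[4 * k + 1] + k4[4 * k + 1]);
          yZ[k] += w1 * (k1[4 * k + 2] + 2 * k2[4 * k + 2] +
                         2 * k3[4 * k + 2] + k4[4 * k + 2]);
          yD[k] += w1 * (k1[4 * k + 3] + 2 * k2[4 * k + 3] +
                         2 * k3[4 * k + 3] + k4[4 * k + 3]);
          col_loss += w1 * (l1[k] + 2 * l2[k] + 2 * l3[k] + l4[k]) * dz[k];
          // clamp the tiny negatives the RK4 combination can produce
          if (yN[k] < 0) { clamp_mass -= yN[k] * dz[k] * cell_area; yN[k] = 0; }
          if (yP[k] < 0) { clamp_mass -= yP[k] * dz[k] * cell_area; yP[k] = 0; }
          if (yZ[k] < 0) { clamp_mass -= yZ[k] * dz[k] * cell_area; yZ[k] = 0; }
          if (yD[k] < 0) { clamp_mass -= yD[k] * dz[k] * cell_area; yD[k] = 0; }
        }
      }
      for (int k = 0; k < kc; ++k) {
        Nn[cell + nxy * k] = yN[k]; Pn[cell + nxy * k] = yP[k];
        Zn[cell + nxy * k] = yZ[k]; Dn[cell + nxy * k] = yD[k];
      }
      closure_map[cell] = col_loss;
    }
  }
  Nn.attr("dim") = N.attr("dim"); Pn.attr("dim") = P.attr("dim");
  Zn.attr("dim") = Z.attr("dim"); Dn.attr("dim") = D.attr("dim");
  return List::create(_["N"] = Nn, _["P"] = Pn, _["Z"] = Zn, _["D"] = Dn,
                      _["closure_map"] = closure_map,
                      _["clamp_mass"] = clamp_mass);
}
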