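#include <Rcpp.h>
using namespace Rcpp;

// D3Q19 velocity set; must match the R-level table exactly (index order,
// weights, opposite pairs).
static const int CX[19] = {0, 1,-1, 0, 0, 0, 0, 1,-1, 1,-1, 1,-1, 1,-1, 0, 0, 0, 0};
static const int CY[19] = {0, 0, 0, 1,-1, 0, 0, 1,-1,-1, 1, 0, 0, 0, 0, 1,-1, 1,-1};
static const int CZ[19] = {0, 0, 0, 0, 0, 1,-1, 0, 0, 0, 0, 1,-1,-1, 1, 1,-1,-1, 1};
static const double W[19] = {
  1.0/3,
  1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18, 1.0/18,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36,
  1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36, 1.0/36};
static const int OPP[19] = {0, 2, 1, 4, 3, 6, 5, 8, 7, 10, 9, 12, 11, 14, 13, 16, 15, 18, 17};
static const double CS2 = 1.0 / 3.0;

static inline double feq_i(int i, double rho, double ux, double uy, double uz,
                           double u2) {
  double cu = CX[i] * ux + CY[i] * uy + CZ[i] * uz;
  return W[i] * rho * (1.0 + cu / CS2 + cu * cu / (2.0 * CS2 * CS2)
                       - u2 / (2.0 * CS2));
}

// One fused TRT lattice-Boltzmann step: macroscopics, TRT collision with
// optional Guo forcing, streaming with boundary rules (interpolated
// bounce-back walls with elastic offset and slip, velocity inlet,
// anti-bounce-back pressure outlets), and plane flux accumulation.
// f is updated in place; fs is scratch of the same shape. rho/ux/uy/uz
// receive the pre-collision macroscopic fields.
// [[Rcpp::export]]
List lbm_step_cpp(NumericMatrix f, NumericMatrix fs, IntegerMatrix nbr,
                  double htp, double htm,
                  IntegerVector ln_site, IntegerVector ln_dir,
                  IntegerVector ln_type, NumericVector ln_q,
                  IntegerVector ln_nbr2, IntegerVector ln_out,
                  NumericVector ln_nx, NumericVector ln_ny, NumericVector ln_nz,
                  NumericVector ln_wx, NumericVector ln_wy, NumericVector ln_wz,
                  double uc_lat, NumericVector rho_out_lat,
                  double f_ratio, double elastic_coef, double rho0_lat,
                  NumericVector gvec,
                  NumericVector rho, NumericVector ux, NumericVector uy,
                  NumericVector uz,
                  IntegerVector plane_site, IntegerVector plane_id,
                  NumericMatrix plane_n, int n_planes) {
  const int n = f.nrow();
  const double gx = gvec[0], gy = gvec[1], gz = gvec[2];
  const bool forced = (gx != 0.0 || gy != 0.0 || gz != 0.0);
  const double ap = 1.0 - 1.0 / (2.0 * htp);
  const double am = 1.0 - 1.0 / (2.0 * htm);
  double umax2 = 0.0;
  bool ok = true;

  // macroscopics + collision into fs
  for (int s = 0; s < n; ++s) {
    double r = 0.0, mx = 0.0, my = 0.0, mz = 0.0;
    for (int i = 0; i < 19; ++i) {
      double v = f(s, i);
      r += v;
      mx += v * CX[i];
      my += v * CY[i];
      mz += v * CZ[i];
    }
    if (!(r > 0.0) || !R_finite(r)) ok = false;
    double vx = mx / r + 0.5 * gx;
    double vy = my / r + 0.5 * gy;
    double vz = mz / r + 0.5 * gz;
    rho[s] = r; ux[s] = vx; uy[s] = vy; uz[s] = vz;
    double u2 = vx * vx + vy * vy + vz * vz;
    if (u2 > umax2) umax2 = u2;
    double feq[19], S[19];
    for (int i = 0; i < 19; ++i) {
      feq[i] = feq_i(i, r, vx, vy, vz, u2);
      if (forced) {
        double cu = CX[i] * vx + CY[i] * vy + CZ[i] * vz;
        double tx = (CX[i] - vx) / CS2 + cu * CX[i] / (CS2 * CS2);
        double ty = (CY[i] - vy) / CS2 + cu * CY[i] / (CS2 * CS2);
        double tz = (CZ[i] - vz) / CS2 + cu * CZ[i] / (CS2 * CS2);
        S[i] = W[i] * (tx * gx + ty * gy + tz * gz);
      }
    }
    for (int i = 0; i < 19; ++i) {
      int o = OPP[i];
      double fp = 0.5 * (f(s, i) + f(s, o));
      double fm = 0.5 * (f(s, i) - f(s, o));
      double ep = 0.5 * (feq[i] + feq[o]);
      double em = 0.5 * (feq[i] - feq[o]);
      double v = f(s, i) - (fp - ep) / htp - (fm - em) / htm;
      if (forced) {
        double sp = 0.5 * (S[i] + S[OPP[i]]);
        double sm = 0.5 * (S[i] - S[OPP[i]]);
        v += ap * sp + am * sm;
      }
      fs(s, i) = v;
    }
  }

  // interior streaming
  for (int i = 0; i < 19; ++i) {
    for (int s = 0; s < n; ++s) {
      int d = nbr(s, i);
      if (d > 0) f(d - 1, i) = fs(s, i);
    }
  }

  // boundary links
  const int nl = ln_site.size();
  for (int l = 0; l < nl; ++l) {
    int s = ln_site[l] - 1;
    int i = ln_dir[l] - 1;
    int o = OPP[i];
    int type = ln_type[l];
    double rs = rho[s];
    double val;
    if (type == 2) { // outlet: anti-bounce-back at imposed density
      double ro = rho_out_lat[ln_out[l] - 1];
      double cu = CX[i] * ux[s] + CY[i] * uy[s] + CZ[i] * uz[s];
      double u2 = ux[s] * ux[s] + uy[s] * uy[s] + uz[s] * uz[s];
      val = -fs(s, i) + 2.0 * W[i] * ro *
        (1.0 + cu * cu / (2.0 * CS2 * CS2) - u2 / (2.0 * CS2));
    } else {
      double uwx = 0.0, uwy = 0.0, uwz = 0.0;
      double q = ln_q[l];
      if (type == 1) { // inlet: imposed velocity, halfway bounce-back
        uwx = uc_lat * ln_wx[l];
        uwy = uc_lat * ln_wy[l];
        uwz = uc_lat * ln_wz[l];
        q = 0.5;
      } else { // wall: tangential slip + elastic offset
        if (f_ratio > 0.0) {
          double nxl = ln_nx[l], nyl = ln_ny[l], nzl = ln_nz[l];
          double un = ux[s] * nxl + uy[s] * nyl + uz[s] * nzl;
          uwx = f_ratio * (ux[s] - un * nxl);
          uwy = f_ratio * (uy[s] - un * nyl);
          uwz = f_ratio * (uz[s] - un * nzl);
        }
        if (elastic_coef != 0.0) {
          double dr = elastic_coef * (rs - rho0_lat);
          if (dr > 0.5) dr = 0.5;
          if (dr < -0.5) dr = -0.5;
          q += dr;
          if (q < 0.05) q = 0.05;
          if (q > 1.0) q = 1.0;
        }
      }
      double cuw = CX[i] * uwx + CY[i] * uwy + CZ[i] * uwz;
      double vt = 2.0 * W[i] * rs * cuw / CS2;
      double fo = fs(s, i);
      if (q <= 0.5) {
        int s2 = ln_nbr2[l];
        double f2 = (s2 > 0) ? fs(s2 - 1, i) : fo;
        val = 2.0 * q * fo + (1.0 - 2.0 * q) * f2 - vt;
      } else {
        val = fo / (2.0 * q) + (1.0 - 1.0 / (2.0 * q)) * fs(s, o)
          - vt / (2.0 * q);
      }
    }
    f(s, o) = val;
  }

  // plane fluxes (lattice units, per unit lattice area)
  NumericVector Q(n_planes);
  const int np = plane_site.size();
  for (int p = 0; p < np; ++p) {
    int s = plane_site[p] - 1;
    int id = plane_id[p] - 1;
    Q[id] += ux[s] * plane_n(p, 0) + uy[s] * plane_n(p, 1)
      + uz[s] * plane_n(p, 2);
  }

  return List::create(_["Q"] = Q, _["umax2"] = umax2, _["ok"] = ok);
}
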