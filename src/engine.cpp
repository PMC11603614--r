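// Compiled core: overdamped Langevin segments with OPES Explore and
// MultiThermal biases evaluated in the inner loop. R orchestrates events
// (kernel deposits, MultiThermal refreshes, replica exchanges) and calls
// engine_run_segment() for the stretches in between. All randomness comes
// from R's RNG so a seed set in R fixes the trajectory bitwise.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct ExploreBias {
  std::vector<int> cv;          // 0-based coordinate indices
  std::vector<double> centers;  // K x k, row-major
  std::vector<double> weights;  // per-kernel weight (merged kernels > 1)
  std::vector<double> inv2s2;   // 1/(2 sigma^2) per dim
  std::vector<double> invs2;    // 1/sigma^2 per dim
  std::vector<double> period;   // 0 = aperiodic
  double pref;                  // (gamma - 1) * kB*T
  double eps;
  double invM;                  // 1 / sup of kernel sum over centers
  int K, k;
  bool active;
};

inline double wrap_diff(double d, double per) {
  if (per > 0.0) {
    d -= per * std::floor(d / per + 0.5);
  }
  return d;
}

// kernel-sum S(s) and dS/ds; returns S
inline double kernel_sum(const ExploreBias& b, const double* s, double* grad) {
  double S = 0.0;
  for (int j = 0; j < b.k; ++j) grad[j] = 0.0;
  const double* c = b.centers.data();
  for (int i = 0; i < b.K; ++i) {
    double e = 0.0;
    double dz[8];
    for (int j = 0; j < b.k; ++j) {
      double d = wrap_diff(s[j] - c[i * b.k + j], b.period[j]);
      dz[j] = d;
      e += d * d * b.inv2s2[j];
    }
    if (e < 30.0) {
      double g = b.weights[i] * std::exp(-e);
      S += g;
      for (int j = 0; j < b.k; ++j) grad[j] -= g * dz[j] * b.invs2[j];
    }
  }
  return S;
}

// bias value and accumulate force on coordinates; force -= dV/dx
inline double explore_bias_force(const ExploreBias& b, const double* x,
                                 double* force) {
  if (!b.active || b.K == 0) return 0.0;
  double s[8], gradS[8];
  for (int j = 0; j < b.k; ++j) s[j] = x[b.cv[j]];
  double S = kernel_sum(b, s, gradS);
  double ratio = S * b.invM;
  if (ratio >= 1.0) {
    return 0.0;  // clamped top of the estimate: V = 0 in the [-dE, 0] gauge
  }
  double V = b.pref * (std::log(ratio + b.eps) - std::log1p(b.eps));
  double fac = b.pref / (ratio + b.eps) * b.invM;
  for (int j = 0; j < b.k; ++j) force[b.cv[j]] -= fac * gradS[j];
  return V;
}

struct MultiThermal {
  std::vector<double> dbeta;  // beta_lambda - beta_0
  std::vector<double> clam;   // log-FEP constants, gauge clam[0] = 0
  double kT0;
  bool active;
};

// V(U) = -kT0 * log( (1/NT) sum_l exp(-dbeta_l U - c_l) ); also dV/dU
inline double mt_bias(const MultiThermal& mt, double U, double* dVdU) {
  int NT = (int)mt.dbeta.size();
  double amax = -1e300;
  double a[64];
  for (int l = 0; l < NT; ++l) {
    a[l] = -mt.dbeta[l] * U - mt.clam[l];
    if (a[l] > amax) amax = a[l];
  }
  double S = 0.0, Sd = 0.0;
  for (int l = 0; l < NT; ++l) {
    double e = std::exp(a[l] - amax);
    S += e;
    Sd += e * mt.dbeta[l];
  }
  *dVdU = mt.kT0 * Sd / S;
  return -mt.kT0 * (amax + std::log(S / NT));
}

struct Walls {
  bool has;
  double Rcyl, tana, zcc, kwall, zlo, zhi, kz;
  bool dual;
};

// base potential energy and force; force is overwritten
double potential(int pot_id, const NumericVector& par, const Walls& w,
                 const double* x, int d, double* force) {
  for (int j = 0; j < d; ++j) force[j] = 0.0;
  double U = 0.0;
  if (pot_id == 1) {  // symmetric quartic double well: par = (B, h)
    double B = par[0], h = par[1];
    double t = x[0] / h;
    double t2m1 = t * t - 1.0;
    U = B * t2m1 * t2m1;
    force[0] = -4.0 * B * t * t2m1 / h;
  } else if (pot_id == 2) {  // toy host-guest: par = (D, w, c, Bq, has_q)
    double D = par[0], ww = par[1], c = par[2], Bq = par[3];
    bool has_q = par[4] > 0.5;
    double r2 = x[0] * x[0] + x[1] * x[1] + x[2] * x[2];
    double b = std::exp(-r2 / (2.0 * ww * ww));
    double q = has_q ? x[3] : 0.0;
    U = -D * b;
    double dUdb = -D;
    if (has_q) {
      double q2m1 = q * q - 1.0;
      U += Bq * q2m1 * q2m1 + c * q * b;
      dUdb += c * q;
      force[3] = -(4.0 * Bq * q * q2m1 + c * b);
    }
    double fac = dUdb * b / (ww * ww);  // force_i = -dU/dr_i = fac * r_i
    for (int j = 0; j < 3; ++j) force[j] += fac * x[j];
  } else if (pot_id == 3) {  // harmonic: par = spring constant per dim
    for (int j = 0; j < d; ++j) {
      U += 0.5 * par[j] * x[j] * x[j];
      force[j] = -par[j] * x[j];
    }
  } else if (pot_id == 4) {  // flat (walls only)
  } else {
    stop("unknown potential id %d", pot_id);
  }
  if (w.has && d >= 3) {
    double rho2 = x[0] * x[0] + x[1] * x[1];
    double rho = std::sqrt(rho2);
    double z = x[2];
    double zz = w.dual ? std::fabs(z) : z;
    double Ra = w.Rcyl + w.tana * std::max(0.0, w.zcc - zz);
    if (rho > Ra) {
      double ex = rho - Ra;
      U += 0.5 * w.kwall * ex * ex;
      if (rho > 1e-12) {
        force[0] -= w.kwall * ex * x[0] / rho;
        force[1] -= w.kwall * ex * x[1] / rho;
      }
      if (zz < w.zcc) {
        double s = w.dual ? (z >= 0.0 ? 1.0 : -1.0) : 1.0;
        force[2] -= w.kwall * ex * w.tana * s;
      }
    }
    if (z < w.zlo) {
      U += 0.5 * w.kz * (z - w.zlo) * (z - w.zlo);
      force[2] -= w.kz * (z - w.zlo);
    } else if (z > w.zhi) {
      U += 0.5 * w.kz * (z - w.zhi) * (z - w.zhi);
      force[2] -= w.kz * (z - w.zhi);
    }
  }
  return U;
}

ExploreBias make_explore(const List& li) {
  ExploreBias b;
  IntegerVector cv = li["cv"];
  NumericMatrix cen = li["centers"];
  NumericVector sig = li["sigma"], per = li["period"], wts = li["weights"];
  b.k = cv.size();
  if (b.k > 8) stop("at most 8 CVs per bias in the compiled engine");
  b.K = cen.nrow();
  b.cv.assign(cv.begin(), cv.end());
  if (wts.size() != b.K) stop("kernel weight length mismatch");
  b.weights.assign(wts.begin(), wts.end());
  b.centers.resize((size_t)b.K * b.k);
  for (int i = 0; i < b.K; ++i)
    for (int j = 0; j < b.k; ++j) b.centers[(size_t)i * b.k + j] = cen(i, j);
  for (int j = 0; j < b.k; ++j) {
    b.inv2s2.push_back(1.0 / (2.0 * sig[j] * sig[j]));
    b.invs2.push_back(1.0 / (sig[j] * sig[j]));
    b.period.push_back(per[j]);
  }
  b.pref = as<double>(li["pref"]);
  b.eps = as<double>(li["eps"]);
  double M = as<double>(li["M"]);
  b.invM = (M > 0.0) ? 1.0 / M : 0.0;
  b.active = (b.pref > 0.0) && (b.K > 0) && (M > 0.0);
  return b;
}

}  // namespace

// [[Rcpp::export]]
List engine_run_segment(NumericVector x0, int nsteps, double dt, double kT,
                        double friction, int pot_id, NumericVector pot_par,
                        NumericVector wall, List expl, SEXP mt_spec,
                        int record_stride, int record_phase,
                        NumericVector noise_prev) {
  int d = x0.size();
  if (d > 16) stop("compiled engine supports at most 16 coordinates");
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> force(d), xi(d), xi_prev(noise_prev.begin(), noise_prev.end());
  if ((int)xi_prev.size() != d) stop("noise_prev length mismatch");

  Walls w;
  w.has = wall.size() >= 8;
  if (w.has) {
    w.Rcyl = wall[0]; w.tana = wall[1]; w.zcc = wall[2]; w.kwall = wall[3];
    w.dual = wall[4] > 0.5; w.zlo = wall[5]; w.zhi = wall[6]; w.kz = wall[7];
  }

  std::vector<ExploreBias> biases;
  for (int i = 0; i < expl.size(); ++i) biases.push_back(make_explore(expl[i]));

  MultiThermal mt;
  mt.active = false;
  bool mt_present = !Rf_isNull(mt_spec);
  if (mt_present) {
    List m(mt_spec);
    NumericVector db = m["dbeta"], cl = m["clam"];
    if (db.size() > 64) stop("at most 64 MultiThermal rungs");
    mt.dbeta.assign(db.begin(), db.end());
    mt.clam.assign(cl.begin(), cl.end());
    mt.kT0 = as<double>(m["kT0"]);
    mt.active = as<bool>(m["active"]);
  }

  int nb = (int)biases.size();
  int ncol = d + 2 + nb + (mt_present ? 1 : 0);  // coords, U, Vtot, per-bias V
  int nrec_max = nsteps / std::max(record_stride, 1) + 2;
  NumericMatrix rec(nrec_max, ncol);
  IntegerVector rec_step(nrec_max);
  int nrec = 0;

  double sq = std::sqrt(2.0 * kT * dt / friction) * 0.5;  // BAOAB-limit half-noise
  double invg = dt / friction;

  RNGScope scope;
  for (int step = 0; step < nsteps; ++step) {
    double U = potential(pot_id, pot_par, w, x.data(), d, force.data());
    double Vtot = 0.0;
    double Vb[32];
    for (int ib = 0; ib < nb; ++ib) {
      Vb[ib] = explore_bias_force(biases[ib], x.data(), force.data());
      Vtot += Vb[ib];
    }
    double Vmt = 0.0;
    if (mt.active) {
      double dVdU;
      Vmt = mt_bias(mt, U, &dVdU);
      Vtot += Vmt;
      // force contribution: -dV/dx = -dVdU * dU/dx = +dVdU * F_pot; F_pot is
      // the base force already in `force` minus bias terms, so recompute cheaply
      // by scaling the base potential force only.
      double fpot[16];
      potential(pot_id, pot_par, w, x.data(), d, fpot);
      // -dV/dx = -V'(U) dU/dx = +V'(U) F_pot
      for (int j = 0; j < d; ++j) force[j] += dVdU * fpot[j];
    }
    if ((record_phase + step) % record_stride == 0) {
      for (int j = 0; j < d; ++j) rec(nrec, j) = x[j];
      rec(nrec, d) = U;
      rec(nrec, d + 1) = Vtot;
      for (int ib = 0; ib < nb; ++ib) rec(nrec, d + 2 + ib) = Vb[ib];
      if (mt_present) rec(nrec, d + 2 + nb) = Vmt;
      rec_step[nrec] = step;
      ++nrec;
    }
    for (int j = 0; j < d; ++j) {
      if (!std::isfinite(force[j]))
        stop("non-finite force on coordinate %d at segment step %d", j + 1, step + 1);
      xi[j] = norm_rand();
      x[j] += invg * force[j] + sq * (xi[j] + xi_prev[j]);
      xi_prev[j] = xi[j];
    }
  }

  return List::create(
      _["x"] = NumericVector(x.begin(), x.end()),
      _["noise_prev"] = NumericVector(xi_prev.begin(), xi_prev.end()),
      _["records"] = rec, _["rec_step"] = rec_step, _["nrec"] = nrec);
}

// [[Rcpp::export]]
NumericVector engine_potential_energy(NumericMatrix X, int pot_id,
                                      NumericVector pot_par, NumericVector wall) {
  int n = X.nrow(), d = X.ncol();
  Walls w;
  w.has = wall.size() >= 8;
  if (w.has) {
    w.Rcyl = wall[0]; w.tana = wall[1]; w.zcc = wall[2]; w.kwall = wall[3];
    w.dual = wall[4] > 0.5; w.zlo = wall[5]; w.zhi = wall[6]; w.kz = wall[7];
  }
  NumericVector out(n);
  std::vector<double> xr(d), f(d);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < d; ++j) xr[j] = X(i, j);
    out[i] = potential(pot_id, pot_par, w, xr.data(), d, f.data());
  }
  return out;
}

// Kernel-density sum over deposited kernels at arbitrary CV points (used by
// the R-level bias evaluation; keeps run-time and analysis numerics identical).
// [[Rcpp::export]]
NumericVector engine_kernel_sum(NumericMatrix S, NumericMatrix centers,
                                NumericVector weights, NumericVector sigma,
                                NumericVector period) {
  int n = S.nrow(), k = S.ncol(), K = centers.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int q = 0; q < K; ++q) {
      double e = 0.0;
      for (int j = 0; j < k; ++j) {
        double dd = S(i, j) - centers(q, j);
        dd = wrap_diff(dd, period[j]);
        e += dd * dd / (2.0 * sigma[j] * sigma[j]);
      }
      if (e < 30.0) acc += weights[q] * std::exp(-e);
    }
    out[i] = acc;
  }
  return out;
}
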