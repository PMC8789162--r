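// Core numerics: gas-exchange ODE right-hand side, forward sensitivity
// equations, adaptive Dormand-Prince 5(4) integration with hard restarts at
// control switch times, and a fast Fisher-information determinant evaluator
// used inside design optimization loops.  The R level re-implements the
// Fisher assembly independently for transparency; tests assert both agree.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct JarPars {
  double Vj;     // jar volume, m^3
  double mp;     // pear mass, kg
  double T;      // temperature, K
  double Patm;   // atmospheric pressure, kPa
  double Rgas;   // universal gas constant, J mol^-1 K^-1
  bool   flow;   // true: flow-through jar; false: closed jar
  double kr;     // (kPa h^-1) per (umol kg^-1 s^-1) of areal rate, incl. mp/Vj
  double kq;     // outflow coefficient: m^3 h^-1 per (umol kg^-1 s^-1)
};

JarPars make_jar(const List& jar) {
  JarPars jp;
  jp.Vj   = as<double>(jar["Vj"]);
  jp.mp   = as<double>(jar["mp"]);
  jp.T    = as<double>(jar["T"]);
  jp.Patm = as<double>(jar["Patm"]);
  jp.Rgas = as<double>(jar["Rgas"]);
  jp.flow = as<std::string>(jar["mode"]) == "flow_through";
  // rates are in umol kg^-1 s^-1; mp * r * 3.6e-3 converts to mol h^-1
  const double molh = jp.mp * 3.6e-3;
  jp.kr = molh * jp.Rgas * jp.T / (1000.0 * jp.Vj);   // -> kPa h^-1
  jp.kq = molh * jp.Rgas * jp.T / (1000.0 * jp.Patm); // -> m^3 h^-1
  return jp;
}

// Michaelis-Menten respiration with noncompetitive CO2 inhibition plus
// O2-inhibited fermentation.  theta = (Vm_O2, Km_O2, inv_Kmn_CO2, rq,
// Vmf_CO2, Kmf_O2); the CO2 inhibition constant enters through its inverse.
struct Rates {
  double rO2, rCO2;
  double dra, drb;          // d rO2 / d pO2, d pCO2
  double dca, dcb;          // d rCO2 / d pO2, d pCO2
  double dro[6], drc[6];    // parameter partials
};

void eval_rates(double a, double b, const double* th, Rates& r, bool with_jac) {
  if (a < 0.0) a = 0.0;   // guard against tiny negative solver excursions
  if (b < 0.0) b = 0.0;
  const double Vm = th[0], Km = th[1], ik = th[2], rq = th[3],
               Vf = th[4], Kf = th[5];
  const double den1 = Km + a;
  const double den2 = 1.0 + b * ik;
  const double p1 = a / (den1 * den2);      // rO2 / Vm
  r.rO2 = Vm * p1;
  const double denf = Kf + a;
  const double g = Vf * Kf / denf;          // fermentative CO2 production
  r.rCO2 = rq * r.rO2 + g;
  if (!with_jac) return;
  r.dra = Vm * Km / (den1 * den1 * den2);
  r.drb = -r.rO2 * ik / den2;
  const double dga = -Vf * Kf / (denf * denf);
  r.dca = rq * r.dra + dga;
  r.dcb = rq * r.drb;
  r.dro[0] = p1;
  r.dro[1] = -r.rO2 / den1;
  r.dro[2] = -r.rO2 * b / den2;
  r.dro[3] = 0.0; r.dro[4] = 0.0; r.dro[5] = 0.0;
  r.drc[0] = rq * r.dro[0];
  r.drc[1] = rq * r.dro[1];
  r.drc[2] = rq * r.dro[2];
  r.drc[3] = r.rO2;
  r.drc[4] = Kf / denf;
  r.drc[5] = Vf * a / (denf * denf);
}

// Augmented RHS: y = (pO2, pCO2, S) with S the 2x6 sensitivity matrix stored
// column-major (dpO2/dth_m, dpCO2/dth_m) for m = 1..6.  dim = 2 or 14.
void rhs(double /*t*/, const double* y, double* dy, const double* th,
         const JarPars& jp, double Qin, double ain, double bin, int dim) {
  const bool with_sens = dim > 2;
  Rates r;
  eval_rates(y[0], y[1], th, r, with_sens);

  double Qout = 0.0, J00, J01, J10, J11;
  if (jp.flow) {
    Qout = Qin + jp.kq * (r.rCO2 - r.rO2);
    dy[0] = (Qin * ain - Qout * y[0]) / jp.Vj - jp.kr * r.rO2;
    dy[1] = (Qin * bin - Qout * y[1]) / jp.Vj + jp.kr * r.rCO2;
  } else {
    dy[0] = -jp.kr * r.rO2;
    dy[1] =  jp.kr * r.rCO2;
  }
  if (!with_sens) return;

  if (jp.flow) {
    const double dQa = jp.kq * (r.dca - r.dra);
    const double dQb = jp.kq * (r.dcb - r.drb);
    J00 = (-Qout - dQa * y[0]) / jp.Vj - jp.kr * r.dra;
    J01 = (-dQb * y[0]) / jp.Vj - jp.kr * r.drb;
    J10 = (-dQa * y[1]) / jp.Vj + jp.kr * r.dca;
    J11 = (-Qout - dQb * y[1]) / jp.Vj + jp.kr * r.dcb;
  } else {
    J00 = -jp.kr * r.dra; J01 = -jp.kr * r.drb;
    J10 =  jp.kr * r.dca; J11 =  jp.kr * r.dcb;
  }
  for (int m = 0; m < 6; ++m) {
    const double s0 = y[2 + 2 * m], s1 = y[3 + 2 * m];
    double f0, f1;
    if (jp.flow) {
      const double dQ = jp.kq * (r.drc[m] - r.dro[m]);
      f0 = -dQ * y[0] / jp.Vj - jp.kr * r.dro[m];
      f1 = -dQ * y[1] / jp.Vj + jp.kr * r.drc[m];
    } else {
      f0 = -jp.kr * r.dro[m];
      f1 =  jp.kr * r.drc[m];
    }
    dy[2 + 2 * m] = J00 * s0 + J01 * s1 + f0;
    dy[3 + 2 * m] = J10 * s0 + J11 * s1 + f1;
  }
}

// Dormand-Prince 5(4) coefficients.
const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
const double a21 = 1.0 / 5;
const double a31 = 3.0 / 40, a32 = 9.0 / 40;
const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
             a53 = 64448.0 / 6561, a54 = -212.0 / 729;
const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
             a64 = 49.0 / 176, a65 = -5103.0 / 18656;
const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
             b5 = -2187.0 / 6784, b6 = 11.0 / 84;
const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
             e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

struct Integrator {
  const double* th;
  JarPars jp;
  double rtol, atol;
  int dim;
  double k1[14], k2[14], k3[14], k4[14], k5[14], k6[14], k7[14], ytmp[14];

  // Integrate y from t0 to t1 under constant controls (FSAL not exploited for
  // simplicity; step sizes here are dominated by the output grid anyway).
  void segment(double& t, double t1, double* y,
               double Qin, double ain, double bin, double& h) {
    const int n = dim;
    int rejected_in_a_row = 0;
    while (t < t1 - 1e-12) {
      if (h <= 0.0 || !std::isfinite(h)) h = (t1 - t) / 8.0;
      if (h > t1 - t) h = t1 - t;
      rhs(t, y, k1, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * a21 * k1[i];
      rhs(t + c2 * h, ytmp, k2, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      rhs(t + c3 * h, ytmp, k3, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      rhs(t + c4 * h, ytmp, k4, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                              a54 * k4[i]);
      rhs(t + c5 * h, ytmp, k5, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                              a64 * k4[i] + a65 * k5[i]);
      rhs(t + h, ytmp, k6, th, jp, Qin, ain, bin, n);
      for (int i = 0; i < n; ++i)
        ytmp[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                              b5 * k5[i] + b6 * k6[i]);
      rhs(t + h, ytmp, k7, th, jp, Qin, ain, bin, n);
      double err = 0.0;
      for (int i = 0; i < n; ++i) {
        const double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                               e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(y[i]),
                                                 std::fabs(ytmp[i]));
        const double q = ei / sc;
        err += q * q;
      }
      err = std::sqrt(err / n);
      if (!std::isfinite(err)) stop("integrator failure near t = %f h", t);
      if (err <= 1.0) {
        t += h;
        for (int i = 0; i < n; ++i) y[i] = ytmp[i];
        rejected_in_a_row = 0;
        const double fac = std::min(5.0, std::max(0.2,
            0.9 * std::pow(std::max(err, 1e-10), -0.2)));
        h *= fac;
      } else {
        h *= std::max(0.2, 0.9 * std::pow(err, -0.2));
        if (++rejected_in_a_row > 50)
          stop("integrator failure (repeated step rejection) near t = %f h", t);
      }
      if (h < 1e-12) stop("integrator failure (step underflow) near t = %f h", t);
    }
    t = t1;
  }
};

// Shared driver: fills states (N x 2) and, when with_sens, sens (N x 12).
void integrate_all(const double* th, const JarPars& jp,
                   const arma::mat& u, double te, const arma::vec& tk,
                   const double* x0, bool with_sens,
                   double rtol, double atol,
                   arma::mat& states, arma::mat& sens) {
  const int M = u.n_rows;
  const int N = tk.n_elem;
  const int dim = with_sens ? 14 : 2;
  Integrator itg;
  itg.th = th; itg.jp = jp; itg.rtol = rtol; itg.atol = atol; itg.dim = dim;
  double y[14];
  y[0] = x0[0]; y[1] = x0[1];
  for (int i = 2; i < 14; ++i) y[i] = 0.0;   // sensitivities start at zero

  // stop points: every measurement time and every control switch
  double t = 0.0;
  int k = 0;                 // next output index
  double h = te / std::max(M * 4, 32);       // initial step guess
  for (int j = 0; j < M; ++j) {
    const double seg_end = (j + 1) * te / M;
    const double Qin = u(j, 0), ain = u(j, 1), bin = u(j, 2);
    h = std::min(h, seg_end - t);            // restart cleanly at switches
    while (k < N && tk(k) <= seg_end + 1e-12) {
      itg.segment(t, std::min(tk(k), seg_end), y, Qin, ain, bin, h);
      states(k, 0) = y[0]; states(k, 1) = y[1];
      if (with_sens) for (int i = 0; i < 12; ++i) sens(k, i) = y[2 + i];
      ++k;
    }
    if (t < seg_end - 1e-12) itg.segment(t, seg_end, y, Qin, ain, bin, h);
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
List cpp_simulate(NumericVector theta, List jar, NumericMatrix u,
                  double te, NumericVector tk, bool with_sens,
                  double rtol, double atol) {
  if (theta.size() != 6) stop("theta must have length 6");
  JarPars jp = make_jar(jar);
  NumericVector x0 = jar["x0"];
  arma::mat um(u.begin(), u.nrow(), u.ncol());
  arma::vec tkv(tk.begin(), tk.size());
  arma::mat states(tk.size(), 2), sens;
  if (with_sens) sens.set_size(tk.size(), 12);
  integrate_all(theta.begin(), jp, um, te, tkv, x0.begin(), with_sens,
                rtol, atol, states, sens);
  if (with_sens)
    return List::create(_["states"] = states, _["sens"] = sens);
  return List::create(_["states"] = states);
}

// Determinant of the Fisher information matrix for each parameter draw.
// Theta: R x 6 (inverse-Kmn parameterization); sig2: R x 2 noise scales.
// Weights fold in both the mean-sensitivity and the variance-sensitivity
// contribution of a heteroscedastic diagonal Gaussian noise model
// v_i = sig2_i * y_i + floor.
// [[Rcpp::export(name = ".cpp_det_fim")]]
NumericVector cpp_det_fim(NumericMatrix Theta, NumericMatrix sig2, List jar,
                          NumericMatrix u, double te, NumericVector tk,
                          double floor_var, double rtol, double atol) {
  const int R = Theta.nrow();
  if (Theta.ncol() != 6) stop("Theta must have 6 columns");
  if (floor_var <= 0) stop("variance floor must be > 0");
  JarPars jp = make_jar(jar);
  NumericVector x0 = jar["x0"];
  arma::mat um(u.begin(), u.nrow(), u.ncol());
  arma::vec tkv(tk.begin(), tk.size());
  const int N = tk.size();
  arma::mat states(N, 2), sens(N, 12);
  NumericVector out(R);
  for (int r = 0; r < R; ++r) {
    double th[6];
    for (int m = 0; m < 6; ++m) th[m] = Theta(r, m);
    integrate_all(th, jp, um, te, tkv, x0.begin(), true, rtol, atol,
                  states, sens);
    arma::mat F(6, 6, arma::fill::zeros);
    for (int i = 0; i < 2; ++i) {
      const double s2 = sig2(r, i);
      for (int k = 0; k < N; ++k) {
        const double yv = std::max(states(k, i), 0.0);
        const double v = s2 * yv + floor_var;
        const double w = 1.0 / v + 0.5 * s2 * s2 / (v * v);
        for (int m = 0; m < 6; ++m) {
          const double sm = sens(k, i + 2 * m);
          for (int n = m; n < 6; ++n)
            F(m, n) += w * sm * sens(k, i + 2 * n);
        }
      }
    }
    F = arma::symmatu(F);
    out[r] = arma::det(F);
  }
  return out;
}

// Gaussian log-likelihood of a measurement set under the jar model.
// [[Rcpp::export(name = ".cpp_loglik")]]
double cpp_loglik(NumericVector theta, NumericVector sig2, List jar,
                  NumericMatrix u, double te, NumericVector tk,
                  NumericMatrix y, double floor_var, double rtol, double atol) {
  JarPars jp = make_jar(jar);
  NumericVector x0 = jar["x0"];
  arma::mat um(u.begin(), u.nrow(), u.ncol());
  arma::vec tkv(tk.begin(), tk.size());
  const int N = tk.size();
  arma::mat states(N, 2), sens;
  integrate_all(theta.begin(), jp, um, te, tkv, x0.begin(), false,
                rtol, atol, states, sens);
  double ll = 0.0;
  const double l2pi = std::log(2.0 * M_PI);
  for (int i = 0; i < 2; ++i) {
    const double s2 = sig2[i];
    for (int k = 0; k < N; ++k) {
      const double mu = states(k, i);
      const double v = s2 * std::max(mu, 0.0) + floor_var;
      const double res = y(k, i) - mu;
      ll += -0.5 * (l2pi + std::log(v) + res * res / v);
    }
  }
  return ll;
}
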