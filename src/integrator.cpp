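#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sigmoidal transfer S(x) = 1/(1+exp(-a(x-theta))) - 1/(1+exp(a*theta)).
// The subtracted constant makes S(0) = 0 so that the origin is a fixed
// point of the uncoupled, unstimulated system.
static inline double sigm(double x, double a, double theta, double offset) {
  return 1.0 / (1.0 + std::exp(-a * (x - theta))) - offset;
}

// Fixed-step Euler integration of N delay-coupled Wilson-Cowan units:
//   tau dE_j/dt = -E_j + (Se_max - E_j) Se(c1 E_j - c2 I_j
//                   + c5 sum_k A_jk E_k(t - tau_djk) + P_j(t)) + sigma w_j
//   tau dI_j/dt = -I_j + (Si_max - I_j) Si(c3 E_j - c4 I_j) + sigma v_j
//
// Delays are pre-quantized to integer step counts (dsteps); the stored E
// trajectory doubles as the delay history buffer, with times before t = 0
// reading the initial condition. Noise w, v is standard normal, drawn per
// step through R's RNG so seeding happens on the R side; by default it
// enters the right-hand side un-scaled (multiplied by dt/tau like every
// other term). noise_sqrt_dt = true instead scales by sqrt(dt*tau)/dt...
// more precisely uses sigma*sqrt(dt)/dt inside the Euler update, i.e. an
// Euler-Maruyama interpretation with Wiener increments.
//
// Stimulation: P_j(t) = p_base[j] (+ stim_amp for j == stim_target while
// onset_step <= t < offset_step).
//
// [[Rcpp::export]]
List wc_integrate_cpp(NumericMatrix A, IntegerMatrix dsteps,
                      List params, NumericVector p_base,
                      int stim_target, double stim_amp,
                      int onset_step, int offset_step,
                      int n_steps, double dt,
                      double e0, double i0,
                      bool noise_sqrt_dt) {
  const int N = A.nrow();
  const double tau = params["tau"];
  const double c1 = params["c1"], c2 = params["c2"], c3 = params["c3"],
               c4 = params["c4"], c5 = params["c5"];
  const double ae = params["a_e"], ai = params["a_i"];
  const double the = params["theta_e"], thi = params["theta_i"];
  const double semax = params["s_e_max"], simax = params["s_i_max"];
  const double sigma = params["sigma"];
  const double off_e = 1.0 / (1.0 + std::exp(ae * the));
  const double off_i = 1.0 / (1.0 + std::exp(ai * thi));
  const double h = dt / tau;
  const double noise_fac = noise_sqrt_dt ? std::sqrt(dt) / dt : 1.0;

  // adjacency in compressed per-row form, zero weights dropped
  std::vector<std::vector<int> > nbr(N);
  std::vector<std::vector<double> > wgt(N);
  std::vector<std::vector<int> > del(N);
  for (int j = 0; j < N; ++j) {
    for (int k = 0; k < N; ++k) {
      if (A(j, k) != 0.0) {
        nbr[j].push_back(k);
        wgt[j].push_back(A(j, k));
        del[j].push_back(dsteps(j, k));
      }
    }
  }

  NumericMatrix E(N, n_steps + 1), I(N, n_steps + 1);
  for (int j = 0; j < N; ++j) { E(j, 0) = e0; I(j, 0) = i0; }

  NumericVector w(N), v(N);
  for (int t = 0; t < n_steps; ++t) {
    if (sigma > 0.0) { w = rnorm(N); v = rnorm(N); }
    bool stim_on = (stim_target >= 0 && t >= onset_step && t < offset_step);
    for (int j = 0; j < N; ++j) {
      double coup = 0.0;
      const std::vector<int> &nb = nbr[j];
      const std::vector<double> &wt = wgt[j];
      const std::vector<int> &dl = del[j];
      for (size_t m = 0; m < nb.size(); ++m) {
        int ts = t - dl[m];
        coup += wt[m] * (ts >= 0 ? E(nb[m], ts) : e0);
      }
      double P = p_base[j] + ((stim_on && j == stim_target) ? stim_amp : 0.0);
      double xe = c1 * E(j, t) - c2 * I(j, t) + c5 * coup + P;
      double xi = c3 * E(j, t) - c4 * I(j, t);
      double dE = -E(j, t) + (semax - E(j, t)) * sigm(xe, ae, the, off_e);
      double dI = -I(j, t) + (simax - I(j, t)) * sigm(xi, ai, thi, off_i);
      if (sigma > 0.0) {
        dE += sigma * w[j] * noise_fac;
        dI += sigma * v[j] * noise_fac;
      }
      E(j, t + 1) = E(j, t) + h * dE;
      I(j, t + 1) = I(j, t) + h * dI;
      if (!R_finite(E(j, t + 1)) || !R_finite(I(j, t + 1))) {
        stop("non-finite state at step %d (region %d); reduce dt or check parameters",
             t + 1, j + 1);
      }
    }
  }
  return List::create(_["E"] = E, _["I"] = I);
}
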