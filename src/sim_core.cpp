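#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (see param_vector() on the R side):
// 0 r, 1 N, 2 mu_a, 3 alpha, 4 lambda_in, 5 d_in, 6 lambda_r, 7 d_r,
// 8 p, 9 delta, 10 sigma, 11 d_i, 12 d_a, 13 rho1, 14 rho2,
// 15 b1, 16 d1, 17 b2, 18 d2

// the 12 transition rates of the Markov chain; q1 is clamped at zero where
// the logistic birth term b1*n1 + b2*n1^2 would go negative (n1 > b1*N/r)
static inline void rates12(const double *n, const double *p, double *q) {
  double q1 = p[15] * n[0] + p[17] * n[0] * n[0];
  q[0] = q1 > 0.0 ? q1 : 0.0;
  q[1] = p[16] * n[0] + p[18] * n[0] * n[0] + p[2] * n[0] * n[3];
  q[2] = p[4];
  q[3] = p[5] * n[1];
  q[4] = p[3] * p[8] * n[0] * n[1];
  q[5] = p[3] * (1.0 - p[8]) * n[0] * n[1];
  q[6] = p[6] + p[13] * n[2] * n[4];
  q[7] = p[7] * n[2];
  q[8] = p[14] * n[3] * n[4];
  q[9] = (p[12] + p[9] * n[2]) * n[3];
  q[10] = p[10] * n[3];
  q[11] = p[11] * n[4];
}

// stoichiometry of the 12 channels (state change per event)
static const int STOICH[12][5] = {
  {+1, 0, 0, 0, 0}, {-1, 0, 0, 0, 0},
  { 0,+1, 0, 0, 0}, { 0,-1, 0, 0, 0},
  { 0,-1,+1, 0, 0}, { 0,-1, 0,+1, 0},
  { 0, 0,+1, 0, 0}, { 0, 0,-1, 0, 0},
  { 0, 0, 0,+1, 0}, { 0, 0, 0,-1, 0},
  { 0, 0, 0, 0,+1}, { 0, 0, 0, 0,-1}
};

// [[Rcpp::export(name = ".rates12_cpp")]]
NumericVector rates12_cpp(NumericVector state, NumericVector pars) {
  NumericVector q(12);
  rates12(REAL(state), REAL(pars), REAL(q));
  return q;
}

// Gillespie direct method.  Records every event (time + state) up to
// max_events; status 0 = reached t_max, 1 = frozen (zero total rate),
// 2 = truncated at max_events.
// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(NumericVector pars, IntegerVector init, double t_max,
              int max_events) {
  double n[5];
  for (int i = 0; i < 5; ++i) n[i] = init[i];
  double q[12];
  std::vector<double> times;
  std::vector<double> states;
  times.reserve(1024);
  states.reserve(5 * 1024);
  double t = 0.0;
  times.push_back(t);
  for (int i = 0; i < 5; ++i) states.push_back(n[i]);
  int status = 0;
  long nev = 0;
  RNGScope scope;
  while (t < t_max) {
    rates12(n, REAL(pars), q);
    double qtot = 0.0;
    for (int k = 0; k < 12; ++k) qtot += q[k];
    if (qtot <= 0.0) { status = 1; break; }
    t += exp_rand() / qtot;
    if (t >= t_max) break;
    double u = unif_rand() * qtot, acc = 0.0;
    int ch = 11;
    for (int k = 0; k < 12; ++k) {
      acc += q[k];
      if (u <= acc) { ch = k; break; }
    }
    for (int i = 0; i < 5; ++i) n[i] += STOICH[ch][i];
    ++nev;
    times.push_back(t);
    for (int i = 0; i < 5; ++i) states.push_back(n[i]);
    if (nev >= max_events) { status = 2; break; }
  }
  // close the path at t_max (state unchanged since last event)
  if (status != 2) {
    times.push_back(t_max);
    for (int i = 0; i < 5; ++i) states.push_back(n[i]);
  }
  int m = (int) times.size();
  NumericVector tv(times.begin(), times.end());
  NumericMatrix sm(m, 5);
  for (int r = 0; r < m; ++r)
    for (int c = 0; c < 5; ++c) sm(r, c) = states[5 * r + c];
  return List::create(_["times"] = tv, _["states"] = sm,
                      _["n_events"] = (double) nev,
                      _["status"] = status);
}

// Euler-Maruyama integration of the Ito SDE with the 7-channel
// block-diagonal diffusion factor.  States are clamped at zero after each
// step; the number of clamped components is counted.  Records the state
// every record_every steps (plus the initial state).
// [[Rcpp::export(name = ".em_core")]]
List em_core(NumericVector pars, NumericVector init, double dt,
             int n_steps, int record_every, double noise_scale) {
  double y[5];
  for (int i = 0; i < 5; ++i) y[i] = init[i];
  double q[12];
  int n_rec = n_steps / record_every + 1;
  NumericMatrix out(n_rec, 5);
  for (int i = 0; i < 5; ++i) out(0, i) = y[i];
  double sdt = std::sqrt(dt) * noise_scale;
  long clamped = 0;
  int row = 1;
  RNGScope scope;
  for (int s = 1; s <= n_steps; ++s) {
    rates12(y, REAL(pars), q);
    double x1 = norm_rand(), x2 = norm_rand(), x3 = norm_rand(),
           x4 = norm_rand(), x5 = norm_rand(), x6 = norm_rand(),
           x7 = norm_rand();
    // drift = stoichiometry-weighted rate sums (identical to the ODE
    // right-hand side wherever the logistic birth rate is unclamped)
    double mu0 = q[0] - q[1];
    double mu1 = q[2] - q[3] - q[4] - q[5];
    double mu2 = q[4] + q[6] - q[7];
    double mu3 = q[5] + q[8] - q[9];
    double mu4 = q[10] - q[11];
    double r5 = std::sqrt(q[4]), r6 = std::sqrt(q[5]);
    y[0] += mu0 * dt + sdt * std::sqrt(q[0] + q[1]) * x1;
    y[1] += mu1 * dt + sdt * (std::sqrt(q[2] + q[3]) * x2 - r5 * x3 - r6 * x4);
    y[2] += mu2 * dt + sdt * (r5 * x3 + std::sqrt(q[6] + q[7]) * x5);
    y[3] += mu3 * dt + sdt * (r6 * x4 + std::sqrt(q[8] + q[9]) * x6);
    y[4] += mu4 * dt + sdt * std::sqrt(q[10] + q[11]) * x7;
    for (int i = 0; i < 5; ++i)
      if (y[i] < 0.0) { y[i] = 0.0; ++clamped; }
    if (s % record_every == 0 && row < n_rec) {
      for (int i = 0; i < 5; ++i) out(row, i) = y[i];
      ++row;
    }
  }
  return List::create(_["states"] = out, _["clamped"] = (double) clamped,
                      _["n_steps"] = (double) n_steps);
}
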