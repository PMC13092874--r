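#include <Rcpp.h>
using namespace Rcpp;

// Single-accumulator first-passage density/CDF at decision time t (> 0),
// threshold b, uniform start on [0, A], slope ~ N(v, s).
static inline double fpt_pdf(double t, double b, double A, double v, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double out = (-v * R::pnorm(z1, 0, 1, 1, 0) + s * R::dnorm(z1, 0, 1, 0) +
                 v * R::pnorm(z2, 0, 1, 1, 0) - s * R::dnorm(z2, 0, 1, 0)) / A;
  return out > 0.0 ? out : 0.0;
}

static inline double fpt_cdf(double t, double b, double A, double v, double s) {
  if (t <= 0.0) return 0.0;
  double ts = t * s;
  double z1 = (b - A - t * v) / ts;
  double z2 = (b - t * v) / ts;
  double out = 1.0 + (b - A - t * v) / A * R::pnorm(z1, 0, 1, 1, 0)
                   - (b - t * v) / A * R::pnorm(z2, 0, 1, 1, 0)
                   + ts / A * (R::dnorm(z1, 0, 1, 0) - R::dnorm(z2, 0, 1, 0));
  if (out < 0.0) out = 0.0;
  if (out > 1.0) out = 1.0;
  return out;
}

// Pointwise log-likelihood of one subject's trials under the RLWM-LBA model,
// replaying the agent forward (policy -> prior entropy -> drifts -> race
// density -> value update -> WM decay). Blocks are replayed independently;
// Q values reset to 1/3 at each block boundary.
//
// theta (constrained scale): alpha_rl, bias, phi, rho, capacity,
//                            A, k, tau, eta, beta_slope
// block: 1-based block id, non-decreasing; stim: 1-based index within block;
// action/reward/rt observed; set_size: block set size per trial;
// slope_z: standardized CPP slope per trial (all zero for the baseline model).
// [[Rcpp::export]]
NumericVector rlwm_lba_loglik_cpp(NumericVector theta,
                                  IntegerVector block, IntegerVector stim,
                                  IntegerVector action, IntegerVector reward,
                                  NumericVector rt, IntegerVector set_size,
                                  NumericVector slope_z,
                                  double beta_rl, double beta_wm,
                                  double s, double eps_h, double eta_min) {
  const int n = block.size();
  const double alpha = theta[0], bias = theta[1], phi = theta[2],
    rho = theta[3], cap = theta[4], A = theta[5], k = theta[6],
    tau = theta[7], eta = theta[8], beta_slope = theta[9];
  const double b = A + k;
  const double log_floor = std::log(1e-300);
  NumericVector out(n);

  double q_rl[5][3], q_wm[5][3];
  int cur_block = -1;
  int ns = 0;
  double w = 0.0;

  for (int i = 0; i < n; ++i) {
    if (block[i] != cur_block) {
      cur_block = block[i];
      ns = set_size[i];
      double c_over = cap / ns;
      w = rho * (c_over < 1.0 ? c_over : 1.0);
      for (int si = 0; si < ns; ++si)
        for (int a = 0; a < 3; ++a) {
          q_rl[si][a] = 1.0 / 3.0;
          q_wm[si][a] = 1.0 / 3.0;
        }
    }
    // mixed policies for all stimuli in the block; accumulate block average
    double mu[3] = {0.0, 0.0, 0.0};
    double pi_s[3] = {0.0, 0.0, 0.0};
    const int st = stim[i] - 1;
    for (int si = 0; si < ns; ++si) {
      double mrl = q_rl[si][0], mwm = q_wm[si][0];
      for (int a = 1; a < 3; ++a) {
        if (q_rl[si][a] > mrl) mrl = q_rl[si][a];
        if (q_wm[si][a] > mwm) mwm = q_wm[si][a];
      }
      double erl[3], ewm[3], srl = 0.0, swm = 0.0;
      for (int a = 0; a < 3; ++a) {
        erl[a] = std::exp(beta_rl * (q_rl[si][a] - mrl));
        ewm[a] = std::exp(beta_wm * (q_wm[si][a] - mwm));
        srl += erl[a]; swm += ewm[a];
      }
      for (int a = 0; a < 3; ++a) {
        double pi_a = w * ewm[a] / swm + (1.0 - w) * erl[a] / srl;
        mu[a] += pi_a / ns;
        if (si == st) pi_s[a] = pi_a;
      }
    }
    double H = 0.0;
    for (int a = 0; a < 3; ++a)
      if (mu[a] > 0.0) H -= mu[a] * std::log2(mu[a]);
    if (H < eps_h) H = eps_h;

    double eta_t = eta + slope_z[i] * beta_slope;
    if (eta_t < eta_min) eta_t = eta_min;

    double v[3];
    for (int a = 0; a < 3; ++a) v[a] = eta_t * pi_s[a] / H;

    // defective density of the observed (choice, rt), truncated to the
    // at-least-one-positive-slope event
    const int ch = action[i] - 1;
    double td = rt[i] - tau;
    double ll;
    if (td <= 0.0) {
      ll = log_floor;
    } else {
      double dens = fpt_pdf(td, b, A, v[ch], s);
      for (int a = 0; a < 3; ++a)
        if (a != ch) dens *= 1.0 - fpt_cdf(td, b, A, v[a], s);
      double p_none = 1.0;
      for (int a = 0; a < 3; ++a) p_none *= R::pnorm(-v[a] / s, 0, 1, 1, 0);
      dens /= (1.0 - p_none);
      ll = dens > 1e-300 ? std::log(dens) : log_floor;
    }
    out[i] = ll;

    // delta-rule updates with negative-feedback bias, then WM decay
    double r = reward[i];
    double pe_rl = r - q_rl[st][ch];
    q_rl[st][ch] += (pe_rl >= 0 ? alpha : (1.0 - bias) * alpha) * pe_rl;
    double pe_wm = r - q_wm[st][ch];
    q_wm[st][ch] += (pe_wm >= 0 ? 1.0 : (1.0 - bias)) * pe_wm;
    for (int si = 0; si < ns; ++si)
      for (int a = 0; a < 3; ++a)
        q_wm[si][a] += phi * (1.0 / 3.0 - q_wm[si][a]);
  }
  return out;
}
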