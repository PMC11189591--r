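#include <Rcpp.h>
using namespace Rcpp;

// Standardised first-passage density at the lower boundary for a Wiener
// process with unit diffusion, boundary separation 1, zero drift, relative
// start w, evaluated at normalised time tau = t / a^2. Series truncation
// follows the usual small-time / large-time accuracy criterion: the number
// of terms needed to bound the truncation error by `eps` is computed for
// both expansions and the cheaper one is used.
static double fpt_std_lower(double tau, double w, double eps) {
  if (tau <= 0.0) return 0.0;

  // terms needed by the small-time expansion
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * tau) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tau * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * tau)));
    ks = std::max(ks, std::sqrt(tau) + 1.0);
  } else {
    ks = 2.0;
  }
  // terms needed by the large-time expansion
  double kl;
  if (M_PI * tau * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tau * eps) / (M_PI * M_PI * tau));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tau)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tau));
  }

  double dens = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -((K - 1) / 2); k <= K / 2; ++k) {
      double z = w + 2.0 * k;
      dens += z * std::exp(-z * z / (2.0 * tau));
    }
    dens /= std::sqrt(2.0 * M_PI * tau * tau * tau);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      dens += k * std::exp(-k * k * M_PI * M_PI * tau / 2.0) *
              std::sin(k * M_PI * w);
    }
    dens *= M_PI;
  }
  return std::max(dens, 0.0);
}

// Density of the first-passage time at the LOWER boundary of a Wiener
// diffusion with drift v, boundary separation a, relative start point w
// (fraction of a measured from the lower boundary), unit diffusion
// coefficient. `t` is decision time (non-decision time already removed).
// [[Rcpp::export]]
NumericVector wfpt_lower_cpp(NumericVector t, double v, double a,
                             double w, double eps) {
  int n = t.size();
  NumericVector out(n);
  double a2 = a * a;
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (!R_finite(ti) || ti <= 0.0) { out[i] = 0.0; continue; }
    double tau = ti / a2;
    double mult = std::exp(-v * a * w - v * v * ti / 2.0) / a2;
    out[i] = mult * fpt_std_lower(tau, w, eps);
  }
  return out;
}

// Same density with per-element drift and boundary separation: t, v and a
// must have equal length. Used for vectorised likelihoods over trials and
// over parameter-grid cells.
// [[Rcpp::export]]
NumericVector wfpt_lower_vec_cpp(NumericVector t, NumericVector v,
                                 NumericVector a, double w, double eps) {
  int n = t.size();
  if (v.size() != n || a.size() != n)
    stop("t, v and a must have equal length");
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (!R_finite(ti) || ti <= 0.0) { out[i] = 0.0; continue; }
    double a2 = a[i] * a[i];
    double tau = ti / a2;
    double mult = std::exp(-v[i] * a[i] * w - v[i] * v[i] * ti / 2.0) / a2;
    out[i] = mult * fpt_std_lower(tau, w, eps);
  }
  return out;
}

// Euler-Maruyama simulation of the same diffusion: n independent paths with
// drift v, boundary separation a, relative start w, unit diffusion, time
// step dt. A Brownian-bridge correction detects within-step boundary
// crossings, removing the O(sqrt(dt)) late-absorption bias of the naive
// scheme. Returns decision times and which boundary was hit (+1 upper,
// -1 lower); paths still alive at max_t are flagged 0 for the caller to
// resample. Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
List ddm_sim_cpp(int n, double v, double a, double w, double dt,
                 double max_t) {
  NumericVector rt(n);
  IntegerVector boundary(n);
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil(max_t / dt);
  for (int i = 0; i < n; ++i) {
    double x = w * a;
    int hit = 0;
    int step = 0;
    while (step < max_steps) {
      double x_new = x + v * dt + sdt * norm_rand();
      ++step;
      if (x_new >= a) { hit = 1; x = x_new; break; }
      if (x_new <= 0.0) { hit = -1; x = x_new; break; }
      // probability that the bridge between x and x_new touched a boundary
      double p_up = std::exp(-2.0 * (a - x) * (a - x_new) / dt);
      double p_lo = std::exp(-2.0 * x * x_new / dt);
      double u = unif_rand();
      if (u < p_up) { hit = 1; x = x_new; break; }
      if (u < p_up + p_lo) { hit = -1; x = x_new; break; }
      x = x_new;
    }
    boundary[i] = hit;
    rt[i] = step * dt;
  }
  return List::create(_["rt"] = rt, _["boundary"] = boundary);
}

// Delta-rule trajectory of the observational learner over one session.
// cond: 0 = none, 1 = rt_only, 2 = choice_only, 3 = both. chose_left uses
// -1 for hidden choices. Returns the estimate before each trial and after
// the last (length n + 1). Mirrors the R-level outcome rules exactly.
// [[Rcpp::export]]
NumericVector rl_traj_cpp(NumericVector left, NumericVector right,
                          IntegerVector chose_left, NumericVector rt,
                          int cond, double alpha, double P0, double omega) {
  int n = left.size();
  NumericVector traj(n + 1);
  double P = P0;
  traj[0] = P;
  double rt_sum = 0.0;
  for (int t = 0; t < n; ++t) {
    double mid = (left[t] + right[t]) / 2.0;
    bool larger_is_left = left[t] > right[t];
    double o;
    if (cond == 0) {
      o = mid;
    } else if (cond == 2) {
      o = ((chose_left[t] == 1) == larger_is_left) ? 1.0 : 0.0;
    } else {
      rt_sum += rt[t];
      bool slow = rt[t] > rt_sum / (t + 1);
      double o_rt;
      if (slow) {
        o_rt = mid;
      } else {
        double dl = left[t] - P, dr = right[t] - P;
        bool closer_is_left = dl * dl <= dr * dr;
        o_rt = (closer_is_left == larger_is_left) ? 1.0 : 0.0;
      }
      if (cond == 1) {
        o = o_rt;
      } else {
        double o_ch = ((chose_left[t] == 1) == larger_is_left) ? 1.0 : 0.0;
        o = o_ch * (1.0 - omega) + o_rt * omega;
      }
    }
    P += alpha * (o - P);
    traj[t + 1] = P;
  }
  return traj;
}
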