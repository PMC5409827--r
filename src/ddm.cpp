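// First-passage-time machinery for the two-boundary drift-diffusion model.
//
// Conventions: decision variable y starts at z*a on [0, a]; dy = mu*dt + c*dW.
// Hitting a is a 'yes', hitting 0 a 'no'. All densities below are for unit
// noise after rescaling (a' = a/c, mu' = mu/c); t is decision time (rt - t0).

#include <Rcpp.h>
using namespace Rcpp;

// Series density (lower boundary, unit variance, boundary sep 1, normalized
// time tt = t/a^2, relative start w). Small-time vs large-time expansion
// chosen by the standard truncation-error bound.
static double ftt_01w(double tt, double w, double err) {
  double kl, ks, p;
  if (tt <= 0.0) return 0.0;
  if (M_PI * tt * err < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(tt));
  }
  if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * std::sqrt(2.0 * M_PI * tt) * err));
    ks = std::max(ks, std::sqrt(tt) + 1.0);
  } else {
    ks = 2.0;
  }
  p = 0.0;
  if (ks < kl) {                       // small-time expansion
    int K = (int)std::ceil(ks);
    for (int k = -(int)std::floor((K - 1) / 2.0); k <= (int)std::ceil((K - 1) / 2.0); k++) {
      double u = w + 2.0 * k;
      p += u * std::exp(-u * u / (2.0 * tt));
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {                             // large-time expansion
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; k++) {
      p += k * std::exp(-k * k * M_PI * M_PI * tt / 2.0) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  return p > 0.0 ? p : 0.0;
}

// Density of hitting the LOWER boundary at decision time t, drift mu,
// boundary separation a, relative start w, unit noise.
static double wfpt_lower(double t, double mu, double a, double w, double err) {
  if (t <= 0.0) return 0.0;
  double tt = t / (a * a);
  double p = ftt_01w(tt, w, err * a * a);
  return p * std::exp(-mu * a * w - mu * mu * t / 2.0) / (a * a);
}

// Boundary- and noise-aware density. choice: 1 = upper ('yes'), 0 = lower.
static double fpt_density_one(double t, double mu, double a, double z,
                              double c, int choice, double err) {
  double as = a / c, ms = mu / c;
  if (choice == 1) return wfpt_lower(t, -ms, as, 1.0 - z, err);
  return wfpt_lower(t, ms, as, z, err);
}

// [[Rcpp::export(name = ".fpt_density_cpp")]]
NumericVector fpt_density_cpp(NumericVector t, double mu, double a, double z,
                              double c, int choice,
                              NumericVector gh_nodes, NumericVector gh_weights,
                              double sv, double err) {
  int n = t.size();
  NumericVector out(n);
  if (sv <= 0.0) {
    for (int i = 0; i < n; i++)
      out[i] = fpt_density_one(t[i], mu, a, z, c, choice, err);
  } else {
    int m = gh_nodes.size();
    for (int i = 0; i < n; i++) {
      double acc = 0.0;
      for (int j = 0; j < m; j++) {
        double muj = mu + M_SQRT2 * sv * gh_nodes[j];
        acc += gh_weights[j] * fpt_density_one(t[i], muj, a, z, c, choice, err);
      }
      out[i] = acc / std::sqrt(M_PI);
    }
  }
  return out;
}

// Summed log-likelihood for a set of trials. mu is per-trial effective drift
// (v*stimulus + dc already composed in R); choice in {0,1}; rt in seconds.
// Densities floored at `floor_dens` so stray trials cannot yield -Inf.
// [[Rcpp::export(name = ".ddm_loglik_cpp")]]
double ddm_loglik_cpp(NumericVector rt, IntegerVector choice, NumericVector mu,
                      double a, double z, double t0, double c,
                      NumericVector gh_nodes, NumericVector gh_weights,
                      double sv, double err, double floor_dens) {
  int n = rt.size(), m = gh_nodes.size();
  double ll = 0.0;
  for (int i = 0; i < n; i++) {
    double t = rt[i] - t0;
    double dens;
    if (sv <= 0.0) {
      dens = fpt_density_one(t, mu[i], a, z, c, choice[i], err);
    } else {
      double acc = 0.0;
      for (int j = 0; j < m; j++) {
        double muj = mu[i] + M_SQRT2 * sv * gh_nodes[j];
        acc += gh_weights[j] * fpt_density_one(t, muj, a, z, c, choice[i], err);
      }
      dens = acc / std::sqrt(M_PI);
    }
    ll += std::log(std::max(dens, floor_dens));
  }
  return ll;
}

// Euler-Maruyama simulator with Brownian-bridge boundary-crossing
// correction: after each step that leaves the path inside the boundaries,
// the probability that the connecting Brownian bridge crossed a boundary
// within the step is evaluated and the trial absorbed accordingly. This
// removes the O(sqrt(dt)) late-detection bias of naive discrete crossing
// checks. Per-trial drift drawn N(mu_i, sv). Uses R's RNG so set.seed()
// governs the output. Returns rt = NA for trials not absorbed within t_max.
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
List ddm_simulate_cpp(int n, NumericVector mu, double a, double z, double t0,
                      double c, double sv, double dt, double t_max) {
  NumericVector rt(n);
  IntegerVector choice(n);
  double sdt = c * std::sqrt(dt);
  double c2dt = c * c * dt;
  int max_steps = (int)std::ceil(t_max / dt);
  RNGScope scope;
  for (int i = 0; i < n; i++) {
    double drift = mu[i];
    if (sv > 0.0) drift += sv * norm_rand();
    double y = z * a;
    int step = 0;
    int hit = -1;  // -1 none, 0 lower, 1 upper
    while (step < max_steps) {
      double y1 = y + drift * dt + sdt * norm_rand();
      step++;
      if (y1 <= 0.0) { hit = 0; break; }
      if (y1 >= a)   { hit = 1; break; }
      // bridge crossing probabilities (only evaluated when non-negligible)
      double elo = 2.0 * y * y1 / c2dt;
      if (elo < 30.0 && unif_rand() < std::exp(-elo)) { hit = 0; break; }
      double ehi = 2.0 * (a - y) * (a - y1) / c2dt;
      if (ehi < 30.0 && unif_rand() < std::exp(-ehi)) { hit = 1; break; }
      y = y1;
    }
    if (hit >= 0) {
      choice[i] = hit; rt[i] = step * dt + t0;
    } else {
      choice[i] = NA_INTEGER; rt[i] = NA_REAL;
    }
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
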