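// Gaussian-emission hidden Markov model core: scaled forward-backward
// Baum-Welch EM and Viterbi decoding. Hot loop of per-molecule trace
// idealization, hence compiled.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double gauss_pdf(double x, double mu, double sd) {
  const double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / (sd * 2.5066282746310002);
}

// [[Rcpp::export(name = ".hmm_em_cpp")]]
List hmm_em_cpp(NumericVector x, NumericVector means0, NumericVector sds0,
                NumericMatrix trans0, NumericVector init0,
                int max_iter, double tol, double sd_floor) {
  const int T = x.size();
  const int S = means0.size();
  NumericVector mu = clone(means0), sd = clone(sds0), pi0 = clone(init0);
  NumericMatrix A = clone(trans0);

  NumericMatrix alpha(T, S), beta(T, S), gamma(T, S), B(T, S);
  NumericVector cscale(T);
  NumericVector ll_trace(max_iter);
  NumericVector occ(S);
  double ll_prev = R_NegInf;
  int iter = 0;
  bool converged = false;

  for (iter = 0; iter < max_iter; ++iter) {
    // emission densities
    for (int t = 0; t < T; ++t)
      for (int s = 0; s < S; ++s)
        B(t, s) = gauss_pdf(x[t], mu[s], sd[s]) + 1e-300;

    // forward with scaling
    double c0 = 0.0;
    for (int s = 0; s < S; ++s) { alpha(0, s) = pi0[s] * B(0, s); c0 += alpha(0, s); }
    if (c0 <= 0) c0 = 1e-300;
    for (int s = 0; s < S; ++s) alpha(0, s) /= c0;
    cscale[0] = c0;
    for (int t = 1; t < T; ++t) {
      double ct = 0.0;
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r) acc += alpha(t - 1, r) * A(r, s);
        alpha(t, s) = acc * B(t, s);
        ct += alpha(t, s);
      }
      if (ct <= 0) ct = 1e-300;
      for (int s = 0; s < S; ++s) alpha(t, s) /= ct;
      cscale[t] = ct;
    }
    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(cscale[t]);
    ll_trace[iter] = ll;

    // backward (same scaling)
    for (int s = 0; s < S; ++s) beta(T - 1, s) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int r = 0; r < S; ++r) acc += A(s, r) * B(t + 1, r) * beta(t + 1, r);
        beta(t, s) = acc / cscale[t + 1];
      }
    }

    // gamma and accumulators
    for (int t = 0; t < T; ++t) {
      double norm = 0.0;
      for (int s = 0; s < S; ++s) { gamma(t, s) = alpha(t, s) * beta(t, s); norm += gamma(t, s); }
      if (norm <= 0) norm = 1e-300;
      for (int s = 0; s < S; ++s) gamma(t, s) /= norm;
    }

    NumericMatrix xi_sum(S, S);
    NumericVector gamma_sum(S);  // over t = 0..T-2, for transition rows
    for (int t = 0; t + 1 < T; ++t) {
      for (int s = 0; s < S; ++s) {
        gamma_sum[s] += gamma(t, s);
        for (int r = 0; r < S; ++r)
          xi_sum(s, r) += alpha(t, s) * A(s, r) * B(t + 1, r) * beta(t + 1, r) / cscale[t + 1];
      }
    }

    // M-step
    for (int s = 0; s < S; ++s) pi0[s] = gamma(0, s);
    for (int s = 0; s < S; ++s) {
      double row = 0.0;
      for (int r = 0; r < S; ++r) row += xi_sum(s, r);
      if (row > 0)
        for (int r = 0; r < S; ++r) A(s, r) = xi_sum(s, r) / row;
    }
    for (int s = 0; s < S; ++s) {
      double g = 0.0, gx = 0.0;
      for (int t = 0; t < T; ++t) { g += gamma(t, s); gx += gamma(t, s) * x[t]; }
      occ[s] = g;
      if (g > 1e-8) {
        mu[s] = gx / g;
        double gv = 0.0;
        for (int t = 0; t < T; ++t) {
          const double d = x[t] - mu[s];
          gv += gamma(t, s) * d * d;
        }
        sd[s] = std::sqrt(gv / g);
        if (sd[s] < sd_floor) sd[s] = sd_floor;
      }
    }

    if (iter > 0 && (ll - ll_prev) < tol * T && (ll - ll_prev) >= -1e-6 * std::abs(ll)) {
      converged = true;
      ++iter;
      break;
    }
    ll_prev = ll;
  }

  int used = (iter < max_iter) ? iter : max_iter;
  NumericVector llt(used);
  for (int i = 0; i < used; ++i) llt[i] = ll_trace[i];

  return List::create(_["means"] = mu, _["sds"] = sd, _["trans"] = A,
                      _["init"] = pi0, _["loglik_trace"] = llt,
                      _["loglik"] = llt[used - 1], _["n_iter"] = used,
                      _["converged"] = converged, _["occupancy"] = occ);
}

// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(NumericVector x, NumericVector means, NumericVector sds,
                     NumericMatrix trans, NumericVector init) {
  const int T = x.size();
  const int S = means.size();
  NumericMatrix delta(T, S);
  IntegerMatrix psi(T, S);
  const double NEG = -1e300;

  for (int s = 0; s < S; ++s) {
    double e = std::log(gauss_pdf(x[0], means[s], sds[s]) + 1e-300);
    delta(0, s) = (init[s] > 0 ? std::log(init[s]) : NEG) + e;
  }
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < S; ++s) {
      double best = NEG * 2;
      int arg = 0;
      for (int r = 0; r < S; ++r) {
        double cand = delta(t - 1, r) + (trans(r, s) > 0 ? std::log(trans(r, s)) : NEG);
        if (cand > best) { best = cand; arg = r; }
      }
      double e = std::log(gauss_pdf(x[t], means[s], sds[s]) + 1e-300);
      delta(t, s) = best + e;
      psi(t, s) = arg;
    }
  }
  IntegerVector path(T);
  double best = delta(T - 1, 0);
  int arg = 0;
  for (int s = 1; s < S; ++s)
    if (delta(T - 1, s) > best) { best = delta(T - 1, s); arg = s; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);

  return List::create(_["path"] = path + 1, _["loglik"] = best);
}
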