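#include <Rcpp.h>
using namespace Rcpp;

// Model codes shared with R/models.R: 1 = full_sv, 2 = reward_only, 3 = tdrl.
//
// Trial data layout (one session): parallel vectors of length n_trials.
//   choice: 0 = easy, 1 = hard (the action actually taken, incl. forced ones)
//   prob:   reward probability level (0.12 / 0.50 / 0.88)
//   easy_mag, hard_mag: dollar magnitudes
//   random_assigned: 1 if the trial was a forced (random) assignment
//   payoff: realized dollars (0 unless completed and rewarded)
//
// Random-assigned trials feed the TDRL value updates but are excluded from
// the log-likelihood sum (and from pointwise output columns).

static const double EASY_EFFORT = 0.3;
static const double HARD_EFFORT = 1.0;
static const double LOG_2PI = 1.8378770664093454836;

// log(1 + exp(x)) without overflow
static inline double lse_log1pexp(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

struct TraceOut {
  double loglik;
  int n_eval;
  // gradient wrt constrained parameters (length = n params of the model)
  double grad[3];
  // optional per-evaluated-trial log probabilities
  std::vector<double>* pointwise;
};

// Core single-session trace. params are on the constrained scale.
// full_sv: (k, h, beta); reward_only: (k, beta); tdrl: (alpha, gamma, beta).
static void session_trace(int model, const double* params,
                          const int* choice, const double* prob,
                          const double* easy_mag, const double* hard_mag,
                          const int* random_assigned, const double* payoff,
                          int n, bool want_grad, TraceOut& out) {
  out.loglik = 0.0;
  out.n_eval = 0;
  out.grad[0] = out.grad[1] = out.grad[2] = 0.0;

  if (model == 1 || model == 2) {
    const double k = params[0];
    const double h = (model == 1) ? params[1] : 0.0;
    const double beta = (model == 1) ? params[2] : params[1];
    for (int t = 0; t < n; ++t) {
      if (random_assigned[t]) continue;
      double ve, vh, dve_dh = 0.0, dvh_dh = 0.0;
      if (model == 1) {
        const double pe = std::pow(prob[t], h);
        ve = easy_mag[t] * pe - k * EASY_EFFORT;
        vh = hard_mag[t] * pe - k * HARD_EFFORT;
        dve_dh = easy_mag[t] * pe * std::log(prob[t]);
        dvh_dh = hard_mag[t] * pe * std::log(prob[t]);
      } else {
        ve = easy_mag[t] - k * EASY_EFFORT;
        vh = hard_mag[t] - k * HARD_EFFORT;
      }
      const bool hard = choice[t] == 1;
      const double D = hard ? (vh - ve) : (ve - vh); // chosen minus unchosen
      const double lp = -lse_log1pexp(-beta * D);
      out.loglik += lp;
      out.n_eval += 1;
      if (out.pointwise) out.pointwise->push_back(lp);
      if (want_grad) {
        const double q = 1.0 / (1.0 + std::exp(beta * D)); // 1 - p(chosen)
        const double dD_dk = hard ? -(HARD_EFFORT - EASY_EFFORT)
                                  : -(EASY_EFFORT - HARD_EFFORT);
        if (model == 1) {
          const double dD_dh = hard ? (dvh_dh - dve_dh) : (dve_dh - dvh_dh);
          out.grad[0] += q * beta * dD_dk;
          out.grad[1] += q * beta * dD_dh;
          out.grad[2] += q * D;
        } else {
          out.grad[0] += q * beta * dD_dk;
          out.grad[1] += q * D;
        }
      }
    }
  } else if (model == 3) {
    const double alpha = params[0];
    const double gamma = params[1];
    const double beta = params[2];
    // Q[a][i], i = 0,1,2 for the three within-trial time points,
    // plus forward-mode derivatives wrt alpha and gamma.
    double Q[2][3] = {{0, 0, 0}, {0, 0, 0}};
    double Qa[2][3] = {{0, 0, 0}, {0, 0, 0}};
    double Qg[2][3] = {{0, 0, 0}, {0, 0, 0}};
    for (int t = 0; t < n; ++t) {
      const int a = choice[t];
      const int u = 1 - a;
      if (!random_assigned[t]) {
        const double D = Q[a][0] - Q[u][0];
        const double lp = -lse_log1pexp(-beta * D);
        out.loglik += lp;
        out.n_eval += 1;
        if (out.pointwise) out.pointwise->push_back(lp);
        if (want_grad) {
          const double q = 1.0 / (1.0 + std::exp(beta * D));
          out.grad[0] += q * beta * (Qa[a][0] - Qa[u][0]);
          out.grad[1] += q * beta * (Qg[a][0] - Qg[u][0]);
          out.grad[2] += q * D;
        }
      }
      // Sequential TD updates along the chosen chain, i = 1,2,3.
      const double r = payoff[t];
      // i = 1: successor is the chosen chain's second time point
      double delta = gamma * Q[a][1] - Q[a][0];
      if (want_grad) {
        const double dd_a = gamma * Qa[a][1] - Qa[a][0];
        const double dd_g = Q[a][1] + gamma * Qg[a][1] - Qg[a][0];
        Qa[a][0] += delta + alpha * dd_a;
        Qg[a][0] += alpha * dd_g;
      }
      Q[a][0] += alpha * delta;
      // i = 2
      delta = gamma * Q[a][2] - Q[a][1];
      if (want_grad) {
        const double dd_a = gamma * Qa[a][2] - Qa[a][1];
        const double dd_g = Q[a][2] + gamma * Qg[a][2] - Qg[a][1];
        Qa[a][1] += delta + alpha * dd_a;
        Qg[a][1] += alpha * dd_g;
      }
      Q[a][1] += alpha * delta;
      // i = 3: terminal, successor value 0, outcome delivered here
      delta = r - Q[a][2];
      if (want_grad) {
        Qa[a][2] += delta + alpha * (-Qa[a][2]);
        Qg[a][2] += alpha * (-Qg[a][2]);
      }
      Q[a][2] += alpha * delta;
    }
  } else {
    stop("unknown model code");
  }
}

static int n_params_of(int model) { return model == 2 ? 2 : 3; }

// [[Rcpp::export]]
List cpp_session_loglik(int model, NumericVector params, IntegerVector choice,
                        NumericVector prob, NumericVector easy_mag,
                        NumericVector hard_mag, IntegerVector random_assigned,
                        NumericVector payoff, bool want_grad = false) {
  const int n = choice.size();
  TraceOut out;
  out.pointwise = nullptr;
  session_trace(model, params.begin(), choice.begin(), prob.begin(),
                easy_mag.begin(), hard_mag.begin(), random_assigned.begin(),
                payoff.begin(), n, want_grad, out);
  const int J = n_params_of(model);
  NumericVector g(J);
  for (int j = 0; j < J; ++j) g[j] = out.grad[j];
  return List::create(_["loglik"] = out.loglik, _["n_evaluated"] = out.n_eval,
                      _["grad"] = g);
}

// Hierarchical log posterior over all subjects, non-centered parameterization.
//
// theta layout (unconstrained): mu[c,j] (C*J), tau[c,j] (C*J, log scales),
// z[s,j] (S*J). Individual unconstrained value x = mu + exp(tau) * z, mapped
// to the constrained scale by a scaled logistic with bounds (lower_j, upper_j).
//
// Returns lp, gradient, and the additive decomposition
// (hyperprior, individual prior, likelihood, jacobian of tau -> sigma).
// [[Rcpp::export]]
List cpp_hier_lp(int model, NumericVector theta, int n_cohorts,
                 IntegerVector cohort_of_subj, IntegerVector offsets,
                 IntegerVector choice, NumericVector prob,
                 NumericVector easy_mag, NumericVector hard_mag,
                 IntegerVector random_assigned, NumericVector payoff,
                 NumericVector lower, NumericVector upper,
                 NumericVector prior_loc_mean, double prior_loc_sd,
                 double prior_scale_sd, bool want_grad = true) {
  const int J = n_params_of(model);
  const int C = n_cohorts;
  const int S = cohort_of_subj.size();
  if (theta.size() != 2 * C * J + S * J) stop("theta length mismatch");

  const double* mu = theta.begin();
  const double* tau = theta.begin() + C * J;
  const double* z = theta.begin() + 2 * C * J;

  NumericVector grad(theta.size());
  double lp_hyper = 0.0, lp_indiv = 0.0, lp_lik = 0.0, lp_jac = 0.0;

  // hyperpriors
  for (int i = 0; i < C * J; ++i) {
    const double mu_c = mu[i] - prior_loc_mean[i % J];
    lp_hyper += -0.5 * (mu_c / prior_loc_sd) * (mu_c / prior_loc_sd) -
                std::log(prior_loc_sd) - 0.5 * LOG_2PI;
    const double sigma = std::exp(tau[i]);
    // half-normal(prior_scale_sd) on sigma
    lp_hyper += std::log(2.0) - 0.5 * LOG_2PI - std::log(prior_scale_sd) -
                0.5 * (sigma / prior_scale_sd) * (sigma / prior_scale_sd);
    lp_jac += tau[i];
    if (want_grad) {
      grad[i] += -mu_c / (prior_loc_sd * prior_loc_sd);
      grad[C * J + i] +=
          1.0 - (sigma * sigma) / (prior_scale_sd * prior_scale_sd);
    }
  }
  // individual standard-normal effects
  for (int i = 0; i < S * J; ++i) {
    lp_indiv += -0.5 * z[i] * z[i] - 0.5 * LOG_2PI;
    if (want_grad) grad[2 * C * J + i] += -z[i];
  }

  // likelihood
  double con[3];
  TraceOut out;
  out.pointwise = nullptr;
  for (int s = 0; s < S; ++s) {
    const int c = cohort_of_subj[s];
    double dcon_dx[3];
    for (int j = 0; j < J; ++j) {
      const double x = mu[c * J + j] + std::exp(tau[c * J + j]) * z[s * J + j];
      const double p = 1.0 / (1.0 + std::exp(-x));
      con[j] = lower[j] + (upper[j] - lower[j]) * p;
      dcon_dx[j] = (upper[j] - lower[j]) * p * (1.0 - p);
    }
    const int o = offsets[s];
    const int nt = offsets[s + 1] - o;
    session_trace(model, con, choice.begin() + o, prob.begin() + o,
                  easy_mag.begin() + o, hard_mag.begin() + o,
                  random_assigned.begin() + o, payoff.begin() + o, nt,
                  want_grad, out);
    lp_lik += out.loglik;
    if (want_grad) {
      for (int j = 0; j < J; ++j) {
        const double gx = out.grad[j] * dcon_dx[j]; // d ll / d x
        const double sigma = std::exp(tau[c * J + j]);
        grad[c * J + j] += gx;
        grad[C * J + c * J + j] += gx * z[s * J + j] * sigma;
        grad[2 * C * J + s * J + j] += gx * sigma;
      }
    }
  }

  const double lp = lp_hyper + lp_indiv + lp_lik + lp_jac;
  return List::create(
      _["lp"] = lp, _["grad"] = grad,
      _["parts"] = NumericVector::create(
          _["hyperprior"] = lp_hyper, _["individual_prior"] = lp_indiv,
          _["loglik"] = lp_lik, _["jacobian"] = lp_jac));
}

// Per-draw, per-evaluated-choice log probabilities.
// draws: matrix n_draws x (S*J) of *constrained* individual parameters,
// columns ordered subject-major (subject s parameter j at s*J + j).
// [[Rcpp::export]]
NumericMatrix cpp_pointwise_loglik(int model, NumericMatrix draws,
                                   IntegerVector offsets, IntegerVector choice,
                                   NumericVector prob, NumericVector easy_mag,
                                   NumericVector hard_mag,
                                   IntegerVector random_assigned,
                                   NumericVector payoff) {
  const int J = n_params_of(model);
  const int S = offsets.size() - 1;
  if (draws.ncol() != S * J) stop("draws column count mismatch");
  int n_eval = 0;
  for (int t = 0; t < choice.size(); ++t)
    if (!random_assigned[t]) ++n_eval;
  NumericMatrix ll(draws.nrow(), n_eval);
  std::vector<double> buf;
  double par[3];
  for (int d = 0; d < draws.nrow(); ++d) {
    int col = 0;
    for (int s = 0; s < S; ++s) {
      for (int j = 0; j < J; ++j) par[j] = draws(d, s * J + j);
      buf.clear();
      TraceOut out;
      out.pointwise = &buf;
      const int o = offsets[s];
      session_trace(model, par, choice.begin() + o, prob.begin() + o,
                    easy_mag.begin() + o, hard_mag.begin() + o,
                    random_assigned.begin() + o, payoff.begin() + o,
                    offsets[s + 1] - o, false, out);
      for (size_t i = 0; i < buf.size(); ++i) ll(d, col++) = buf[i];
    }
  }
  return ll;
}
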