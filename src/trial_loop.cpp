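#include <Rcpp.h>
using namespace Rcpp;

// Trial-by-trial prediction core shared by simulation and likelihood code.
//
// Model ids follow the package-wide numbering:
//   1  no-learning regression            P = beta0 + beta1 * IB
//   2  fine granularity                  P(t) = E + sum alpha  * PE(i) * SIM
//   3  fine granularity, dual rates      alpha+ / alpha- by sign of PE(i)
//   4  anchored fine granularity         P = gamma * IB + (1 - gamma) * Pm
//   5  anchored, dual rates
//
// Constrained parameter layout expected in `par` (sigma always last):
//   1: beta0, beta1, sigma
//   2: alpha, e1, sigma
//   3: alpha_pos, alpha_neg, e1, sigma
//   4: alpha, e1, gamma, sigma
//   5: alpha_pos, alpha_neg, e1, gamma, sigma

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

static inline double clip(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Initial feedback expectations per item: the first-presented item carries the
// free parameter e1; every other item j regresses toward the scale midpoint
// (anchor) in proportion to its similarity with the first item.
static void build_expectations(std::vector<double>& e,
                               double e1, int first_item,
                               const NumericMatrix& sim,
                               double anchor, double lo, double hi) {
  int n = sim.nrow();
  for (int j = 0; j < n; ++j) {
    double val = (j == first_item)
      ? e1
      : anchor + sim(first_item, j) * (e1 - anchor);
    e[j] = clip(val, lo, hi);
  }
}

// Core recursion. order is 0-based item indices in presentation order.
// Fills pm, p, pe (each length n). literal_bounds reproduces the printed
// summation limits (skip the first trial and the immediately preceding one);
// the default sums over all completed trials.
static void run_loop(int model_id, const double* par,
                     const IntegerVector& order,
                     const NumericVector& ib,
                     const NumericVector& fb,
                     const NumericMatrix& sim,
                     double anchor, double lo, double hi,
                     bool literal_bounds,
                     std::vector<double>& pm,
                     std::vector<double>& p,
                     std::vector<double>& pe) {
  int n = order.size();

  if (model_id == 1) {
    double b0 = par[0], b1 = par[1];
    for (int t = 0; t < n; ++t) {
      int item = order[t];
      p[t] = b0 + b1 * ib[item];
      pm[t] = NA_REAL;
      pe[t] = fb[t] - p[t];
    }
    return;
  }

  double a_pos, a_neg, e1, gamma;
  switch (model_id) {
    case 2: a_pos = a_neg = par[0]; e1 = par[1]; gamma = 0.0; break;
    case 3: a_pos = par[0]; a_neg = par[1]; e1 = par[2]; gamma = 0.0; break;
    case 4: a_pos = a_neg = par[0]; e1 = par[1]; gamma = par[2]; break;
    case 5: a_pos = par[0]; a_neg = par[1]; e1 = par[2]; gamma = par[3]; break;
    default: stop("unknown model_id: %d", model_id);
  }
  bool anchored = (model_id == 4 || model_id == 5);

  std::vector<double> e(n);
  build_expectations(e, e1, order[0], sim, anchor, lo, hi);

  for (int t = 0; t < n; ++t) {
    int item = order[t];
    double acc = e[item];
    int i_lo = literal_bounds ? 1 : 0;
    int i_hi = literal_bounds ? t - 2 : t - 1;
    for (int i = i_lo; i <= i_hi; ++i) {
      double a = pe[i] > 0 ? a_pos : a_neg;  // pe == 0 contributes nothing
      acc += a * pe[i] * sim(order[i], item);
    }
    pm[t] = acc;
    p[t] = anchored ? gamma * ib[item] + (1.0 - gamma) * acc : acc;
    pe[t] = fb[t] - p[t];
  }
}

// [[Rcpp::export(name = ".trial_trace_cpp")]]
NumericMatrix trial_trace_cpp(int model_id, NumericVector par,
                              IntegerVector order0, NumericVector ib,
                              NumericVector fb, NumericMatrix sim,
                              double anchor, double scale_min,
                              double scale_max, bool literal_bounds) {
  int n = order0.size();
  std::vector<double> pm(n), p(n), pe(n);
  run_loop(model_id, REAL(par), order0, ib, fb, sim,
           anchor, scale_min, scale_max, literal_bounds, pm, p, pe);
  NumericMatrix out(n, 3);
  for (int t = 0; t < n; ++t) {
    out(t, 0) = pm[t];
    out(t, 1) = p[t];
    out(t, 2) = pe[t];
  }
  colnames(out) = CharacterVector::create("pm", "prediction", "pe");
  return out;
}

// Negative log posterior in unconstrained space: Gaussian observation model
// on the Block-2 ratings plus independent Gaussian priors on the
// unconstrained parameters. Transform layout matches param_space() in R.
// [[Rcpp::export(name = ".neg_log_post_cpp")]]
double neg_log_post_cpp(NumericVector x, int model_id,
                        IntegerVector order0, NumericVector ib,
                        NumericVector fb, NumericVector ratings,
                        NumericMatrix sim, NumericVector prior_mean,
                        NumericVector prior_var, double anchor,
                        double scale_min, double scale_max,
                        bool literal_bounds) {
  int d = x.size();
  double range = scale_max - scale_min;
  double par[5];

  switch (model_id) {
    case 1:
      par[0] = x[0];
      par[1] = x[1];
      par[2] = std::exp(x[2]);
      break;
    case 2:
      par[0] = inv_logit(x[0]);
      par[1] = scale_min + range * inv_logit(x[1]);
      par[2] = std::exp(x[2]);
      break;
    case 3:
      par[0] = inv_logit(x[0]);
      par[1] = inv_logit(x[1]);
      par[2] = scale_min + range * inv_logit(x[2]);
      par[3] = std::exp(x[3]);
      break;
    case 4:
      par[0] = inv_logit(x[0]);
      par[1] = scale_min + range * inv_logit(x[1]);
      par[2] = inv_logit(x[2]);
      par[3] = std::exp(x[3]);
      break;
    case 5:
      par[0] = inv_logit(x[0]);
      par[1] = inv_logit(x[1]);
      par[2] = scale_min + range * inv_logit(x[2]);
      par[3] = inv_logit(x[3]);
      par[4] = std::exp(x[4]);
      break;
    default: stop("unknown model_id: %d", model_id);
  }
  double sigma = par[d - 1];

  int n = order0.size();
  std::vector<double> pm(n), p(n), pe(n);
  run_loop(model_id, par, order0, ib, fb, sim,
           anchor, scale_min, scale_max, literal_bounds, pm, p, pe);

  const double LOG_2PI = 1.8378770664093454836;
  double ll = 0.0;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double lsig = std::log(sigma);
  for (int t = 0; t < n; ++t) {
    double r = ratings[t] - p[t];
    ll += -0.5 * LOG_2PI - lsig - r * r * inv2s2;
  }

  double lp = 0.0;
  for (int j = 0; j < d; ++j) {
    double z = x[j] - prior_mean[j];
    lp += -0.5 * LOG_2PI - 0.5 * std::log(prior_var[j])
          - z * z / (2.0 * prior_var[j]);
  }

  double nlp = -(ll + lp);
  if (!std::isfinite(nlp)) nlp = 1e10;
  return nlp;
}
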