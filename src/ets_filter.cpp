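#include <Rcpp.h>
using namespace Rcpp;

// Holt-Winters seasonal smoothing filter.
//
// Runs the classical recursions over y given fixed smoothing weights and
// initial states, returning the full state trajectories, one-step fitted
// values and residuals, and the residual sum of squares.
//
// Conventions (t = 1..n):
//   additive / damped (phi = 1 reduces damped to additive):
//     yhat_t = l_{t-1} + phi * b_{t-1} + s_{t-m}
//     l_t    = alpha * (y_t - s_{t-m}) + (1 - alpha) * (l_{t-1} + phi * b_{t-1})
//     b_t    = beta  * (l_t - l_{t-1}) + (1 - beta)  * phi * b_{t-1}
//     s_t    = gamma * (y_t - l_{t-1} - phi * b_{t-1}) + (1 - gamma) * s_{t-m}
//   multiplicative (trend undamped):
//     yhat_t = (l_{t-1} + b_{t-1}) * s_{t-m}
//     l_t    = alpha * (y_t / s_{t-m}) + (1 - alpha) * (l_{t-1} + b_{t-1})
//     b_t    = beta  * (l_t - l_{t-1}) + (1 - beta)  * b_{t-1}
//     s_t    = gamma * (y_t / (l_{t-1} + b_{t-1})) + (1 - gamma) * s_{t-m}
//
// The seasonal vector is stored padded: seas[0..m-1] holds the initial
// indices s_{1-m}..s_0, seas[m + t - 1] holds s_t.
// [[Rcpp::export]]
List ets_filter_cpp(NumericVector y, int m,
                    double alpha, double beta, double gamma, double phi,
                    double l0, double b0, NumericVector s0,
                    bool multiplicative) {
  int n = y.size();
  if (s0.size() != m) stop("initial seasonal vector must have length m");
  NumericVector level(n), trend(n), fitted(n), resid(n);
  NumericVector seas(n + m);
  for (int j = 0; j < m; ++j) seas[j] = s0[j];

  double l_prev = l0, b_prev = b0;
  double sse = 0.0;
  for (int t = 0; t < n; ++t) {
    double s_lag = seas[t];            // s_{t-m}
    double base = l_prev + phi * b_prev;
    double yh, l_new, b_new, s_new;
    if (multiplicative) {
      if (s_lag == 0.0 || base == 0.0)
        stop("multiplicative recursion hit a zero level+trend or seasonal index");
      yh = base * s_lag;
      l_new = alpha * (y[t] / s_lag) + (1.0 - alpha) * base;
      b_new = beta * (l_new - l_prev) + (1.0 - beta) * phi * b_prev;
      s_new = gamma * (y[t] / base) + (1.0 - gamma) * s_lag;
    } else {
      yh = base + s_lag;
      l_new = alpha * (y[t] - s_lag) + (1.0 - alpha) * base;
      b_new = beta * (l_new - l_prev) + (1.0 - beta) * phi * b_prev;
      s_new = gamma * (y[t] - base) + (1.0 - gamma) * s_lag;
    }
    double e = y[t] - yh;
    sse += e * e;
    level[t] = l_new;
    trend[t] = b_new;
    seas[m + t] = s_new;
    fitted[t] = yh;
    resid[t] = e;
    l_prev = l_new;
    b_prev = b_new;
  }

  NumericVector s_final(m);
  for (int j = 0; j < m; ++j) s_final[j] = seas[n + j];

  return List::create(_["level"] = level,
                      _["trend"] = trend,
                      _["seasonal"] = seas,
                      _["s_final"] = s_final,
                      _["fitted"] = fitted,
                      _["residuals"] = resid,
                      _["sse"] = sse);
}

// Residual sum of squares only; the optimizer's objective.
// [[Rcpp::export]]
double ets_sse_cpp(NumericVector y, int m,
                   double alpha, double beta, double gamma, double phi,
                   double l0, double b0, NumericVector s0,
                   bool multiplicative) {
  int n = y.size();
  std::vector<double> seas(n + m);
  for (int j = 0; j < m; ++j) seas[j] = s0[j];
  double l_prev = l0, b_prev = b0, sse = 0.0;
  for (int t = 0; t < n; ++t) {
    double s_lag = seas[t];
    double base = l_prev + phi * b_prev;
    double l_new, s_new, e;
    if (multiplicative) {
      if (s_lag == 0.0 || base == 0.0) return R_PosInf;
      e = y[t] - base * s_lag;
      l_new = alpha * (y[t] / s_lag) + (1.0 - alpha) * base;
      s_new = gamma * (y[t] / base) + (1.0 - gamma) * s_lag;
    } else {
      e = y[t] - (base + s_lag);
      l_new = alpha * (y[t] - s_lag) + (1.0 - alpha) * base;
      s_new = gamma * (y[t] - base) + (1.0 - gamma) * s_lag;
    }
    double b_new = beta * (l_new - l_prev) + (1.0 - beta) * phi * b_prev;
    sse += e * e;
    seas[m + t] = s_new;
    l_prev = l_new;
    b_prev = b_new;
  }
  if (!std::isfinite(sse)) return R_PosInf;
  return sse;
}
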