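#include <Rcpp.h>
using namespace Rcpp;

// Family codes (kept in sync with MODEL_FAMILIES on the R side):
// 1 = ql, 2 = fql, 3 = fql_egreedy, 4 = directed, 5 = meta

namespace {

inline double clamp01(double x) {
  if (x < 0.0) return 0.0;
  if (x > 1.0) return 1.0;
  return x;
}

// softmax over x with max-subtraction; writes into p
inline void softmax_fill(const std::vector<double>& x, std::vector<double>& p) {
  const int n = x.size();
  double m = x[0];
  for (int i = 1; i < n; ++i) if (x[i] > m) m = x[i];
  double s = 0.0;
  for (int i = 0; i < n; ++i) { p[i] = std::exp(x[i] - m); s += p[i]; }
  for (int i = 0; i < n; ++i) p[i] /= s;
}

// epsilon-greedy with ties: non-argmax levers get eps/(n-1), the argmax set
// shares the remaining mass equally (all-equal Q => uniform)
inline void egreedy_fill(const std::vector<double>& q, double eps,
                         std::vector<double>& p) {
  const int n = q.size();
  double m = q[0];
  for (int i = 1; i < n; ++i) if (q[i] > m) m = q[i];
  const double tol = 1e-12;
  int nmax = 0;
  for (int i = 0; i < n; ++i) if (q[i] >= m - tol) ++nmax;
  const double p_other = eps / (n - 1);
  const double p_max = (1.0 - (n - nmax) * p_other) / nmax;
  for (int i = 0; i < n; ++i) p[i] = (q[i] >= m - tol) ? p_max : p_other;
}

// Core constrained replay: walks the model through the observed actions and
// rewards, recording the full choice-probability matrix (state before each
// trial). Q, v, R are reset to 0 at the start of the sequence; callers split
// data by subject x condition.
void replay_core(int family, const NumericVector& par,
                 const IntegerVector& action, const NumericVector& reward,
                 int n_levers, bool update_on_loss, NumericMatrix& P) {
  const int T = action.size();
  const int n = n_levers;
  std::vector<double> Q(n, 0.0), v(n, 0.0), x(n), p(n);

  // parameters are clamped to their boxes so that finite-difference
  // excursions of the optimizer just outside a bound stay well-defined
  double alpha = 0, alpha2 = 0, beta = 0, eps = 0,
         alpha_phi = 0, phi = 0, alpha_r = 0, beta0 = 0, beta1 = 0;
  switch (family) {
  case 1: alpha = clamp01(par[0]); beta = std::max(0.0, par[1]); break;
  case 2: alpha = clamp01(par[0]); alpha2 = clamp01(par[1]);
          beta = std::max(0.0, par[2]); break;
  case 3: alpha = clamp01(par[0]); alpha2 = clamp01(par[1]);
          eps = clamp01(par[2]); break;
  case 4: alpha = clamp01(par[0]); alpha2 = clamp01(par[1]);
          beta = std::max(0.0, par[2]); alpha_phi = clamp01(par[3]);
          phi = par[4]; break;
  case 5: alpha = clamp01(par[0]); alpha2 = clamp01(par[1]);
          alpha_r = clamp01(par[2]); beta0 = std::max(0.0, par[3]);
          beta1 = std::max(0.0, par[4]); break;
  default: stop("unknown family code");
  }

  double R = 0.0;
  double beta_t = beta0;  // meta only

  for (int t = 0; t < T; ++t) {
    // choice probabilities from the state before trial t
    switch (family) {
    case 1: case 2:
      for (int i = 0; i < n; ++i) x[i] = beta * Q[i];
      softmax_fill(x, p);
      break;
    case 3:
      egreedy_fill(Q, eps, p);
      break;
    case 4:
      for (int i = 0; i < n; ++i) x[i] = beta * (Q[i] + phi * v[i]);
      softmax_fill(x, p);
      break;
    case 5:
      for (int i = 0; i < n; ++i) x[i] = beta_t * Q[i];
      softmax_fill(x, p);
      break;
    }
    for (int i = 0; i < n; ++i) P(t, i) = p[i];

    // learning update from the observed outcome
    const int a = action[t];
    const double r = reward[t];
    const double delta = r - Q[a];
    Q[a] += alpha * delta;
    if (family != 1) {
      for (int i = 0; i < n; ++i) if (i != a) Q[i] *= (1.0 - alpha2);
    }
    if (family == 4 && (r > 0.0 || update_on_loss)) {
      const double xi = delta * delta - v[a];
      v[a] += alpha_phi * xi;
    }
    if (family == 5) {
      R += alpha_r * delta;
      beta_t = beta0 + (beta1 - beta0) * R;
      if (beta_t < 0.0) beta_t = 0.0;  // negative beta would invert preferences
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector ll_trials_cpp(int family, NumericVector par, IntegerVector action,
                            NumericVector reward, int n_levers,
                            bool update_on_loss) {
  const int T = action.size();
  NumericMatrix P(T, n_levers);
  replay_core(family, par, action, reward, n_levers, update_on_loss, P);
  NumericVector lp(T);
  const double floor = 1e-12;  // guards log() against underflow
  for (int t = 0; t < T; ++t) {
    double pc = P(t, action[t]);
    lp[t] = std::log(pc > floor ? pc : floor);
  }
  return lp;
}

// [[Rcpp::export]]
NumericMatrix probs_trials_cpp(int family, NumericVector par,
                               IntegerVector action, NumericVector reward,
                               int n_levers, bool update_on_loss) {
  const int T = action.size();
  NumericMatrix P(T, n_levers);
  replay_core(family, par, action, reward, n_levers, update_on_loss, P);
  return P;
}
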