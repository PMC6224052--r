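#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// log(sum(exp(v))) over a raw buffer, tolerating -Inf entries
static double logsumexp(const double* v, int n) {
  double m = NEG_INF;
  for (int i = 0; i < n; ++i) if (v[i] > m) m = v[i];
  if (m == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward recursion in log space; fills log_alpha (T x N, column-major) and
// returns log p(x_{1:T}).
static double forward_pass(const IntegerVector& x,
                           const NumericVector& log_pi,
                           const NumericMatrix& log_A,
                           const NumericMatrix& log_B,
                           std::vector<double>& log_alpha) {
  const int T = x.size(), N = log_pi.size();
  std::vector<double> buf(N);
  for (int s = 0; s < N; ++s)
    log_alpha[0 + (size_t)s * T] = log_pi[s] + log_B(s, x[0]);
  for (int t = 1; t < T; ++t) {
    for (int s = 0; s < N; ++s) {
      for (int r = 0; r < N; ++r)
        buf[r] = log_alpha[(t - 1) + (size_t)r * T] + log_A(r, s);
      log_alpha[t + (size_t)s * T] = logsumexp(buf.data(), N) + log_B(s, x[t]);
    }
  }
  std::vector<double> last(N);
  for (int s = 0; s < N; ++s) last[s] = log_alpha[(T - 1) + (size_t)s * T];
  return logsumexp(last.data(), N);
}

// Backward recursion; fills log_beta (T x N).
static void backward_pass(const IntegerVector& x,
                          const NumericMatrix& log_A,
                          const NumericMatrix& log_B,
                          std::vector<double>& log_beta) {
  const int T = x.size(), N = log_A.nrow();
  std::vector<double> buf(N);
  for (int s = 0; s < N; ++s) log_beta[(T - 1) + (size_t)s * T] = 0.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int s = 0; s < N; ++s) {
      for (int r = 0; r < N; ++r)
        buf[r] = log_A(s, r) + log_B(r, x[t + 1]) + log_beta[(t + 1) + (size_t)r * T];
      log_beta[t + (size_t)s * T] = logsumexp(buf.data(), N);
    }
  }
}

// [[Rcpp::export]]
double hmm_loglik_cpp(IntegerVector x, NumericVector log_pi,
                      NumericMatrix log_A, NumericMatrix log_B) {
  const int T = x.size(), N = log_pi.size();
  std::vector<double> log_alpha((size_t)T * N);
  return forward_pass(x, log_pi, log_A, log_B, log_alpha);
}

// [[Rcpp::export]]
List hmm_forward_backward_cpp(IntegerVector x, NumericVector log_pi,
                              NumericMatrix log_A, NumericMatrix log_B) {
  const int T = x.size(), N = log_pi.size();
  std::vector<double> log_alpha((size_t)T * N), log_beta((size_t)T * N);
  const double ll = forward_pass(x, log_pi, log_A, log_B, log_alpha);
  backward_pass(x, log_A, log_B, log_beta);

  // backward-route log-likelihood for cross-checking the recursions
  std::vector<double> b0(N);
  for (int s = 0; s < N; ++s)
    b0[s] = log_pi[s] + log_B(s, x[0]) + log_beta[0 + (size_t)s * T];
  const double ll_b = logsumexp(b0.data(), N);

  NumericMatrix gamma(T, N);
  for (int t = 0; t < T; ++t)
    for (int s = 0; s < N; ++s) {
      double g = log_alpha[t + (size_t)s * T] + log_beta[t + (size_t)s * T] - ll;
      gamma(t, s) = std::exp(g);
    }

  NumericVector xi;
  if (T > 1) {
    xi = NumericVector(Dimension(T - 1, N, N));
    for (int t = 0; t < T - 1; ++t)
      for (int r = 0; r < N; ++r)
        for (int s = 0; s < N; ++s) {
          double v = log_alpha[t + (size_t)r * T] + log_A(r, s) +
                     log_B(s, x[t + 1]) + log_beta[(t + 1) + (size_t)s * T] - ll;
          xi[t + (size_t)r * (T - 1) + (size_t)s * (T - 1) * N] = std::exp(v);
        }
  } else {
    xi = NumericVector(Dimension(0, N, N));
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = ll, _["loglik_backward"] = ll_b);
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export]]
List hmm_viterbi_cpp(IntegerVector x, NumericVector log_pi,
                     NumericMatrix log_A, NumericMatrix log_B) {
  const int T = x.size(), N = log_pi.size();
  std::vector<double> delta((size_t)T * N);
  std::vector<int> psi((size_t)T * N);
  for (int s = 0; s < N; ++s) {
    delta[0 + (size_t)s * T] = log_pi[s] + log_B(s, x[0]);
    psi[0 + (size_t)s * T] = 0;
  }
  for (int t = 1; t < T; ++t)
    for (int s = 0; s < N; ++s) {
      double best = NEG_INF;
      int arg = 0;
      for (int r = 0; r < N; ++r) {
        const double v = delta[(t - 1) + (size_t)r * T] + log_A(r, s);
        if (v > best) { best = v; arg = r; }  // strict ">" keeps lowest r on tie
      }
      delta[t + (size_t)s * T] = best + log_B(s, x[t]);
      psi[t + (size_t)s * T] = arg;
    }
  double best = NEG_INF;
  int arg = 0;
  for (int s = 0; s < N; ++s) {
    const double v = delta[(T - 1) + (size_t)s * T];
    if (v > best) { best = v; arg = s; }
  }
  IntegerVector path(T);
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t)
    path[t] = psi[(t + 1) + (size_t)path[t + 1] * T];
  return List::create(_["states"] = path, _["log_joint"] = best);
}

// Scaled (linear-space) forward recursion, Rabiner convention: alpha_hat
// rows sum to 1, c holds the per-step scaling totals, and
// log p(x_{1:T}) = sum_t log c_t. Returns -Inf when some step has zero
// total mass (an observation impossible under every reachable state).
// Emission probability with optional boundary truncation: the first and
// last months of a series are utilization months by construction, so under
// boundary-aware fitting their emissions follow the zero-truncated row
// B_adj (cell 0 removed, remainder renormalized).
static inline double emis(const NumericMatrix& B, const NumericMatrix& Badj,
                          bool boundary, int T, int t, int s, int x) {
  if (boundary && (t == 0 || t == T - 1) && x > 0) return Badj(s, x);
  return B(s, x);
}

static double forward_scaled(const IntegerVector& x,
                             const NumericVector& pi,
                             const NumericMatrix& A,
                             const NumericMatrix& B,
                             const NumericMatrix& Badj,
                             bool boundary,
                             std::vector<double>& alpha,
                             std::vector<double>& c) {
  const int T = x.size(), N = pi.size();
  double tot = 0.0;
  for (int s = 0; s < N; ++s) {
    alpha[0 + (size_t)s * T] = pi[s] * emis(B, Badj, boundary, T, 0, s, x[0]);
    tot += alpha[0 + (size_t)s * T];
  }
  if (tot <= 0.0) return NEG_INF;
  c[0] = tot;
  for (int s = 0; s < N; ++s) alpha[0 + (size_t)s * T] /= tot;
  double ll = std::log(tot);
  for (int t = 1; t < T; ++t) {
    tot = 0.0;
    for (int s = 0; s < N; ++s) {
      double v = 0.0;
      for (int r = 0; r < N; ++r)
        v += alpha[(t - 1) + (size_t)r * T] * A(r, s);
      v *= emis(B, Badj, boundary, T, t, s, x[t]);
      alpha[t + (size_t)s * T] = v;
      tot += v;
    }
    if (tot <= 0.0) return NEG_INF;
    c[t] = tot;
    for (int s = 0; s < N; ++s) alpha[t + (size_t)s * T] /= tot;
    ll += std::log(tot);
  }
  return ll;
}

// Scaled backward recursion sharing the forward scaling totals c.
static void backward_scaled(const IntegerVector& x,
                            const NumericMatrix& A,
                            const NumericMatrix& B,
                            const NumericMatrix& Badj,
                            bool boundary,
                            const std::vector<double>& c,
                            std::vector<double>& beta) {
  const int T = x.size(), N = A.nrow();
  for (int s = 0; s < N; ++s) beta[(T - 1) + (size_t)s * T] = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const double ct1 = c[t + 1];
    for (int s = 0; s < N; ++s) {
      double v = 0.0;
      for (int r = 0; r < N; ++r)
        v += A(s, r) * emis(B, Badj, boundary, T, t + 1, r, x[t + 1]) *
             beta[(t + 1) + (size_t)r * T];
      beta[t + (size_t)s * T] = v / ct1;
    }
  }
}

// Complete E-step of the mixture: per-series component log-likelihoods,
// responsibilities, and responsibility-weighted expected counts for the
// initial, transition and emission distributions of every component.
// Parameters arrive in linear space; recursions use Rabiner scaling
// (with gamma_t = alpha_hat_t * beta_hat_t and
// xi_t = alpha_hat_t A B beta_hat_{t+1} / c_{t+1}).
// [[Rcpp::export]]
List mhmm_estep_cpp(List series, NumericVector w,
                    List pi_list, List A_list, List B_list,
                    bool boundary) {
  const int n = series.size(), M = w.size();
  NumericMatrix comp_ll(n, M), resp(n, M);
  const int N = as<NumericVector>(pi_list[0]).size();
  const int K = as<NumericMatrix>(B_list[0]).ncol();

  NumericMatrix init(M, N);
  List trans(M), emit(M);
  for (int m = 0; m < M; ++m) {
    trans[m] = NumericMatrix(N, N);
    emit[m] = NumericMatrix(N, K);
  }
  std::vector<double> log_w(M);
  for (int m = 0; m < M; ++m)
    log_w[m] = w[m] > 0 ? std::log(w[m]) : NEG_INF;

  // zero-truncated emission rows for boundary months
  List Badj_list(M);
  for (int m = 0; m < M; ++m) {
    NumericMatrix B = B_list[m];
    NumericMatrix Badj(N, K);
    for (int s = 0; s < N; ++s) {
      const double pos = 1.0 - B(s, 0);
      for (int k = 1; k < K; ++k)
        Badj(s, k) = pos > 0 ? B(s, k) / pos : 0.0;
      Badj(s, 0) = 0.0;
    }
    Badj_list[m] = Badj;
  }

  double total_ll = 0.0;
  std::vector<double> lw(M);
  std::vector<std::vector<double> > alpha(M), cvec(M);
  std::vector<double> beta;

  for (int i = 0; i < n; ++i) {
    IntegerVector x = series[i];
    const int T = x.size();
    for (int m = 0; m < M; ++m) {
      alpha[m].resize((size_t)T * N);
      cvec[m].resize(T);
      comp_ll(i, m) = forward_scaled(x, pi_list[m], A_list[m], B_list[m],
                                     Badj_list[m], boundary,
                                     alpha[m], cvec[m]);
      lw[m] = log_w[m] + comp_ll(i, m);
    }
    const double lse = logsumexp(lw.data(), M);
    total_ll += lse;
    for (int m = 0; m < M; ++m)
      resp(i, m) = (lse == NEG_INF) ? NA_REAL : std::exp(lw[m] - lse);
    if (lse == NEG_INF) continue;  // flagged via NA responsibilities

    beta.resize((size_t)T * N);
    for (int m = 0; m < M; ++m) {
      const double r_im = resp(i, m);
      if (r_im <= 0.0 || comp_ll(i, m) == NEG_INF) continue;
      NumericMatrix A = A_list[m], B = B_list[m], Badj = Badj_list[m];
      const std::vector<double>& al = alpha[m];
      const std::vector<double>& c = cvec[m];
      backward_scaled(x, A, B, Badj, boundary, c, beta);
      NumericMatrix tr = trans[m], em = emit[m];
      for (int t = 0; t < T; ++t)
        for (int s = 0; s < N; ++s) {
          const double g = al[t + (size_t)s * T] * beta[t + (size_t)s * T];
          if (t == 0) init(m, s) += r_im * g;
          em(s, x[t]) += r_im * g;
          // boundary months are zero-truncated draws: augment the expected
          // count of hidden zero draws, B0/(1-B0) per truncated month, so
          // the closed-form M-step stays an exact EM step
          if (boundary && (t == 0 || t == T - 1) && x[t] > 0) {
            const double b0 = B(s, 0);
            if (b0 > 0 && b0 < 1)
              em(s, 0) += r_im * g * b0 / (1.0 - b0);
          }
        }
      for (int t = 0; t < T - 1; ++t) {
        const double ct1 = c[t + 1];
        for (int r = 0; r < N; ++r) {
          const double a_tr = al[t + (size_t)r * T];
          if (a_tr == 0.0) continue;
          for (int s = 0; s < N; ++s)
            tr(r, s) += r_im * a_tr * A(r, s) * B(s, x[t + 1]) *
                        beta[(t + 1) + (size_t)s * T] / ct1;
        }
      }
    }
  }
  return List::create(_["comp_loglik"] = comp_ll, _["resp"] = resp,
                      _["loglik"] = total_ll, _["init"] = init,
                      _["trans"] = trans, _["emit"] = emit);
}


// Per-series log-likelihood under each component (no statistics); linear
// parameters, scaled recursion, optional boundary truncation.
// [[Rcpp::export]]
NumericMatrix mhmm_comp_loglik_cpp(List series, List pi_list,
                                   List A_list, List B_list,
                                   bool boundary) {
  const int n = series.size(), M = pi_list.size();
  const int N = as<NumericVector>(pi_list[0]).size();
  const int K = as<NumericMatrix>(B_list[0]).ncol();
  List Badj_list(M);
  for (int m = 0; m < M; ++m) {
    NumericMatrix B = B_list[m];
    NumericMatrix Badj(N, K);
    for (int s = 0; s < N; ++s) {
      const double pos = 1.0 - B(s, 0);
      for (int k = 1; k < K; ++k)
        Badj(s, k) = pos > 0 ? B(s, k) / pos : 0.0;
      Badj(s, 0) = 0.0;
    }
    Badj_list[m] = Badj;
  }
  NumericMatrix out(n, M);
  std::vector<double> alpha, c;
  for (int i = 0; i < n; ++i) {
    IntegerVector x = series[i];
    alpha.resize((size_t)x.size() * N);
    c.resize(x.size());
    for (int m = 0; m < M; ++m)
      out(i, m) = forward_scaled(x, pi_list[m], A_list[m], B_list[m],
                                 Badj_list[m], boundary, alpha, c);
  }
  return out;
}
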