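#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Matrix exponential of a generator by uniformization:
//   exp(tQ) = sum_k Pois(k; q*t) * M^k,  M = I + Q/q,  q >= max exit rate.
// The identity holds for any q > 0; choosing q as the max exit rate keeps M
// substochastic and the series numerically benign.  Poisson weights are
// computed in log space so large q*t does not underflow.
// ---------------------------------------------------------------------------

static inline int series_length(double lambda) {
  int k = (int)(lambda + 12.0 * std::sqrt(lambda + 4.0) + 25.0);
  return k;
}

// Full-matrix version (used for transition_probability and diagnostics).
static void expm_unif(const std::vector<double>& Q, int S, double dt,
                      std::vector<double>& P) {
  double qmax = 0.0;
  for (int i = 0; i < S; ++i) qmax = std::max(qmax, -Q[i * S + i]);
  std::fill(P.begin(), P.end(), 0.0);
  if (dt <= 0.0 || qmax <= 0.0) {
    for (int i = 0; i < S; ++i) P[i * S + i] = 1.0;
    return;
  }
  double lambda = qmax * dt;
  std::vector<double> M(S * S), A(S * S), tmp(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      M[i * S + j] = Q[i * S + j] / qmax + (i == j ? 1.0 : 0.0);
  std::fill(A.begin(), A.end(), 0.0);
  for (int i = 0; i < S; ++i) A[i * S + i] = 1.0;
  int kmax = series_length(lambda);
  double lw = -lambda;  // log Poisson weight at k = 0
  for (int k = 0; k <= kmax; ++k) {
    if (k > 0) {
      for (int i = 0; i < S; ++i)
        for (int j = 0; j < S; ++j) {
          double acc = 0.0;
          for (int l = 0; l < S; ++l) acc += A[i * S + l] * M[l * S + j];
          tmp[i * S + j] = acc;
        }
      std::swap(A, tmp);
      lw += std::log(lambda) - std::log((double)k);
    }
    double w = std::exp(lw);
    if (w > 0.0) for (int i = 0; i < S * S; ++i) P[i] += w * A[i];
    if (k > lambda && w < 1e-16) break;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_ctmc_expm(NumericMatrix Q, double dt) {
  int S = Q.nrow();
  std::vector<double> q(S * S), p(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) q[i * S + j] = Q(i, j);
  expm_unif(q, S, dt, p);
  NumericMatrix P(S, S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j) {
      double v = p[i * S + j];
      P(i, j) = (v < 0.0 && v > -1e-12) ? 0.0 : v;
    }
  return P;
}

// ---------------------------------------------------------------------------
// Panel likelihood machinery.
//
// Parameter layout: E baseline log intensities, then the E x C matrix of
// per-transition covariate log hazard ratios, edge-major
// (beta[e, c] = par[E + e * C + c]).
//
// Only the s_prev row of P(dt) enters the likelihood, so the Poisson series
// is propagated as a row vector: p_{k+1} = p_k M.  The gradient uses the
// exact directional derivative of the series per edge e,
//   g_{k+1}^e = g_k^e M + p_k dM_e,  dM_e = D_e / q,
// where D_e has +q_e at (from, to) and -q_e at (from, from) per unit change
// of q_e -- and dM_e p is sparse, making the full gradient nearly free.
// ---------------------------------------------------------------------------

struct PanelData {
  int E, C, S, nsub;
  const int *edge_from, *edge_to;     // 1-based
  const int *state, *exact, *offsets; // obs arrays
  const double *time;
  const double *X;                    // nsub x C, column-major
};

// Row s0 of P(dt) and (optionally) its derivative w.r.t. each edge
// intensity q_e.  Q is the subject generator, qe the edge intensities.
static void row_expm_grad(const std::vector<double>& Q, int S, double dt,
                          int s0, int E, const int* ef, const int* et,
                          double* prow, double* drow /* E x S or null */) {
  double qmax = 0.0;
  for (int i = 0; i < S; ++i) qmax = std::max(qmax, -Q[i * S + i]);
  for (int j = 0; j < S; ++j) prow[j] = (j == s0) ? 1.0 : 0.0;
  if (drow) std::fill(drow, drow + E * S, 0.0);
  if (dt <= 0.0 || qmax <= 0.0) return;

  double lambda = qmax * dt;
  std::vector<double> M(S * S);
  for (int i = 0; i < S; ++i)
    for (int j = 0; j < S; ++j)
      M[i * S + j] = Q[i * S + j] / qmax + (i == j ? 1.0 : 0.0);

  std::vector<double> p(S), pn(S), g(E * S, 0.0), gn(E * S);
  for (int j = 0; j < S; ++j) p[j] = (j == s0) ? 1.0 : 0.0;
  std::vector<double> ps(S, 0.0), gs(E * S, 0.0);

  int kmax = series_length(lambda);
  double lw = -lambda;
  for (int k = 0; k <= kmax; ++k) {
    if (k > 0) {
      for (int j = 0; j < S; ++j) {
        double acc = 0.0;
        for (int i = 0; i < S; ++i) acc += p[i] * M[i * S + j];
        pn[j] = acc;
      }
      if (drow) {
        for (int e = 0; e < E; ++e) {
          const double* ge = &g[e * S];
          double* gne = &gn[e * S];
          for (int j = 0; j < S; ++j) {
            double acc = 0.0;
            for (int i = 0; i < S; ++i) acc += ge[i] * M[i * S + j];
            gne[j] = acc;
          }
          // + p_k * dM_e (per unit q_e): +1/qmax at (f,t), -1/qmax at (f,f)
          int f = ef[e] - 1, t = et[e] - 1;
          gne[t] += p[f] / qmax;
          gne[f] -= p[f] / qmax;
        }
        std::swap(g, gn);
      }
      std::swap(p, pn);
      lw += std::log(lambda) - std::log((double)k);
    }
    double w = std::exp(lw);
    if (w > 0.0) {
      for (int j = 0; j < S; ++j) ps[j] += w * p[j];
      if (drow) for (int i = 0; i < E * S; ++i) gs[i] += w * g[i];
    }
    if (k > lambda && w < 1e-16) break;
  }
  for (int j = 0; j < S; ++j) prow[j] = ps[j];
  if (drow) for (int i = 0; i < E * S; ++i) drow[i] = gs[i];
}

// clamp log intensities so runaway optimizer steps cannot explode the series
static const double LOGQ_CAP = 4.0;  // rate cap ~55 per year

static double subject_loglik_grad(const PanelData& d, int i,
                                  const double* par, double* grad) {
  const int E = d.E, C = d.C, S = d.S;
  std::vector<double> qe(E), Q(S * S, 0.0), qdeath(S, 0.0);
  for (int e = 0; e < E; ++e) {
    double lq = par[e];
    for (int c = 0; c < C; ++c) lq += par[E + e * C + c] * d.X[c * d.nsub + i];
    if (lq > LOGQ_CAP) lq = LOGQ_CAP;
    double q = std::exp(lq);
    qe[e] = q;
    int f = d.edge_from[e] - 1, t = d.edge_to[e] - 1;
    Q[f * S + t] += q;
    Q[f * S + f] -= q;
    if (t == S - 1) qdeath[f] = q;
  }
  std::vector<double> prow(S), drow(grad ? E * S : 0);
  double ll = 0.0;
  std::vector<double> dlik(E);
  for (int j = d.offsets[i]; j < d.offsets[i + 1] - 1; ++j) {
    int s0 = d.state[j] - 1, s1 = d.state[j + 1] - 1;
    double dt = d.time[j + 1] - d.time[j];
    row_expm_grad(Q, S, dt, s0, E, d.edge_from, d.edge_to, prow.data(),
                  grad ? drow.data() : nullptr);
    double lik;
    std::fill(dlik.begin(), dlik.end(), 0.0);
    if (d.exact[j + 1] && s1 == S - 1) {
      lik = 0.0;
      for (int s = 0; s < S - 1; ++s)
        if (qdeath[s] > 0.0) lik += prow[s] * qdeath[s];
      if (grad) {
        for (int e = 0; e < E; ++e) {
          double acc = 0.0;
          for (int s = 0; s < S - 1; ++s)
            if (qdeath[s] > 0.0) acc += drow[e * S + s] * qdeath[s];
          // direct dependence of the death intensity factor on q_e
          if (d.edge_to[e] == S) acc += prow[d.edge_from[e] - 1];
          dlik[e] = acc;
        }
      }
    } else {
      lik = prow[s1];
      if (grad) for (int e = 0; e < E; ++e) dlik[e] = drow[e * S + s1];
    }
    if (!(lik > 0.0) || !std::isfinite(lik)) return R_NegInf;
    ll += std::log(lik);
    if (grad) {
      for (int e = 0; e < E; ++e) {
        double dl = dlik[e] / lik * qe[e];  // chain rule through exp()
        grad[e] += dl;
        for (int c = 0; c < C; ++c)
          grad[E + e * C + c] += dl * d.X[c * d.nsub + i];
      }
    }
  }
  return ll;
}

static PanelData make_data(IntegerVector& edge_from, IntegerVector& edge_to,
                           int n_state, IntegerVector& state,
                           NumericVector& time, IntegerVector& exact,
                           IntegerVector& offsets, NumericMatrix& X) {
  PanelData d;
  d.E = edge_from.size();
  d.C = X.ncol();
  d.S = n_state;
  d.nsub = offsets.size() - 1;
  d.edge_from = edge_from.begin();
  d.edge_to = edge_to.begin();
  d.state = state.begin();
  d.exact = exact.begin();
  d.offsets = offsets.begin();
  d.time = time.begin();
  d.X = X.begin();
  return d;
}

// [[Rcpp::export]]
double cpp_panel_loglik(NumericVector par, IntegerVector edge_from,
                        IntegerVector edge_to, int n_state,
                        IntegerVector state, NumericVector time,
                        IntegerVector exact, IntegerVector offsets,
                        NumericMatrix X) {
  PanelData d = make_data(edge_from, edge_to, n_state, state, time, exact,
                          offsets, X);
  double ll = 0.0;
  for (int i = 0; i < d.nsub; ++i) {
    double li = subject_loglik_grad(d, i, par.begin(), nullptr);
    if (!std::isfinite(li)) return R_NegInf;
    ll += li;
  }
  return ll;
}

// [[Rcpp::export]]
List cpp_panel_loglik_grad(NumericVector par, IntegerVector edge_from,
                           IntegerVector edge_to, int n_state,
                           IntegerVector state, NumericVector time,
                           IntegerVector exact, IntegerVector offsets,
                           NumericMatrix X) {
  PanelData d = make_data(edge_from, edge_to, n_state, state, time, exact,
                          offsets, X);
  NumericVector grad(par.size());
  double ll = 0.0;
  bool ok = true;
  for (int i = 0; i < d.nsub && ok; ++i) {
    double li = subject_loglik_grad(d, i, par.begin(), grad.begin());
    if (!std::isfinite(li)) ok = false; else ll += li;
  }
  if (!ok) {
    std::fill(grad.begin(), grad.end(), NA_REAL);
    return List::create(Named("loglik") = R_NegInf,
                        Named("gradient") = grad);
  }
  return List::create(Named("loglik") = ll, Named("gradient") = grad);
}

// Per-interval log-likelihood contributions (diagnostics): aligned with the
// second observation of each pair; -Inf marks an infeasible observed pair.
// [[Rcpp::export]]
NumericVector cpp_panel_loglik_by_interval(NumericVector par,
                                           IntegerVector edge_from,
                                           IntegerVector edge_to, int n_state,
                                           IntegerVector state,
                                           NumericVector time,
                                           IntegerVector exact,
                                           IntegerVector offsets,
                                           NumericMatrix X) {
  PanelData d = make_data(edge_from, edge_to, n_state, state, time, exact,
                          offsets, X);
  const int E = d.E, C = d.C, S = d.S;
  NumericVector out(state.size(), NA_REAL);
  std::vector<double> Q(S * S), qdeath(S), prow(S);
  for (int i = 0; i < d.nsub; ++i) {
    std::fill(Q.begin(), Q.end(), 0.0);
    std::fill(qdeath.begin(), qdeath.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      double lq = par[e];
      for (int c = 0; c < C; ++c)
        lq += par[E + e * C + c] * d.X[c * d.nsub + i];
      double q = std::exp(std::min(lq, LOGQ_CAP));
      int f = d.edge_from[e] - 1, t = d.edge_to[e] - 1;
      Q[f * S + t] += q;
      Q[f * S + f] -= q;
      if (t == S - 1) qdeath[f] = q;
    }
    for (int j = d.offsets[i]; j < d.offsets[i + 1] - 1; ++j) {
      int s0 = d.state[j] - 1, s1 = d.state[j + 1] - 1;
      double dt = d.time[j + 1] - d.time[j];
      row_expm_grad(Q, S, dt, s0, E, d.edge_from, d.edge_to, prow.data(),
                    nullptr);
      double lik;
      if (d.exact[j + 1] && s1 == S - 1) {
        lik = 0.0;
        for (int s = 0; s < S - 1; ++s)
          if (qdeath[s] > 0.0) lik += prow[s] * qdeath[s];
      } else {
        lik = prow[s1];
      }
      out[j + 1] = (lik > 0.0) ? std::log(lik) : R_NegInf;
    }
  }
  return out;
}
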