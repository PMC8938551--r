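// Continuous-time HMM kernels for irregularly sampled binary antibody panels.
//
// The latent state follows a Markov jump process with rate matrix Q; visits at
// ages a_1 < ... < a_V contribute Bernoulli emission likelihoods. Transition
// kernels over a gap dt are exp(Q dt). Endpoint-conditioned expected dwell
// times and jump counts (the E-step sufficient statistics) are computed from
// the spectral decomposition of Q: with Q = U diag(d) U^-1,
//   int_0^t P(s)_{ik} P(t-s)_{lj} ds = sum_{a,b} U_ia V_ak U_lb V_bj J_ab(t),
//   J_ab(t) = (e^{d_a t} - e^{d_b t}) / (d_a - d_b),  V = U^-1,
// so for a matrix of endpoint weights W the whole statistic reduces to
//   G = V' [ (U' W V') o J ] U'   (plain transposes, complex arithmetic),
// with expected dwell_k = Re G_kk and expected jumps q_kl Re G_kl.
// Defective rate matrices fall back to the augmented-matrix-exponential
// construction: the upper-right block of exp([[Q, E_kl],[0, Q]] t) is
// int_0^t e^{Qs} E_kl e^{Q(t-s)} ds.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct RateEig {
  cx_vec d;
  cx_mat U, V;
  bool ok;
};

RateEig decompose_rate(const mat& Q) {
  RateEig e;
  e.ok = false;
  cx_vec d;
  cx_mat U;
  if (eig_gen(d, U, Q)) {
    // the E-step integrals amplify eigenvector error roughly by the
    // squared condition number, so demand comfortable conditioning
    // (1e-16 / rcond^2 <= 1e-6 requires rcond >= ~1e-5)
    double rc = rcond(U);
    if (std::isfinite(rc) && rc > 1e-5) {
      e.d = d;
      e.U = U;
      e.V = inv(U);
      e.ok = true;
    }
  }
  return e;
}

// Robust decomposition for the high-throughput E-step path: when Q is
// defective (or numerically close), apply a deterministic relative jitter
// of ~1e-9 to the off-diagonal rates to split coincident eigenvalues.
// The perturbation changes expectations at the same order and EM
// self-corrects; the exact augmented-exponential fallback remains for the
// exported small-matrix endpoint statistics.
RateEig decompose_rate_jittered(mat& Q) {
  RateEig e = decompose_rate(Q);
  double eps = 1e-9;
  int tries = 0;
  const uword S = Q.n_rows;
  while (!e.ok && tries < 2) {
    for (uword i = 0; i < S; ++i) {
      for (uword j = 0; j < S; ++j) {
        if (i != j && Q(i, j) > 0.0) {
          const double u = static_cast<double>((7 * i + 13 * j) % 17) - 8.0;
          Q(i, j) *= 1.0 + eps * u;
        }
      }
    }
    for (uword i = 0; i < S; ++i) {
      Q(i, i) = 0.0;
      Q(i, i) = -accu(Q.row(i));
    }
    e = decompose_rate(Q);
    eps *= 100.0;
    ++tries;
  }
  return e;
}

mat transmat_eig(const mat& Q, double dt, const RateEig& e) {
  mat P;
  if (dt == 0.0) {
    P.eye(Q.n_rows, Q.n_cols);
    return P;
  }
  if (e.ok) {
    P = real(e.U * diagmat(exp(e.d * dt)) * e.V);
  } else {
    P = expmat(Q * dt);
  }
  P.for_each([](double& x) { if (x < 0.0) x = 0.0; });
  vec rs = sum(P, 1);
  for (uword i = 0; i < P.n_rows; ++i)
    if (rs(i) > 0.0) P.row(i) /= rs(i);
  return P;
}

// per-visit emission likelihood vector over states; obs coded 1/0/-1
// (missing); temper < 1 flattens the emission terms (deterministic
// annealing)
vec emis_lik(const mat& E, const imat& obs, uword v, double temper = 1.0) {
  const uword S = E.n_rows;
  vec b(S, fill::ones);
  for (uword m = 0; m < E.n_cols; ++m) {
    const int o = obs(v, m);
    if (o < 0) continue;
    for (uword s = 0; s < S; ++s)
      b(s) *= (o == 1) ? E(s, m) : (1.0 - E(s, m));
  }
  if (temper != 1.0)
    for (uword s = 0; s < S; ++s) b(s) = std::pow(b(s), temper);
  return b;
}

// J_ab(t) matrix of eigenvalue-pair integrals
cx_mat pair_integrals(const cx_vec& d, double t) {
  const uword S = d.n_elem;
  cx_mat J(S, S);
  for (uword a = 0; a < S; ++a) {
    for (uword b = 0; b < S; ++b) {
      const cx_double diff = d(a) - d(b);
      if (std::abs(diff) < 1e-8) {
        J(a, b) = t * std::exp(0.5 * (d(a) + d(b)) * t);
      } else {
        J(a, b) = (std::exp(d(a) * t) - std::exp(d(b) * t)) / diff;
      }
    }
  }
  return J;
}

// int_0^t P(s)_{ik} P(t-s)_{lj} ds for fixed (k,l), all (i,j): augmented expm
mat aug_integral(const mat& Q, double dt, uword k, uword l) {
  const uword S = Q.n_rows;
  mat A(2 * S, 2 * S, fill::zeros);
  A.submat(0, 0, S - 1, S - 1) = Q;
  A.submat(S, S, 2 * S - 1, 2 * S - 1) = Q;
  A(k, S + l) = 1.0;
  mat M = expmat(A * dt);
  return M.submat(0, S, S - 1, 2 * S - 1);
}

struct FBResult {
  mat alpha;      // scaled forward, V x S
  mat beta;       // scaled backward, V x S
  mat B;          // emission likelihoods, V x S
  vec cvec;       // per-visit scale factors
  double loglik;
  std::vector<mat> P;  // per-interval kernels
  bool finite;
};

FBResult forward_backward_core(const mat& Q, const mat& E, const vec& init,
                               const imat& obs, const vec& gaps,
                               const RateEig& eig, double temper = 1.0) {
  const uword S = Q.n_rows;
  const uword V = obs.n_rows;
  FBResult r;
  r.alpha.set_size(V, S);
  r.beta.set_size(V, S);
  r.B.set_size(V, S);
  r.cvec.set_size(V);
  r.finite = true;
  r.P.resize(V > 1 ? V - 1 : 0);

  for (uword v = 0; v < V; ++v)
    r.B.row(v) = emis_lik(E, obs, v, temper).t();
  for (uword v = 0; v + 1 < V; ++v) r.P[v] = transmat_eig(Q, gaps(v), eig);

  rowvec a = init.t() % r.B.row(0);
  double c = accu(a);
  if (!(c > 0.0)) { r.finite = false; r.loglik = -datum::inf; return r; }
  r.cvec(0) = c;
  r.alpha.row(0) = a / c;
  for (uword v = 1; v < V; ++v) {
    a = (r.alpha.row(v - 1) * r.P[v - 1]) % r.B.row(v);
    c = accu(a);
    if (!(c > 0.0)) { r.finite = false; r.loglik = -datum::inf; return r; }
    r.cvec(v) = c;
    r.alpha.row(v) = a / c;
  }
  r.loglik = accu(log(r.cvec));

  r.beta.row(V - 1).ones();
  for (uword v = V - 1; v-- > 0;) {
    rowvec bb = (r.B.row(v + 1) % r.beta.row(v + 1));
    r.beta.row(v) = (r.P[v] * bb.t()).t() / r.cvec(v + 1);
  }
  return r;
}

// endpoint weight matrix for interval v: xi_ij / P_ij. Pairs carrying
// negligible posterior mass (xi below 1e-14) are dropped: their true
// contribution is bounded by xi * dt, while their weights can reach
// astronomical magnitudes when P_ij underflows and would poison the
// conditioned integrals through cancellation.
mat endpoint_weights(const FBResult& fb, uword v) {
  const uword S = fb.alpha.n_cols;
  mat W(S, S, fill::zeros);
  const mat& P = fb.P[v];
  for (uword i = 0; i < S; ++i) {
    const double ai = fb.alpha(v, i);
    if (ai <= 0.0) continue;
    for (uword j = 0; j < S; ++j) {
      if (P(i, j) <= 0.0) continue;
      const double w =
          ai * fb.B(v + 1, j) * fb.beta(v + 1, j) / fb.cvec(v + 1);
      if (w * P(i, j) >= 1e-14) W(i, j) = w;
    }
  }
  return W;
}

// Exact fallback for the E-step when Q is not comfortably
// diagonalizable: the weighted integral
//   G = int_0^t exp(Q' s) W exp(Q' (t-s)) ds   (plain transposes)
// is the upper-right block of exp([[Q', W], [0, Q']] t) — one 2S x 2S
// matrix exponential per interval, robust to stiff rate matrices.
void accumulate_interval_aug(const mat& Q, double dt, const mat& W,
                             vec& dwell, mat& jumps) {
  const uword S = Q.n_rows;
  mat A(2 * S, 2 * S, fill::zeros);
  A.submat(0, 0, S - 1, S - 1) = Q.t();
  A.submat(S, S, 2 * S - 1, 2 * S - 1) = Q.t();
  A.submat(0, S, S - 1, 2 * S - 1) = W;
  mat EA = expmat(A * dt);
  mat G = EA.submat(0, S, S - 1, 2 * S - 1);
  for (uword k = 0; k < S; ++k) {
    dwell(k) += std::max(G(k, k), 0.0);
    for (uword l = 0; l < S; ++l) {
      if (l == k || Q(k, l) <= 0.0) continue;
      if (G(k, l) > 0.0) jumps(k, l) += Q(k, l) * G(k, l);
    }
  }
}

// accumulate expected dwell and jumps for one interval given endpoint weights
void accumulate_interval(const mat& Q, double dt, const RateEig& eig,
                         const mat& W, vec& dwell, mat& jumps) {
  const uword S = Q.n_rows;
  if (eig.ok) {
    cx_mat Wc(W, mat(S, S, fill::zeros));
    cx_mat C = eig.U.st() * Wc * eig.V.st();
    cx_mat G = eig.V.st() * (C % pair_integrals(eig.d, dt)) * eig.U.st();
    for (uword k = 0; k < S; ++k) {
      double dk = std::real(G(k, k));
      dwell(k) += std::max(dk, 0.0);
      for (uword l = 0; l < S; ++l) {
        if (l == k || Q(k, l) <= 0.0) continue;
        double g = std::real(G(k, l));
        if (g > 0.0) jumps(k, l) += Q(k, l) * g;
      }
    }
  } else {
    for (uword k = 0; k < S; ++k) {
      for (uword l = 0; l < S; ++l) {
        if (l != k && Q(k, l) <= 0.0) continue;
        mat M = aug_integral(Q, dt, k, l);
        double val = accu(W % M);
        if (l == k) dwell(k) += std::max(val, 0.0);
        else if (val > 0.0) jumps(k, l) += Q(k, l) * val;
      }
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".cpp_transmat")]]
arma::mat cpp_transmat(const arma::mat& Q, double dt) {
  RateEig eig = decompose_rate(Q);
  return transmat_eig(Q, dt, eig);
}

// [[Rcpp::export(name = ".cpp_forward_backward")]]
Rcpp::List cpp_forward_backward(const arma::mat& Q, const arma::mat& E,
                                const arma::vec& init, const arma::imat& obs,
                                const arma::vec& gaps) {
  RateEig eig = decompose_rate(Q);
  FBResult fb = forward_backward_core(Q, E, init, obs, gaps, eig);
  const uword V = obs.n_rows, S = Q.n_rows;
  if (!fb.finite) {
    return List::create(_["loglik"] = R_NegInf, _["gamma"] = R_NilValue,
                        _["xi"] = R_NilValue);
  }
  mat gamma = fb.alpha % fb.beta;
  // renormalize rows against numerical drift
  for (uword v = 0; v < V; ++v) {
    double s = accu(gamma.row(v));
    if (s > 0.0) gamma.row(v) /= s;
  }
  cube xi(S, S, V > 1 ? V - 1 : 0);
  for (uword v = 0; v + 1 < V; ++v) xi.slice(v) = endpoint_weights(fb, v) % fb.P[v];
  return List::create(_["loglik"] = fb.loglik, _["gamma"] = gamma, _["xi"] = xi);
}

// [[Rcpp::export(name = ".cpp_endpoint_stats")]]
Rcpp::List cpp_endpoint_stats(const arma::mat& Q, double dt, int start, int end) {
  const uword S = Q.n_rows;
  RateEig eig = decompose_rate(Q);
  mat P = transmat_eig(Q, dt, eig);
  const double pij = P(start, end);
  if (!(pij > 0.0))
    stop("endpoint pair has zero transition probability over the interval");
  mat W(S, S, fill::zeros);
  W(start, end) = 1.0 / pij;
  vec dwell(S, fill::zeros);
  mat jumps(S, S, fill::zeros);
  accumulate_interval(Q, dt, eig, W, dwell, jumps);
  return List::create(_["dwell"] = dwell, _["jumps"] = jumps);
}

// Full E-step over a cohort. obs_list: list of integer matrices (V x 3,
// coded 1/0/-1), gaps_list: list of numeric vectors (length V-1).
// [[Rcpp::export(name = ".cpp_estep")]]
Rcpp::List cpp_estep(const arma::mat& Q_in, const arma::mat& E,
                     const arma::vec& init, Rcpp::List obs_list,
                     Rcpp::List gaps_list, double temper = 1.0) {
  mat Q = Q_in;
  const uword S = Q.n_rows;
  const uword M = E.n_cols;
  RateEig eig = decompose_rate_jittered(Q);
  vec dwell(S, fill::zeros), initw(S, fill::zeros);
  mat jumps(S, S, fill::zeros);
  mat epos(S, M, fill::zeros), eobs(S, M, fill::zeros);
  const int n = obs_list.size();
  vec logliks(n);
  for (int p = 0; p < n; ++p) {
    imat obs = as<imat>(obs_list[p]);
    vec gaps = as<vec>(gaps_list[p]);
    FBResult fb = forward_backward_core(Q, E, init, obs, gaps, eig, temper);
    logliks(p) = fb.loglik;
    if (!fb.finite) continue;
    const uword V = obs.n_rows;
    mat gamma = fb.alpha % fb.beta;
    for (uword v = 0; v < V; ++v) {
      double s = accu(gamma.row(v));
      if (s > 0.0) gamma.row(v) /= s;
    }
    initw += gamma.row(0).t();
    for (uword v = 0; v < V; ++v) {
      for (uword m = 0; m < M; ++m) {
        const int o = obs(v, m);
        if (o < 0) continue;
        for (uword s = 0; s < S; ++s) {
          eobs(s, m) += gamma(v, s);
          if (o == 1) epos(s, m) += gamma(v, s);
        }
      }
    }
    for (uword v = 0; v + 1 < V; ++v) {
      mat W = endpoint_weights(fb, v);
      if (eig.ok) accumulate_interval(Q, gaps(v), eig, W, dwell, jumps);
      else accumulate_interval_aug(Q, gaps(v), W, dwell, jumps);
    }
  }
  return List::create(_["dwell"] = dwell, _["jumps"] = jumps,
                      _["emission_pos_weight"] = epos,
                      _["emission_obs_weight"] = eobs,
                      _["initial_weight"] = initw,
                      _["logliks"] = logliks,
                      _["total_loglik"] = accu(logliks));
}

// Forward log-likelihood only (per series), for held-out scoring.
// [[Rcpp::export(name = ".cpp_loglik")]]
arma::vec cpp_loglik(const arma::mat& Q, const arma::mat& E,
                     const arma::vec& init, Rcpp::List obs_list,
                     Rcpp::List gaps_list) {
  RateEig eig = decompose_rate(Q);
  const int n = obs_list.size();
  vec out(n);
  for (int p = 0; p < n; ++p) {
    imat obs = as<imat>(obs_list[p]);
    vec gaps = as<vec>(gaps_list[p]);
    const uword V = obs.n_rows;
    rowvec a = init.t() % emis_lik(E, obs, 0).t();
    double c = accu(a);
    if (!(c > 0.0)) { out(p) = -datum::inf; continue; }
    double ll = std::log(c);
    a /= c;
    bool fin = true;
    for (uword v = 1; v < V; ++v) {
      mat P = transmat_eig(Q, gaps(v - 1), eig);
      a = (a * P) % emis_lik(E, obs, v).t();
      c = accu(a);
      if (!(c > 0.0)) { fin = false; break; }
      ll += std::log(c);
      a /= c;
    }
    out(p) = fin ? ll : -datum::inf;
  }
  return out;
}

// Viterbi decoding; ties broken toward the lower state index.
// [[Rcpp::export(name = ".cpp_viterbi")]]
Rcpp::IntegerVector cpp_viterbi(const arma::mat& Q, const arma::mat& E,
                                const arma::vec& init, const arma::imat& obs,
                                const arma::vec& gaps) {
  const uword S = Q.n_rows;
  const uword V = obs.n_rows;
  RateEig eig = decompose_rate(Q);
  mat delta(V, S);
  umat psi(V, S, fill::zeros);
  for (uword s = 0; s < S; ++s) {
    double b = emis_lik(E, obs, 0)(s);
    delta(0, s) = (init(s) > 0.0 && b > 0.0) ? std::log(init(s)) + std::log(b)
                                             : -datum::inf;
  }
  for (uword v = 1; v < V; ++v) {
    mat lP = transmat_eig(Q, gaps(v - 1), eig);
    lP.transform([](double x) { return x > 0.0 ? std::log(x) : -datum::inf; });
    vec b = emis_lik(E, obs, v);
    for (uword s = 0; s < S; ++s) {
      double best = -datum::inf;
      uword arg = 0;
      for (uword k = 0; k < S; ++k) {
        const double cand = delta(v - 1, k) + lP(k, s);
        if (cand > best) { best = cand; arg = k; }
      }
      delta(v, s) = best + (b(s) > 0.0 ? std::log(b(s)) : -datum::inf);
      psi(v, s) = arg;
    }
  }
  IntegerVector path(V);
  uword last = 0;
  double best = -datum::inf;
  for (uword s = 0; s < S; ++s)
    if (delta(V - 1, s) > best) { best = delta(V - 1, s); last = s; }
  path[V - 1] = static_cast<int>(last);
  for (uword v = V - 1; v-- > 0;) {
    last = psi(v + 1, last);
    path[v] = static_cast<int>(last);
  }
  return path;
}
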