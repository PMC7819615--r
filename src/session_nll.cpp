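// Per-session likelihood of the judgement-bias POMDP.
//
// The backward (Bellman) and forward (remain-probability) recursions run
// per trial; the bias delta is composed from the experience state.  When
// the bias includes weighted-prediction-error terms, delta depends on the
// start-state values V00 of earlier trials and the session is inherently
// sequential.  Otherwise delta depends only on the realised outcomes, all
// deltas are known upfront, and both recursions batch across trials into
// level-3 BLAS products (one multiply per time bin for the whole session).
// Model tables (belief-averaged subjective kernels M_t, true-stimulus
// kernels, posterior P(mu=+1|t,X), hazard) are precomputed in R per
// (sigma, zeta, phi).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double sigmoid(double z) {
  if (z >= 0.0) return 1.0 / (1.0 + std::exp(-z));
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Backward induction for one trial: fills pi (S x T) and returns V00.
// Decisions at t = 0..T-1; all mass at t = T times out by fiat.
static double trial_policy(const arma::cube& M, const arma::mat& P1,
                           const arma::vec& hazard, double R, double L,
                           double drive, double lam, double B,
                           arma::mat& pi_out) {
  const arma::uword S = P1.n_cols;
  const arma::uword T = M.n_slices;
  arma::vec Vnext(S), q(S);
  for (arma::uword x = 0; x < S; ++x)
    Vnext(x) = R * P1(T, x) + L * (1.0 - P1(T, x));
  double q_center0 = 0.0, pi_center0 = 0.0;
  for (arma::uword tt = T; tt-- > 0;) {
    double h = hazard(tt);
    q = (1.0 - h) * (M.slice(tt) * Vnext);
    for (arma::uword x = 0; x < S; ++x) {
      double vt = R * P1(tt, x) + L * (1.0 - P1(tt, x));
      double qx = q(x) + h * vt;
      double p = 0.5 * lam + (1.0 - lam) * sigmoid(B * (qx + drive));
      pi_out(x, tt) = p;
      Vnext(x) = p * qx;
      if (tt == 0 && x == (S - 1) / 2) { q_center0 = qx; pi_center0 = p; }
    }
  }
  return pi_center0 * q_center0;  // V00 = pi * Q(STAY) at (0, 0)
}

// Forward recursion for one trial under the true kernel.
// Returns the observation probability; optionally fills full distributions.
static double trial_forward(const arma::mat& Kt, const arma::mat& pi,
                            const arma::vec& hazard, bool is_stay, int rbin,
                            bool want_dists, arma::vec* prel_out,
                            double* pto_out) {
  const arma::uword S = pi.n_rows;
  const arma::uword T = pi.n_cols;
  const arma::uword center = (S - 1) / 2;
  arma::vec p(S, arma::fill::zeros), staying(S);
  p(center) = 1.0;
  double pto = 0.0, pobs = 0.0;
  arma::uword tstop = (is_stay || want_dists) ? T : (arma::uword)rbin + 1;
  for (arma::uword tt = 0; tt < tstop; ++tt) {
    double rel = 0.0;
    for (arma::uword x = 0; x < S; ++x) rel += p(x) * (1.0 - pi(x, tt));
    if (want_dists) (*prel_out)(tt) = rel;
    if (!is_stay && (arma::uword)rbin == tt) { pobs = rel; if (!want_dists) break; }
    staying = p % pi.col(tt);
    pto += hazard(tt) * arma::accu(staying);
    if (tt + 1 < T) p = Kt.t() * (staying * (1.0 - hazard(tt)));
    else p = staying * (1.0 - hazard(tt));  // survivors of the last decision
  }
  if (is_stay || want_dists) pto += arma::accu(p);  // forced timeout at T
  if (is_stay) pobs = pto;
  if (want_dists) *pto_out = pto;
  return pobs;
}

// [[Rcpp::export]]
List cpp_session_eval(const arma::cube& M, const arma::cube& kernels,
                      const arma::mat& P1, const arma::vec& hazard,
                      const NumericVector& Rv, const NumericVector& Lv,
                      const IntegerVector& nidx, const IntegerVector& kid,
                      const NumericVector& lam, const IntegerVector& stay,
                      const IntegerVector& rbin, const NumericVector& O,
                      double B, double beta0, double betaR, double betaPE,
                      double betaPE2, double betaO, double betan,
                      double alphaR, double gammaPE, bool want_dists) {
  const arma::uword S = P1.n_cols;
  const arma::uword T = M.n_slices;
  const int N = Rv.size();
  const arma::uword center = (S - 1) / 2;
  const bool sequential = (betaPE != 0.0) || (betaPE2 != 0.0);

  arma::mat trace(N, 7);  // delta, V00, PE, Rbar, wPE, wPE2, O
  NumericVector p_obs(N);
  arma::mat prel_all;
  arma::vec pto_all;
  if (want_dists) { prel_all.zeros(T, N); pto_all.zeros(N); }
  double nll = 0.0;

  if (sequential) {
    arma::mat pi(S, T);
    double Rbar = 0.0, wpe = 0.0, wpe2 = 0.0, Oprev = 0.0;
    double s1 = 0.0, s2 = 0.0, wsum = 0.0;
    arma::vec prel_i(T);
    for (int i = 0; i < N; ++i) {
      double delta = beta0 + betaR * Rbar + betaPE * wpe + betaPE2 * wpe2 +
                     betaO * Oprev;
      double drive = delta - (double)nidx[i] * betan;
      double V00 = trial_policy(M, P1, hazard, Rv[i], Lv[i], drive, lam[i], B, pi);
      double pto = 0.0;
      double pobs = trial_forward(kernels.slice(kid[i] - 1), pi, hazard,
                                  stay[i] == 1, rbin[i], want_dists,
                                  &prel_i, &pto);
      if (want_dists) { prel_all.col(i) = prel_i; pto_all(i) = pto; }
      if (pobs < 1e-300) pobs = 1e-300;
      nll -= std::log(pobs);
      p_obs[i] = pobs;
      double pe = O[i] - V00;
      s1 = gammaPE * s1 + pe; s2 = gammaPE * s2 + pe * pe;
      wsum = gammaPE * wsum + 1.0;
      wpe = s1 / wsum; wpe2 = s2 / wsum;
      Rbar += alphaR * (O[i] - Rbar);
      trace(i, 0) = delta; trace(i, 1) = V00; trace(i, 2) = pe;
      trace(i, 3) = Rbar;  trace(i, 4) = wpe; trace(i, 5) = wpe2;
      trace(i, 6) = O[i];
      Oprev = O[i];
    }
  } else {
    // deltas depend only on outcomes: compute upfront, batch the recursions
    arma::vec drive(N);
    {
      double Rbar = 0.0, Oprev = 0.0;
      for (int i = 0; i < N; ++i) {
        double delta = beta0 + betaR * Rbar + betaO * Oprev;
        drive(i) = delta - (double)nidx[i] * betan;
        trace(i, 0) = delta;
        Rbar += alphaR * (O[i] - Rbar);
        Oprev = O[i];
      }
    }
    // batched backward induction: V is S x N, one BLAS-3 product per bin
    arma::cube Pi(S, N, T);
    arma::mat V(S, N), W(S, N);
    for (int i = 0; i < N; ++i)
      for (arma::uword x = 0; x < S; ++x)
        V(x, i) = Rv[i] * P1(T, x) + Lv[i] * (1.0 - P1(T, x));
    for (arma::uword tt = T; tt-- > 0;) {
      double h = hazard(tt);
      W = M.slice(tt) * V;
      arma::mat& Pit = Pi.slice(tt);
      for (int i = 0; i < N; ++i) {
        double Ri = Rv[i], Li = Lv[i], lm = lam[i], dr = drive(i);
        for (arma::uword x = 0; x < S; ++x) {
          double vt = Ri * P1(tt, x) + Li * (1.0 - P1(tt, x));
          double qx = (1.0 - h) * W(x, i) + h * vt;
          double p = 0.5 * lm + (1.0 - lm) * sigmoid(B * (qx + dr));
          Pit(x, i) = p;
          V(x, i) = p * qx;
          if (tt == 0 && x == center) trace(i, 1) = p * qx;  // V00
        }
      }
    }
    // batched forward recursion, grouped by true-stimulus kernel
    arma::vec pto(N, arma::fill::zeros);
    arma::mat rel(T, N, arma::fill::zeros);
    const int nk = kernels.n_slices;
    for (int g = 0; g < nk; ++g) {
      std::vector<arma::uword> idx;
      for (int i = 0; i < N; ++i) if (kid[i] - 1 == g) idx.push_back(i);
      if (idx.empty()) continue;
      const arma::uword ng = idx.size();
      arma::mat P(S, ng, arma::fill::zeros), staying(S, ng);
      for (arma::uword j = 0; j < ng; ++j) P(center, j) = 1.0;
      const arma::mat Kt = kernels.slice(g).t();
      for (arma::uword tt = 0; tt < T; ++tt) {
        double h = hazard(tt);
        for (arma::uword j = 0; j < ng; ++j) {
          const arma::uword i = idx[j];
          double r = 0.0, st = 0.0;
          for (arma::uword x = 0; x < S; ++x) {
            double pix = Pi(x, i, tt);
            double sx = P(x, j) * pix;
            r += P(x, j) - sx;
            st += sx;
            staying(x, j) = sx;
          }
          rel(tt, i) = r;
          pto(i) += h * st;
        }
        if (tt + 1 < T) P = Kt * (staying * (1.0 - h));
        else P = staying * (1.0 - h);
      }
      for (arma::uword j = 0; j < ng; ++j)
        pto(idx[j]) += arma::accu(P.col(j));  // forced timeout at T
    }
    // observation probabilities and experience trace
    double wpe = 0.0, wpe2 = 0.0, s1 = 0.0, s2 = 0.0, wsum = 0.0, Rbar = 0.0;
    for (int i = 0; i < N; ++i) {
      double pobs = (stay[i] == 1) ? pto(i) : rel(rbin[i], i);
      if (pobs < 1e-300) pobs = 1e-300;
      nll -= std::log(pobs);
      p_obs[i] = pobs;
      double pe = O[i] - trace(i, 1);
      s1 = gammaPE * s1 + pe; s2 = gammaPE * s2 + pe * pe;
      wsum = gammaPE * wsum + 1.0;
      wpe = s1 / wsum; wpe2 = s2 / wsum;
      Rbar += alphaR * (O[i] - Rbar);
      trace(i, 2) = pe; trace(i, 3) = Rbar; trace(i, 4) = wpe;
      trace(i, 5) = wpe2; trace(i, 6) = O[i];
    }
    if (want_dists) { prel_all = rel; pto_all = pto; }
  }

  List out = List::create(_["nll"] = nll, _["trace"] = trace,
                          _["p_obs"] = p_obs);
  if (want_dists) {
    out["p_release"] = prel_all;
    out["p_timeout"] = pto_all;
  }
  return out;
}

// Belief-average the evidence kernels: M_t(x, .) = sum_k W(x, k, t) K(x, ., k)
// [[Rcpp::export]]
arma::cube cpp_mix_kernels(const arma::cube& kernels, const arma::cube& W,
                           int T) {
  const arma::uword S = kernels.n_rows;
  const arma::uword nk = kernels.n_slices;
  arma::cube M(S, S, T, arma::fill::zeros);
  for (int tt = 0; tt < T; ++tt)
    for (arma::uword k = 0; k < nk; ++k)
      for (arma::uword j = 0; j < S; ++j)
        for (arma::uword x = 0; x < S; ++x)
          M(x, j, tt) += W(x, k, tt) * kernels(x, j, k);
  return M;
}
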