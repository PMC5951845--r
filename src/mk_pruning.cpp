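// Core pruning machinery for k-state Markov models of discrete characters.
// Trees arrive as postorder edge matrices (ape convention, 1-based node ids:
// tips 1..Ntip, root Ntip+1). Tip observations are k x Ntip indicator
// matrices: a polymorphic tip has a 1 on each observed state, a missing tip
// is all ones.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-edge transition matrices P(t) = expm(Q t). One eigendecomposition of Q
// serves all edges; if Q is defective (reconstruction fails) fall back to
// scaling-and-squaring per edge.
static void edge_pmats(const mat& Q, const vec& elen, std::vector<mat>& P) {
  const uword k = Q.n_rows, ne = elen.n_elem;
  P.resize(ne);
  cx_vec eval;
  cx_mat evec;
  bool ok = eig_gen(eval, evec, Q);
  cx_mat evinv;
  if (ok) ok = inv(evinv, evec);
  if (ok) {
    mat recon = real(evec * diagmat(eval) * evinv);
    if (norm(recon - Q, "inf") > 1e-8 * (1.0 + norm(Q, "inf"))) ok = false;
  }
  for (uword e = 0; e < ne; ++e) {
    mat Pe;
    if (ok) {
      Pe = real(evec * diagmat(exp(eval * elen(e))) * evinv);
    } else {
      Pe = expmat(Q * elen(e));
    }
    Pe.clamp(0.0, 1.0);
    P[e] = Pe;
  }
  (void)k;
}

// Equal-rates closed form: message to the parent for a child partial vector.
// P_same(t) = 1/k + (k-1)/k e^{-kqt}, P_diff(t) = (1 - e^{-kqt})/k.
static inline vec er_message(const vec& child, double q, double t, double k) {
  const double et = std::exp(-k * q * t);
  const double pdiff = (1.0 - et) / k;
  // v_i = psame*c_i + pdiff*(S - c_i) = pdiff*S + e^{-kqt} * c_i
  return pdiff * accu(child) + et * child;
}

// [[Rcpp::export]]
double C_mk_loglik(const arma::imat& edge, const arma::vec& elen,
                   const arma::mat& tipL, const int n_node,
                   const arma::mat& Q, const arma::vec& root_prior,
                   const bool er, const double q) {
  const uword k = tipL.n_rows, ntip = tipL.n_cols, ne = edge.n_rows;
  mat L(k, (uword)n_node, fill::ones);
  L.cols(0, ntip - 1) = tipL;
  std::vector<mat> P;
  if (!er) edge_pmats(Q, elen, P);
  double logscale = 0.0;
  for (uword e = 0; e < ne; ++e) {
    const uword par = (uword)edge(e, 0) - 1, ch = (uword)edge(e, 1) - 1;
    vec v = er ? er_message(L.col(ch), q, elen(e), (double)k)
               : vec(P[e] * L.col(ch));
    const double m = v.max();
    if (!(m > 0.0)) return -datum::inf;
    v /= m;
    logscale += std::log(m);
    L.col(par) %= v;
  }
  const uword root = (uword)edge(ne - 1, 0) - 1;
  const double lik = dot(root_prior, L.col(root));
  if (!(lik > 0.0)) return -datum::inf;
  return std::log(lik) + logscale;
}

// Marginal ancestral state probabilities at every node (up-down algorithm).
// Returns a k x n_node matrix of normalized marginals.
// [[Rcpp::export]]
arma::mat C_mk_asr(const arma::imat& edge, const arma::vec& elen,
                   const arma::mat& tipL, const int n_node,
                   const arma::mat& Q, const arma::vec& root_prior,
                   const bool er, const double q) {
  const uword k = tipL.n_rows, ntip = tipL.n_cols, ne = edge.n_rows;
  mat D(k, (uword)n_node, fill::ones);   // down (conditional) partials
  D.cols(0, ntip - 1) = tipL;
  std::vector<mat> P;
  if (!er) edge_pmats(Q, elen, P);
  mat msg(k, ne);                        // scaled child->parent messages
  for (uword e = 0; e < ne; ++e) {
    const uword par = (uword)edge(e, 0) - 1, ch = (uword)edge(e, 1) - 1;
    vec v = er ? er_message(D.col(ch), q, elen(e), (double)k)
               : vec(P[e] * D.col(ch));
    const double m = v.max();
    if (m > 0.0) v /= m;
    msg.col(e) = v;
    D.col(par) %= v;
  }
  const uword root = (uword)edge(ne - 1, 0) - 1;
  mat U(k, (uword)n_node, fill::zeros);  // upward (outside-subtree) partials
  U.col(root) = root_prior;
  // reverse postorder = preorder over edges
  for (uword ei = ne; ei-- > 0;) {
    const uword par = (uword)edge(ei, 0) - 1, ch = (uword)edge(ei, 1) - 1;
    // parent context excluding this child's message
    vec excl = U.col(par) % (D.col(par) / clamp(msg.col(ei), 1e-300, datum::inf));
    vec u(k);
    if (er) {
      const double et = std::exp(-k * q * elen(ei));
      const double pdiff = (1.0 - et) / k;
      u = pdiff * accu(excl) + et * excl;  // ER is symmetric: P^T = P
    } else {
      u = P[ei].t() * excl;
    }
    const double m = u.max();
    if (m > 0.0) u /= m;
    U.col(ch) = u;
  }
  mat marg(k, (uword)n_node);
  for (uword nd = 0; nd < (uword)n_node; ++nd) {
    vec w = U.col(nd) % D.col(nd);
    const double s = accu(w);
    marg.col(nd) = (s > 0.0) ? vec(w / s) : vec(k, fill::value(1.0 / k));
  }
  return marg;
}

// [[Rcpp::export]]
arma::mat C_expm_Q(const arma::mat& Q, const double t) {
  mat P = expmat(Q * t);
  P.clamp(0.0, 1.0);
  return P;
}
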