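// Felsenstein pruning over a fixed topology for one rate category.
//
// Conventions follow ape: nodes are numbered 1..nTip for tips, the root is
// `root` (1-based), and `edge` rows are in postorder (every edge appears
// after all edges inside its child's subtree).  P is a states x states x
// nEdge cube of transition matrices, row = parent state, col = child state.
// Tip states are 1-based indices into the state alphabet; 0 marks a gap or
// ambiguity and contributes a partial of ones.
//
// Per-pattern conditional likelihoods are rescaled when their column maximum
// drops below 1e-200; accumulated log scalers are returned alongside every
// partial so callers can reconstruct exact log-likelihoods.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SCALE_THRESHOLD = 1e-200;

static void rescale_columns(arma::mat& M, arma::vec& lsc) {
  arma::rowvec mx = arma::max(M, 0);
  for (arma::uword s = 0; s < M.n_cols; ++s) {
    if (mx(s) > 0.0 && mx(s) < SCALE_THRESHOLD) {
      M.col(s) /= mx(s);
      lsc(s) += std::log(mx(s));
    }
  }
}

// [[Rcpp::export(name = ".cpp_prune")]]
List cpp_prune(const arma::imat& edge, int nTip, int nNode, int root,
               const arma::imat& tipState, const arma::cube& P,
               const arma::vec& pi, bool wantUp) {
  const int nEdge = edge.n_rows;
  const int S = P.n_rows;
  const int nPat = tipState.n_cols;

  arma::cube down(S, nPat, nNode, arma::fill::zeros);
  arma::mat lscDown(nPat, nNode, arma::fill::zeros);
  arma::cube X(S, nPat, nEdge, arma::fill::none); // P_e * down[child]
  arma::mat lscX(nPat, nEdge, arma::fill::zeros);
  std::vector<bool> seen(nNode, false);

  for (int t = 0; t < nTip; ++t) {
    arma::mat D(S, nPat, arma::fill::zeros);
    for (int s = 0; s < nPat; ++s) {
      int st = tipState(t, s);
      if (st <= 0) D.col(s).ones();
      else D(st - 1, s) = 1.0;
    }
    down.slice(t) = D;
    seen[t] = true;
  }

  for (int e = 0; e < nEdge; ++e) {
    const int par = edge(e, 0) - 1;
    const int ch = edge(e, 1) - 1;
    X.slice(e) = P.slice(e) * down.slice(ch);
    lscX.col(e) = lscDown.col(ch);
    if (!seen[par]) {
      down.slice(par) = X.slice(e);
      lscDown.col(par) = lscX.col(e);
      seen[par] = true;
    } else {
      down.slice(par) %= X.slice(e);
      lscDown.col(par) += lscX.col(e);
    }
    arma::vec lsc = lscDown.col(par);
    arma::mat M = down.slice(par);
    rescale_columns(M, lsc);
    down.slice(par) = M;
    lscDown.col(par) = lsc;
  }

  const int r = root - 1;
  arma::vec siteLogLik(nPat);
  for (int s = 0; s < nPat; ++s) {
    double v = arma::dot(pi, down.slice(r).col(s));
    siteLogLik(s) = std::log(v) + lscDown(s, r);
  }

  List out = List::create(
    Named("siteLogLik") = siteLogLik,
    Named("down") = down,
    Named("lscDown") = lscDown);

  if (wantUp) {
    arma::cube A(S, nPat, nEdge, arma::fill::none);
    arma::mat lscA(nPat, nEdge, arma::fill::zeros);
    arma::cube upnode(S, nPat, nNode, arma::fill::zeros);
    arma::mat lscUp(nPat, nNode, arma::fill::zeros);

    upnode.slice(r) = arma::repmat(pi, 1, nPat);

    std::vector<std::vector<int>> kids(nNode);
    for (int e = 0; e < nEdge; ++e) kids[edge(e, 0) - 1].push_back(e);

    for (int e = nEdge - 1; e >= 0; --e) { // reverse postorder = preorder
      const int par = edge(e, 0) - 1;
      const int ch = edge(e, 1) - 1;
      arma::mat Ae = upnode.slice(par);
      arma::vec lsc = lscUp.col(par);
      for (int f : kids[par]) {
        if (f == e) continue;
        Ae %= X.slice(f);
        lsc += lscX.col(f);
      }
      rescale_columns(Ae, lsc);
      A.slice(e) = Ae;
      lscA.col(e) = lsc;
      upnode.slice(ch) = P.slice(e).t() * Ae;
      lscUp.col(ch) = lsc;
    }
    out["A"] = A;
    out["lscA"] = lscA;
    out["upnode"] = upnode;
    out["lscUp"] = lscUp;
  }
  return out;
}

// Per-pattern likelihood contribution of a single edge given the partials on
// both of its sides: v(s) = sum_ij A_i(s) P_ij D_j(s).  Used by the 1-D
// branch-length optimizer, so it must be cheap.
// [[Rcpp::export(name = ".cpp_edge_lik")]]
arma::vec cpp_edge_lik(const arma::mat& A, const arma::mat& D,
                       const arma::mat& P) {
  return arma::sum(A % (P * D), 0).t();
}
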