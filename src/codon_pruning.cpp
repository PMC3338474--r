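// Felsenstein pruning for Goldman-Yang codon models, over several omega
// classes and several global branch-length scalings at once. Rate matrices
// are time-reversible, so P(t) = D^{-1/2} V exp(Lambda t) V' D^{1/2} from a
// symmetric eigendecomposition, one per class, shared across branches and
// scalings.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Qlist: list of 61x61 rate matrices (already normalized as the caller
//        intends), one per site class
// pi: stationary codon frequencies (length 61)
// tipStates: ntip x npat integer matrix, 0-based codon state, -1 = missing
// edge: nedge x 2 postorder edge matrix, 1-based ape node ids
// edgeLen: branch lengths (same order as edge rows)
// root: 1-based id of the root node of the postorder traversal
// tauVec: global branch-length multipliers
// returns: cube npat x nclass x ntau of per-site likelihoods
// [[Rcpp::export]]
arma::cube site_class_lik(List Qlist, arma::vec pi, IntegerMatrix tipStates,
                          IntegerMatrix edge, arma::vec edgeLen,
                          int ntip, int nnode, int root, arma::vec tauVec) {
  const int ns = pi.n_elem;            // 61 states
  const int npat = tipStates.ncol();
  const int nclass = Qlist.size();
  const int ntau = tauVec.n_elem;
  const int nedge = edge.nrow();
  const int nNodesTotal = ntip + nnode;

  arma::cube out(npat, nclass, ntau, arma::fill::zeros);
  arma::vec sqp = arma::sqrt(pi);
  arma::mat Dl = arma::diagmat(1.0 / sqp);
  arma::mat Dr = arma::diagmat(sqp);

  for (int cl = 0; cl < nclass; ++cl) {
    arma::mat Q = as<arma::mat>(Qlist[cl]);
    arma::mat B = Dr * Q * Dl;         // symmetric for reversible Q
    B = 0.5 * (B + B.t());             // guard against roundoff asymmetry
    arma::vec eval;
    arma::mat evec;
    if (!arma::eig_sym(eval, evec, B))
      stop("eigendecomposition failed for class %d", cl + 1);
    arma::mat W = Dl * evec;           // P(t) = W diag(exp(eval t)) Wi
    arma::mat Wi = evec.t() * Dr;

    for (int tv = 0; tv < ntau; ++tv) {
      double tau = tauVec(tv);
      // per-edge transition matrices
      std::vector<arma::mat> P(nedge);
      for (int e = 0; e < nedge; ++e) {
        arma::vec ex = arma::exp(eval * (edgeLen(e) * tau));
        arma::mat M = W * arma::diagmat(ex) * Wi;
        M.elem(arma::find(M < 0)).zeros();
        P[e] = M;
      }
      // pruning
      std::vector<arma::mat> L(nNodesTotal + 1);
      std::vector<bool> seen(nNodesTotal + 1, false);
      for (int e = 0; e < nedge; ++e) {
        int par = edge(e, 0);
        int ch = edge(e, 1);
        arma::mat contrib(ns, npat);
        if (ch <= ntip) {
          for (int s = 0; s < npat; ++s) {
            int st = tipStates(ch - 1, s);
            if (st < 0)
              contrib.col(s) = arma::sum(P[e], 1); // missing: sum over states
            else
              contrib.col(s) = P[e].col(st);
          }
        } else {
          contrib = P[e] * L[ch];
        }
        if (!seen[par]) { L[par] = contrib; seen[par] = true; }
        else            { L[par] %= contrib; }
      }
      arma::rowvec lik = pi.t() * L[root];
      for (int s = 0; s < npat; ++s) out(s, cl, tv) = lik(s);
    }
  }
  return out;
}
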