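// Felsenstein pruning for k-state Mk models on rooted trees (polytomies
// allowed), plus the two-pass (down/up) computation of marginal ancestral
// state probabilities. Edges must arrive in ape "postorder" so that every
// child's partial likelihood is complete before its edge is processed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Down pass. Returns per-node partial likelihoods (scaled), per-edge
// transition matrices and scaled edge contributions, and the log-likelihood.
static void down_pass(const arma::imat &edge, const arma::vec &elen,
                      int ntip, const arma::mat &tipL, const arma::mat &Q,
                      arma::mat &D, arma::cube &P, arma::mat &C,
                      double &logscale) {
  const int nedge = edge.n_rows;
  const int k = Q.n_rows;
  logscale = 0.0;
  for (int e = 0; e < nedge; ++e) {
    const int child = edge(e, 1) - 1;  // 0-based
    const int par = edge(e, 0) - 1;
    P.slice(e) = arma::expmat(Q * elen[e]);
    arma::vec dc = D.row(child).t();
    arma::vec ce = P.slice(e) * dc;
    double s = arma::accu(ce);
    if (!(s > 0.0) || !std::isfinite(s))
      stop("non-finite partial likelihood on edge %d (branch length %g)",
           e + 1, elen[e]);
    ce /= s;
    logscale += std::log(s);
    C.row(e) = ce.t();
    D.row(par) %= ce.t();
  }
  (void)ntip; (void)k;
}

// [[Rcpp::export]]
List mk_pruning_cpp(const arma::imat &edge, const arma::vec &edge_length,
                    int ntip, const arma::mat &tipL, const arma::mat &Q,
                    const arma::vec &prior, bool fitzjohn,
                    bool marginals) {
  const int k = Q.n_rows;
  const int nnode_total = arma::max(arma::vectorise(edge));
  const int root = edge(edge.n_rows - 1, 0) - 1;  // last postorder parent

  arma::mat D(nnode_total, k, arma::fill::ones);
  D.rows(0, ntip - 1) = tipL;
  arma::cube P(k, k, edge.n_rows);
  arma::mat C(edge.n_rows, k);
  double logscale = 0.0;
  down_pass(edge, edge_length, ntip, tipL, Q, D, P, C, logscale);

  arma::vec droot = D.row(root).t();
  arma::vec pi = fitzjohn ? arma::vec(droot / arma::accu(droot)) : prior;
  double lik = arma::dot(pi, droot);
  if (!(lik > 0.0) || !std::isfinite(lik))
    stop("non-finite likelihood at root");
  double loglik = std::log(lik) + logscale;

  if (!marginals)
    return List::create(_["loglik"] = loglik);

  // child-edge index lists per node
  std::vector<std::vector<int>> kids(nnode_total);
  for (unsigned int e = 0; e < edge.n_rows; ++e)
    kids[edge(e, 0) - 1].push_back(e);

  // Up pass in preorder (reverse postorder): U(v) = likelihood of the rest
  // of the tree given the state at v, up to normalization.
  arma::mat U(nnode_total, k, arma::fill::zeros);
  U.row(root) = pi.t();
  for (int e = edge.n_rows - 1; e >= 0; --e) {
    const int par = edge(e, 0) - 1;
    const int child = edge(e, 1) - 1;
    arma::vec a = U.row(par).t();
    for (int s : kids[par])
      if (s != e) a %= C.row(s).t();
    arma::vec u = P.slice(e).t() * a;
    double ssum = arma::accu(u);
    if (ssum > 0.0) u /= ssum;
    U.row(child) = u.t();
  }

  arma::mat M(nnode_total, k);
  for (int v = 0; v < nnode_total; ++v) {
    arma::vec m = (D.row(v) % U.row(v)).t();
    double s = arma::accu(m);
    if (s > 0.0) m /= s;
    M.row(v) = m.t();
  }
  return List::create(_["loglik"] = loglik, _["marginal"] = M,
                      _["root_prior"] = pi);
}
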