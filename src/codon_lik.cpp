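// GY94-style codon-model likelihood by Felsenstein pruning.
//
// The rate matrix uses single-nucleotide codon moves only, kappa on
// transitions, omega on nonsynonymous changes and target-codon frequencies
// pi_j; it is normalized so that one unit of branch length equals one
// expected substitution per codon site averaged over the site classes.
// Reversibility makes diag(pi)^(1/2) Q diag(pi)^(-1/2) symmetric, so the
// transition matrices come from a symmetric eigendecomposition.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_Q(const arma::vec& pi, const arma::imat& type,
                         double kappa, double omega) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      double mult = 0.0;
      switch (type(i, j)) {
        case 1: mult = 1.0; break;
        case 2: mult = kappa; break;
        case 3: mult = omega; break;
        case 4: mult = kappa * omega; break;
        default: mult = 0.0;
      }
      Q(i, j) = mult * pi(j);
      rowsum += Q(i, j);
    }
    Q(i, i) = -rowsum;
  }
  return Q;
}

// symmetric-form eigendecomposition of one class rate matrix, plus its
// stationary substitution rate (for mixture normalization)
// [[Rcpp::export]]
List codon_eigen_cpp(NumericVector pi_r, IntegerMatrix type_r,
                     double kappa, double omega) {
  const int NC = pi_r.size();
  arma::vec pi(pi_r.begin(), NC);
  arma::imat type(NC, NC);
  for (int i = 0; i < NC; ++i)
    for (int j = 0; j < NC; ++j) type(i, j) = type_r(i, j);
  arma::mat Q = build_Q(pi, type, kappa, omega);
  double rate = 0.0;
  for (int i = 0; i < NC; ++i) rate += -pi(i) * Q(i, i);
  arma::vec sqrt_pi = arma::sqrt(pi);
  arma::mat A = Q;
  for (int i = 0; i < NC; ++i)
    for (int j = 0; j < NC; ++j) A(i, j) *= sqrt_pi(i) / sqrt_pi(j);
  A = 0.5 * (A + A.t());
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, A)) stop("eigendecomposition failed");
  return List::create(Named("values") = wrap(eval),
                      Named("vectors") = wrap(evec),
                      Named("rate") = rate);
}

// [[Rcpp::export]]
List codon_lik_cpp(IntegerMatrix states, IntegerMatrix edge,
                   NumericVector edge_len, int ntips,
                   NumericVector pi_r, List eigens,
                   NumericVector rates, NumericVector weights,
                   bool per_site) {
  const int S = states.ncol();          // sites
  const int K = eigens.size();          // site classes
  const int nedge = edge.nrow();
  const int nnode = ntips + (nedge - ntips + 1) + 1; // generous upper bound
  const int NC = pi_r.size();           // 61 sense codons

  arma::vec pi(pi_r.begin(), NC);
  double mean_rate = 0.0;
  for (int k = 0; k < K; ++k) mean_rate += weights[k] * rates[k];
  if (mean_rate <= 0.0) stop("degenerate rate matrix (zero mean rate)");
  const double mu = 1.0 / mean_rate;

  arma::vec sqrt_pi = arma::sqrt(pi);
  arma::vec inv_sqrt_pi = 1.0 / sqrt_pi;

  arma::mat logLks(K, S, arma::fill::zeros);

  int root = ntips;                     // 0-based; ape root = ntips + 1
  for (int k = 0; k < K; ++k) {
    List ek = eigens[k];
    arma::vec eval = as<arma::vec>(ek["values"]);
    arma::mat evec = as<arma::mat>(ek["vectors"]);

    std::vector<arma::mat> partial(nnode);
    std::vector<arma::rowvec> logscale(nnode);
    std::vector<bool> touched(nnode, false);

    for (int e = 0; e < nedge; ++e) {   // edges in postorder
      int p = edge(e, 0) - 1;
      int c = edge(e, 1) - 1;
      if (p >= nnode || c >= nnode) stop("edge index out of range");
      // child partial
      arma::mat Lc;
      arma::rowvec sc(S, arma::fill::zeros);
      if (c < ntips) {
        Lc.zeros(NC, S);
        for (int s = 0; s < S; ++s) {
          int st = states(c, s);
          if (st == NA_INTEGER) Lc.col(s).ones();
          else Lc(st - 1, s) = 1.0;
        }
      } else {
        if (!touched[c]) stop("internal node used before its children (edges not in postorder)");
        Lc = partial[c];
        sc = logscale[c];
      }
      // transition matrix along this edge
      double t = edge_len[e] * mu;
      arma::vec ex = arma::exp(eval * t);
      arma::mat P = evec * arma::diagmat(ex) * evec.t();
      for (int i = 0; i < NC; ++i)
        for (int j = 0; j < NC; ++j) {
          double v = P(i, j) * inv_sqrt_pi(i) * sqrt_pi(j);
          P(i, j) = v > 0.0 ? v : 0.0;
        }
      arma::mat contrib = P * Lc;
      if (!touched[p]) {
        partial[p] = contrib;
        logscale[p] = sc;
        touched[p] = true;
      } else {
        partial[p] %= contrib;
        logscale[p] += sc;
      }
      // rescale parent columns
      arma::rowvec mx = arma::max(partial[p], 0);
      for (int s = 0; s < S; ++s) {
        double m = mx(s);
        if (m > 0.0 && (m < 1e-100 || m > 1e100)) {
          partial[p].col(s) /= m;
          logscale[p](s) += std::log(m);
        } else if (m <= 0.0) {
          // impossible column under this class; leave zeros, log-lik -> -Inf
        }
      }
    }
    if (!touched[root]) stop("root never reached; check edge matrix");
    arma::rowvec lik = pi.t() * partial[root];
    for (int s = 0; s < S; ++s) {
      double l = lik(s);
      logLks(k, s) = (l > 0.0) ? std::log(l) + logscale[root](s) : -arma::datum::inf;
    }
  }

  // mixture log-likelihood with log-sum-exp over classes
  double lnl = 0.0;
  for (int s = 0; s < S; ++s) {
    double mx = -arma::datum::inf;
    for (int k = 0; k < K; ++k) {
      if (weights[k] <= 0.0) continue;
      double v = std::log(weights[k]) + logLks(k, s);
      if (v > mx) mx = v;
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) {
      if (weights[k] <= 0.0) continue;
      acc += std::exp(std::log(weights[k]) + logLks(k, s) - mx);
    }
    lnl += mx + std::log(acc);
  }

  if (per_site) {
    return List::create(Named("lnl") = lnl,
                        Named("site_class_loglik") = wrap(logLks));
  }
  return List::create(Named("lnl") = lnl);
}
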