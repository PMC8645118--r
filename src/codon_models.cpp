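// Goldman-Yang codon model machinery: scaled 61x61 rate matrix, transition
// probabilities via symmetrized eigendecomposition (the model is time
// reversible), and Felsenstein pruning over site patterns. Also a small
// affine-gap profile aligner used by the progressive MSA.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat build_Q(double kappa, double omega, const arma::vec& pi,
                         const arma::imat& pairs) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (arma::uword r = 0; r < pairs.n_rows; ++r) {
    const int i = pairs(r, 0), j = pairs(r, 1);
    double rate = (pairs(r, 2) ? kappa : 1.0) * (pairs(r, 3) ? 1.0 : omega);
    Q(i, j) = rate * pi(j);
    Q(j, i) = rate * pi(i);
  }
  Q.diag() = -arma::sum(Q, 1);
  // scale so one unit of branch length = one expected substitution per codon
  double mu = -arma::dot(pi, arma::vec(Q.diag()));
  if (mu > 0) Q /= mu;
  return Q;
}

struct RevEig {
  arma::mat U, Uinv;
  arma::vec d;
};

static RevEig eig_reversible(const arma::mat& Q, const arma::vec& pi) {
  arma::vec sq = arma::sqrt(pi);
  arma::mat B = Q;
  B.each_col() %= sq;       // D^{1/2} Q
  B.each_row() /= sq.t();   // D^{1/2} Q D^{-1/2}, symmetric for reversible Q
  B = 0.5 * (B + B.t());
  RevEig e;
  arma::mat V;
  arma::eig_sym(e.d, V, B);
  e.U = V;
  e.U.each_col() /= sq;     // D^{-1/2} V
  e.Uinv = V.t();
  e.Uinv.each_row() %= sq.t();  // V^T D^{1/2}
  return e;
}

static arma::mat pmat_from_eig(const RevEig& e, double t) {
  arma::mat P = e.U * arma::diagmat(arma::exp(e.d * t)) * e.Uinv;
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

// [[Rcpp::export(name = "cpp_codon_pmat")]]
NumericMatrix cpp_codon_pmat(double kappa, double omega, arma::vec pi,
                             double t, arma::imat pairs) {
  arma::mat Q = build_Q(kappa, omega, pi, pairs);
  RevEig e = eig_reversible(Q, pi);
  arma::mat P = pmat_from_eig(e, t);
  // renormalize rows (simulation draws from them)
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    double s = arma::accu(P.row(i));
    if (s > 0) P.row(i) /= s;
  }
  return wrap(P);
}

// Log-likelihood of codon site patterns on a rooted representation of an
// unrooted tree. tips: ntip x npat matrix of 0-based codon states (-1 =
// missing/gap). edge: nedge x 2 matrix of 0-based (parent, child) node ids in
// postorder (children before parents). edge_class selects the omega in
// `omegas` applying to that edge.
// [[Rcpp::export(name = "cpp_codon_lnL")]]
double cpp_codon_lnL(IntegerMatrix tips, NumericVector weights,
                     IntegerMatrix edge, int nnode,
                     NumericVector edge_len, IntegerVector edge_class,
                     double kappa, NumericVector omegas, arma::vec pi,
                     arma::imat pairs) {
  const int ntip = tips.nrow();
  const int npat = tips.ncol();
  const int nstate = pi.n_elem;
  const int nclass = omegas.size();

  std::vector<RevEig> eigs(nclass);
  for (int c = 0; c < nclass; ++c) {
    arma::mat Q = build_Q(kappa, omegas[c], pi, pairs);
    eigs[c] = eig_reversible(Q, pi);
  }

  std::vector<arma::mat> part(nnode);
  std::vector<bool> seen(nnode, false);
  arma::rowvec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < edge.nrow(); ++e) {
    const int p = edge(e, 0), c = edge(e, 1);
    arma::mat P = pmat_from_eig(eigs[edge_class[e]], edge_len[e]);
    arma::mat contrib(nstate, npat);
    if (c < ntip) {
      for (int s = 0; s < npat; ++s) {
        const int obs = tips(c, s);
        if (obs >= 0) contrib.col(s) = P.col(obs);
        else contrib.col(s).ones();
      }
    } else {
      contrib = P * part[c];
      part[c].reset();
    }
    if (!seen[p]) {
      part[p] = contrib;
      seen[p] = true;
    } else {
      part[p] %= contrib;
      arma::rowvec m = arma::max(part[p], 0);
      for (int s = 0; s < npat; ++s) {
        if (m(s) > 0 && (m(s) < 1e-150 || m(s) > 1e150)) {
          part[p].col(s) /= m(s);
          logscale(s) += std::log(m(s));
        }
      }
    }
  }

  const int root = edge(edge.nrow() - 1, 0);
  arma::rowvec site = pi.t() * part[root];
  double lnL = 0.0;
  for (int s = 0; s < npat; ++s) {
    double v = site(s);
    if (v <= 0) return -1e12;
    lnL += weights[s] * (std::log(v) + logscale(s));
  }
  return lnL;
}

// Gotoh global alignment of two profiles given a precomputed column-pair
// score matrix C (n1 x n2). Returns the optimal score and the traceback as a
// vector of moves: 0 = match column, 1 = gap in profile 2 (consume profile 1
// column), 2 = gap in profile 1.
// [[Rcpp::export(name = "cpp_affine_profile_align")]]
List cpp_affine_profile_align(NumericMatrix C, double gap_open,
                              double gap_extend) {
  const int n1 = C.nrow(), n2 = C.ncol();
  const double NEG = -1e30;
  arma::mat M(n1 + 1, n2 + 1, arma::fill::value(NEG));
  arma::mat X(n1 + 1, n2 + 1, arma::fill::value(NEG));  // gap in profile 2
  arma::mat Y(n1 + 1, n2 + 1, arma::fill::value(NEG));  // gap in profile 1
  M(0, 0) = 0.0;
  for (int i = 1; i <= n1; ++i) X(i, 0) = -gap_open - gap_extend * i;
  for (int j = 1; j <= n2; ++j) Y(0, j) = -gap_open - gap_extend * j;

  arma::umat tbM(n1 + 1, n2 + 1, arma::fill::zeros);
  arma::umat tbX(n1 + 1, n2 + 1, arma::fill::zeros);
  arma::umat tbY(n1 + 1, n2 + 1, arma::fill::zeros);

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // M: prefer diagonal continuation, then X, then Y (deterministic)
      double m0 = M(i - 1, j - 1), m1 = X(i - 1, j - 1), m2 = Y(i - 1, j - 1);
      int bm = 0; double vm = m0;
      if (m1 > vm) { vm = m1; bm = 1; }
      if (m2 > vm) { vm = m2; bm = 2; }
      M(i, j) = vm + C(i - 1, j - 1);
      tbM(i, j) = bm;

      double xo = M(i - 1, j) - gap_open - gap_extend;
      double xe = X(i - 1, j) - gap_extend;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 0; }
      else { X(i, j) = xe; tbX(i, j) = 1; }

      double yo = M(i, j - 1) - gap_open - gap_extend;
      double ye = Y(i, j - 1) - gap_extend;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 0; }
      else { Y(i, j) = ye; tbY(i, j) = 2; }
    }
  }

  double best = M(n1, n2); int state = 0;
  if (X(n1, n2) > best) { best = X(n1, n2); state = 1; }
  if (Y(n1, n2) > best) { best = Y(n1, n2); state = 2; }

  std::vector<int> moves;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (i == 0) { moves.push_back(2); --j; continue; }
    if (j == 0) { moves.push_back(1); --i; continue; }
    if (state == 0) {
      moves.push_back(0);
      state = tbM(i, j);
      --i; --j;
    } else if (state == 1) {
      moves.push_back(1);
      state = tbX(i, j) == 0 ? 0 : 1;
      --i;
    } else {
      moves.push_back(2);
      state = tbY(i, j) == 0 ? 0 : 2;
      --j;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return List::create(_["score"] = best, _["moves"] = wrap(moves));
}
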