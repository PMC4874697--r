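// MuSSE-type pruning likelihood: coupled extinction (E) and data (D)
// probabilities integrated along branches with an adaptive Dormand-Prince
// 5(4) scheme.  The transition matrix is stored sparsely (hypercube rows
// have at most n_chars off-diagonal entries).

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct SsePars {
  int n;                       // number of states
  std::vector<double> lambda;  // speciation, per state
  std::vector<double> mu;      // extinction, per state
  // CSR off-diagonal transition rates; diag[i] = -sum of row i off-diagonals
  std::vector<int> rowptr;
  std::vector<int> col;
  std::vector<double> val;
  std::vector<double> diag;
};

SsePars make_pars(const NumericVector& lambda, const NumericVector& mu,
                  const NumericMatrix& Q) {
  SsePars p;
  p.n = lambda.size();
  p.lambda.assign(lambda.begin(), lambda.end());
  p.mu.assign(mu.begin(), mu.end());
  p.rowptr.assign(p.n + 1, 0);
  p.diag.assign(p.n, 0.0);
  for (int i = 0; i < p.n; ++i) {
    p.rowptr[i] = (int)p.col.size();
    for (int j = 0; j < p.n; ++j) {
      if (j == i) continue;
      double q = Q(i, j);
      if (q != 0.0) {
        p.col.push_back(j);
        p.val.push_back(q);
        p.diag[i] -= q;
      }
    }
  }
  p.rowptr[p.n] = (int)p.col.size();
  return p;
}

// y = [E_1..E_n, D_1..D_n]
void sse_deriv(const SsePars& p, const double* y, double* dy) {
  const int n = p.n;
  const double* E = y;
  const double* D = y + n;
  for (int i = 0; i < n; ++i) {
    double qe = p.diag[i] * E[i];
    double qd = p.diag[i] * D[i];
    for (int k = p.rowptr[i]; k < p.rowptr[i + 1]; ++k) {
      qe += p.val[k] * E[p.col[k]];
      qd += p.val[k] * D[p.col[k]];
    }
    const double lm = p.lambda[i] + p.mu[i];
    dy[i] = p.mu[i] - lm * E[i] + p.lambda[i] * E[i] * E[i] + qe;
    dy[n + i] = -lm * D[i] + 2.0 * p.lambda[i] * D[i] * E[i] + qd;
  }
}

// Dormand-Prince 5(4) with standard error control.  Returns false on
// step-size collapse.
bool dopri5(const SsePars& p, std::vector<double>& y, double t0, double t1,
            double rtol, double atol) {
  const int dim = 2 * p.n;
  if (t1 <= t0) return true;
  static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
  static const double a21 = 1.0 / 5;
  static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
  static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
  static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                      a53 = 64448.0 / 6561, a54 = -212.0 / 729;
  static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                      a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                      a65 = -5103.0 / 18656;
  static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                      b5 = -2187.0 / 6784, b6 = 11.0 / 84;
  static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                      e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

  std::vector<double> k1(dim), k2(dim), k3(dim), k4(dim), k5(dim), k6(dim),
      k7(dim), yt(dim), ynew(dim);

  double t = t0;
  double h = (t1 - t0) / 10.0;
  if (h <= 0) return true;
  const double hmin = (t1 - t0) * 1e-14;
  int n_reject = 0;

  sse_deriv(p, y.data(), k1.data());
  for (int iter = 0; iter < 1000000; ++iter) {
    if (t >= t1) return true;
    if (h > t1 - t) h = t1 - t;

    for (int i = 0; i < dim; ++i) yt[i] = y[i] + h * a21 * k1[i];
    sse_deriv(p, yt.data(), k2.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    sse_deriv(p, yt.data(), k3.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    sse_deriv(p, yt.data(), k4.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    sse_deriv(p, yt.data(), k5.data());
    for (int i = 0; i < dim; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    sse_deriv(p, yt.data(), k6.data());
    for (int i = 0; i < dim; ++i)
      ynew[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                            b6 * k6[i]);
    sse_deriv(p, ynew.data(), k7.data());

    double err = 0.0;
    for (int i = 0; i < dim; ++i) {
      double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                       e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = ei / sc;
      err += r * r;
    }
    err = std::sqrt(err / dim);

    if (err <= 1.0 || h <= hmin) {
      t += h;
      y = ynew;
      k1 = k7;  // FSAL
      n_reject = 0;
    } else {
      ++n_reject;
      if (n_reject > 50) return false;
    }
    double fac = 0.9 * std::pow(err > 1e-30 ? err : 1e-30, -0.2);
    if (fac > 5.0) fac = 5.0;
    if (fac < 0.2) fac = 0.2;
    h *= fac;
    if (h < hmin && t < t1) h = hmin;
  }
  return false;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
List sse_branch_cpp(NumericVector D, NumericVector E, NumericVector lambda,
                    NumericVector mu, NumericMatrix Q, double len,
                    double rtol, double atol) {
  SsePars p = make_pars(lambda, mu, Q);
  std::vector<double> y(2 * p.n);
  for (int i = 0; i < p.n; ++i) {
    y[i] = E[i];
    y[p.n + i] = D[i];
  }
  bool ok = dopri5(p, y, 0.0, len, rtol, atol);
  NumericVector Dout(p.n), Eout(p.n);
  for (int i = 0; i < p.n; ++i) {
    Eout[i] = y[i];
    Dout[i] = y[p.n + i];
  }
  return List::create(_["D"] = Dout, _["E"] = Eout, _["ok"] = ok);
}

// Postorder pruning pass.  `edge` is an ape edge matrix already in postorder
// (children rows before the row leading to their parent); nodes are numbered
// 1..n_tip for tips, n_tip+1 for the root, then internals.
//' @noRd
// [[Rcpp::export]]
List sse_prune_cpp(IntegerMatrix edge, NumericVector edge_length, int n_tip,
                   NumericMatrix tipD, NumericVector E0, NumericVector lambda,
                   NumericVector mu, NumericMatrix Q,
                   NumericVector node_lambda, double rtol, double atol) {
  SsePars p = make_pars(lambda, mu, Q);
  const int n = p.n;
  const int n_edge = edge.nrow();
  const int n_node = n_tip + n_edge + 1;  // upper bound on node ids

  NumericMatrix nodeD(n_node, n);   // conditional likelihoods at nodes
  NumericMatrix nodeE(n_node, n);   // extinction probabilities at nodes
  NumericMatrix branchTopD(n_edge, n);  // rescaled D at the top of each edge
  std::vector<double> logcomp(n_node, 0.0);
  std::vector<int> n_child_seen(n_node, 0);
  std::vector<bool> failed_flag(1, false);

  // tip initial conditions
  for (int i = 0; i < n_tip; ++i) {
    for (int s = 0; s < n; ++s) {
      nodeD(i, s) = tipD(i, s);
      nodeE(i, s) = E0[s];
    }
  }

  int root = -1;
  bool numerical_failure = false;
  std::vector<double> y(2 * n);

  for (int e = 0; e < n_edge; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    for (int s = 0; s < n; ++s) {
      y[s] = nodeE(child, s);
      y[n + s] = nodeD(child, s);
    }
    if (!dopri5(p, y, 0.0, edge_length[e], rtol, atol)) {
      numerical_failure = true;
    }
    // rescale branch-top D
    double tot = 0.0;
    for (int s = 0; s < n; ++s) tot += y[n + s];
    if (!(tot > 0.0) || !std::isfinite(tot)) {
      // likelihood underflowed to zero (or failed): report -Inf
      return List::create(_["loglik"] = R_NegInf, _["ok"] = false,
                          _["edge"] = e + 1);
    }
    for (int s = 0; s < n; ++s) branchTopD(e, s) = y[n + s] / tot;
    double lc = logcomp[child] + std::log(tot);

    if (n_child_seen[parent] == 0) {
      for (int s = 0; s < n; ++s) {
        nodeD(parent, s) = branchTopD(e, s);
        nodeE(parent, s) = y[s];
      }
      logcomp[parent] = lc;
    } else {
      double tot2 = 0.0;
      for (int s = 0; s < n; ++s) {
        double v = node_lambda[s] * nodeD(parent, s) * branchTopD(e, s);
        nodeD(parent, s) = v;
        tot2 += v;
      }
      if (!(tot2 > 0.0) || !std::isfinite(tot2)) {
        return List::create(_["loglik"] = R_NegInf, _["ok"] = false,
                            _["edge"] = e + 1);
      }
      for (int s = 0; s < n; ++s) nodeD(parent, s) /= tot2;
      logcomp[parent] += lc + std::log(tot2);
    }
    ++n_child_seen[parent];
    root = parent;
  }

  NumericVector rootD(n), rootE(n);
  for (int s = 0; s < n; ++s) {
    rootD[s] = nodeD(root, s);
    rootE[s] = nodeE(root, s);
  }
  return List::create(_["rootD"] = rootD, _["rootE"] = rootE,
                      _["logcomp"] = logcomp[root], _["root"] = root + 1,
                      _["nodeD"] = nodeD, _["nodeE"] = nodeE,
                      _["branchTopD"] = branchTopD,
                      _["ok"] = !numerical_failure);
}
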