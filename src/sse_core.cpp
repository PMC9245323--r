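#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Generic k-state state-dependent birth-death pruning.
//
// Along each branch the coupled extinction/likelihood ODEs are integrated
// backwards in time (tipward -> rootward):
//   E_i' = mu_i - (lambda_i + mu_i + r_i) E_i + lambda_i E_i^2 + sum_j Q_ij E_j
//   D_i' = -(lambda_i + mu_i + r_i) D_i + 2 lambda_i E_i D_i + sum_j Q_ij D_j
// with r_i = sum_{j != i} Q_ij.  Q holds off-diagonal transition rates;
// its diagonal is ignored.  Integration uses an embedded Cash-Karp
// Runge-Kutta 4(5) pair with adaptive step control.

struct SseSystem {
  int k;
  std::vector<double> lambda, mu, qrow;
  std::vector<double> Q; // row-major k*k, diagonal unused

  void deriv(const double* y, double* dy) const {
    const double* E = y;
    const double* D = y + k;
    for (int i = 0; i < k; ++i) {
      double qe = 0.0, qd = 0.0;
      for (int j = 0; j < k; ++j) {
        if (j == i) continue;
        qe += Q[i * k + j] * E[j];
        qd += Q[i * k + j] * D[j];
      }
      double tot = lambda[i] + mu[i] + qrow[i];
      dy[i]     = mu[i] - tot * E[i] + lambda[i] * E[i] * E[i] + qe;
      dy[k + i] = -tot * D[i] + 2.0 * lambda[i] * E[i] * D[i] + qd;
    }
  }
};

// Cash-Karp tableau
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0, c4 = 125.0 / 594.0,
                    c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                    dc6 = c6 - 1.0 / 4.0;

// one adaptive integration over [0, len]; y modified in place
static void integrate_branch(const SseSystem& sys, std::vector<double>& y,
                             double len, double reltol, double abstol) {
  int n = 2 * sys.k;
  if (len <= 0.0) return;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n);
  std::vector<double> ytmp(n), yerr(n), ynew(n);
  double t = 0.0;
  double h = len; // optimistic first step; controller shrinks as needed
  int iter = 0;
  const int maxiter = 1000000;
  while (t < len) {
    if (++iter > maxiter)
      stop("SSE branch integration failed to converge (too many steps)");
    if (t + h > len) h = len - t;
    sys.deriv(y.data(), k1.data());
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    sys.deriv(ytmp.data(), k2.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    sys.deriv(ytmp.data(), k3.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    sys.deriv(ytmp.data(), k4.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                            b54 * k4[i]);
    sys.deriv(ytmp.data(), k5.data());
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    sys.deriv(ytmp.data(), k6.data());
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                     dc6 * k6[i]);
      double sc = abstol + reltol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      errmax = std::max(errmax, std::fabs(yerr[i]) / sc);
    }
    if (errmax <= 1.0) {
      t += h;
      y = ynew;
      double fac = (errmax > 0.0) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errmax, -0.25));
    }
    if (h < 1e-14 * len)
      stop("SSE branch integration step size underflow");
  }
  // clamp tiny negative round-off
  for (int i = 0; i < n; ++i)
    if (y[i] < 0.0 && y[i] > -1e-12) y[i] = 0.0;
}

// Full pruning with lambda factors applied at internal nodes at the moment
// each node's daughters are combined (correct order of operations).
// [[Rcpp::export]]
List sse_loglik_cpp(IntegerMatrix edge, NumericVector edge_length, int ntip,
                    NumericMatrix tipD, NumericVector lambda, NumericVector mu,
                    NumericMatrix Q, double reltol, double abstol) {
  int k = lambda.size();
  if (mu.size() != k || Q.nrow() != k || Q.ncol() != k)
    stop("parameter dimensions disagree");
  if (tipD.nrow() != ntip || tipD.ncol() != k)
    stop("tip likelihood matrix has wrong dimensions");

  SseSystem sys;
  sys.k = k;
  sys.lambda.assign(lambda.begin(), lambda.end());
  sys.mu.assign(mu.begin(), mu.end());
  sys.Q.resize(k * k);
  sys.qrow.assign(k, 0.0);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      sys.Q[i * k + j] = (i == j) ? 0.0 : Q(i, j);
      if (i != j) sys.qrow[i] += Q(i, j);
    }

  int nedge = edge.nrow();
  int maxid = 0;
  for (int e = 0; e < nedge; ++e) {
    maxid = std::max(maxid, edge(e, 0));
    maxid = std::max(maxid, edge(e, 1));
  }
  std::vector<std::vector<double> > nodeE(maxid + 1), nodeD(maxid + 1);
  std::vector<double> nodeLog(maxid + 1, 0.0);
  std::vector<int> nin(maxid + 1, 0);   // daughters combined so far
  std::vector<int> ntot(maxid + 1, 0);  // total daughters
  for (int e = 0; e < nedge; ++e) ntot[edge(e, 0)] += 1;

  for (int tip = 1; tip <= ntip; ++tip) {
    nodeD[tip].assign(k, 0.0);
    nodeE[tip].assign(k, 0.0);
    for (int s = 0; s < k; ++s) nodeD[tip][s] = tipD(tip - 1, s);
  }

  for (int e = 0; e < nedge; ++e) {
    int parent = edge(e, 0);
    int child = edge(e, 1);
    double len = edge_length[e];
    if (len <= 0.0) len = 1e-9;
    if (nodeD[child].empty())
      stop("edge matrix is not in postorder");
    // if child is internal, apply its speciation factors now (daughters done)
    if (child > ntip) {
      for (int s = 0; s < k; ++s)
        for (int d = 1; d < ntot[child]; ++d)
          nodeD[child][s] *= sys.lambda[s];
    }
    std::vector<double> y(2 * k);
    for (int s = 0; s < k; ++s) {
      y[s] = nodeE[child][s];
      y[k + s] = nodeD[child][s];
    }
    integrate_branch(sys, y, len, reltol, abstol);
    double scale = 0.0;
    for (int s = 0; s < k; ++s) scale += y[k + s];
    if (!(scale > 0.0))
      stop("SSE likelihood underflow: all D values vanished on a branch");
    if (nodeD[parent].empty()) {
      nodeD[parent].assign(k, 1.0);
      nodeE[parent].assign(k, 0.0);
      for (int s = 0; s < k; ++s) nodeE[parent][s] = y[s];
    }
    for (int s = 0; s < k; ++s) nodeD[parent][s] *= y[k + s] / scale;
    nodeLog[parent] += nodeLog[child] + std::log(scale);
    nin[parent] += 1;
  }

  int root = edge(nedge - 1, 0);
  // root speciation factors
  for (int s = 0; s < k; ++s)
    for (int d = 1; d < ntot[root]; ++d) nodeD[root][s] *= sys.lambda[s];

  return List::create(
      _["E"] = NumericVector(nodeE[root].begin(), nodeE[root].end()),
      _["D"] = NumericVector(nodeD[root].begin(), nodeD[root].end()),
      _["logcomp"] = nodeLog[root]);
}
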