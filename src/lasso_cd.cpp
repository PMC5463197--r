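#include <Rcpp.h>
using namespace Rcpp;

// Coordinate descent for the lasso objective
//   ||x - D a||_2^2 + gamma * ||a||_1
// (unit coefficient on the quadratic term: the soft threshold sits at
// gamma/2). One column per data vector, covariance updates on the
// precomputed Gram matrix, active-set sweeps between full sweeps, and an
// optional warm start. Every coordinate update is a descent step, so the
// objective never increases from the warm start.

static inline double soft_update(double rho, double thr, double gjj) {
  if (rho > thr) return (rho - thr) / gjj;
  if (rho < -thr) return (rho + thr) / gjj;
  return 0.0;
}

// [[Rcpp::export(name = ".cd_lasso")]]
NumericMatrix cd_lasso(const NumericMatrix& D, const NumericMatrix& X,
                       double gamma, double tol, int max_sweeps,
                       Nullable<NumericMatrix> warm = R_NilValue) {
  const int k = D.nrow(), s = D.ncol(), m = X.ncol();
  if (X.nrow() != k) stop("dimension mismatch between dictionary and data");

  NumericMatrix G(s, s);
  for (int i = 0; i < s; ++i)
    for (int j = i; j < s; ++j) {
      double acc = 0.0;
      for (int r = 0; r < k; ++r) acc += D(r, i) * D(r, j);
      G(i, j) = acc;
      G(j, i) = acc;
    }

  NumericMatrix A(s, m);
  const double thr = gamma / 2.0;
  const bool has_warm = warm.isNotNull();
  NumericMatrix W;
  if (has_warm) {
    W = NumericMatrix(warm);
    if (W.nrow() != s || W.ncol() != m) stop("warm start has wrong shape");
  }

  std::vector<double> c(s), Ga(s), a(s);
  std::vector<int> active(s);

  for (int e = 0; e < m; ++e) {
    for (int j = 0; j < s; ++j) {
      double acc = 0.0;
      for (int r = 0; r < k; ++r) acc += D(r, j) * X(r, e);
      c[j] = acc;
    }
    std::fill(Ga.begin(), Ga.end(), 0.0);
    if (has_warm) {
      for (int j = 0; j < s; ++j) a[j] = W(j, e);
      for (int j = 0; j < s; ++j)
        if (a[j] != 0.0)
          for (int l = 0; l < s; ++l) Ga[l] += G(l, j) * a[j];
    } else {
      std::fill(a.begin(), a.end(), 0.0);
    }

    int sweeps = 0;
    while (sweeps < max_sweeps) {
      // full sweep over all coordinates
      double max_delta = 0.0;
      for (int j = 0; j < s; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) { a[j] = 0.0; continue; }
        const double rho = c[j] - Ga[j] + gjj * a[j];
        const double aj = soft_update(rho, thr, gjj);
        const double delta = aj - a[j];
        if (delta != 0.0) {
          for (int l = 0; l < s; ++l) Ga[l] += G(l, j) * delta;
          a[j] = aj;
          const double ad = std::fabs(delta);
          if (ad > max_delta) max_delta = ad;
        }
      }
      ++sweeps;
      if (max_delta < tol) break;

      // iterate on the current support until it stabilises
      int na = 0;
      for (int j = 0; j < s; ++j) if (a[j] != 0.0) active[na++] = j;
      while (sweeps < max_sweeps && na > 0) {
        double md = 0.0;
        for (int t = 0; t < na; ++t) {
          const int j = active[t];
          const double gjj = G(j, j);
          if (gjj <= 0.0) continue;
          const double rho = c[j] - Ga[j] + gjj * a[j];
          const double aj = soft_update(rho, thr, gjj);
          const double delta = aj - a[j];
          if (delta != 0.0) {
            for (int l = 0; l < s; ++l) Ga[l] += G(l, j) * delta;
            a[j] = aj;
            const double ad = std::fabs(delta);
            if (ad > md) md = ad;
          }
        }
        ++sweeps;
        if (md < tol) break;
      }
    }
    for (int j = 0; j < s; ++j) A(j, e) = a[j];
  }
  return A;
}
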