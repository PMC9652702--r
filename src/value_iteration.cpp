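#include <Rcpp.h>
using namespace Rcpp;

// Jacobi value-iteration sweeps for the grid MDP.
//
// The transition model is encoded as three n x k index matrices (1-based):
// under action a from state s, probability p[0] goes to T1(s,a), p[1] to
// T2(s,a) and p[2] to T3(s,a). Clamped states (goal / obstacle-belief
// cells) keep their initial value throughout; their Q rows are still
// computed so the policy is defined everywhere. Jacobi (double-buffered)
// sweeps keep each sweep a sup-norm contraction with modulus <= eta.
//
// [[Rcpp::export(name = ".vi_core")]]
List vi_core(NumericVector V0, LogicalVector clamped,
             IntegerMatrix T1, IntegerMatrix T2, IntegerMatrix T3,
             NumericVector p, double eta, Nullable<NumericMatrix> reward,
             double tol, int max_iter) {
  const int n = V0.size();
  const int k = T1.ncol();
  NumericVector V = clone(V0);
  NumericVector Vnew(n);
  NumericMatrix Q(n, k);
  std::vector<double> deltas;
  deltas.reserve(64);
  const bool has_r = reward.isNotNull();
  NumericMatrix R;
  if (has_r) R = NumericMatrix(reward);

  const double p0 = p[0], p1 = p[1], p2 = p[2];
  const int *t1 = INTEGER(T1), *t2 = INTEGER(T2), *t3 = INTEGER(T3);
  double *q = REAL(Q);

  double resid = R_PosInf;
  int iter = 0;
  std::vector<double> best(n);
  while (iter < max_iter) {
    ++iter;
    double *v = REAL(V);
    double *vn = REAL(Vnew);
    // column-major pass: one action at a time, contiguous memory
    for (int a = 0; a < k; ++a) {
      const int *c1 = t1 + (size_t)a * n;
      const int *c2 = t2 + (size_t)a * n;
      const int *c3 = t3 + (size_t)a * n;
      double *qa = q + (size_t)a * n;
      const double *ra = has_r ? REAL(R) + (size_t)a * n : nullptr;
      if (a == 0) {
        for (int s = 0; s < n; ++s) {
          double val = eta * (p0 * v[c1[s] - 1] + p1 * v[c2[s] - 1] +
                              p2 * v[c3[s] - 1]) + (ra ? ra[s] : 0.0);
          qa[s] = val;
          best[s] = val;
        }
      } else {
        for (int s = 0; s < n; ++s) {
          double val = eta * (p0 * v[c1[s] - 1] + p1 * v[c2[s] - 1] +
                              p2 * v[c3[s] - 1]) + (ra ? ra[s] : 0.0);
          qa[s] = val;
          if (val > best[s]) best[s] = val;
        }
      }
    }
    double d = 0.0;
    for (int s = 0; s < n; ++s) {
      if (clamped[s]) {
        vn[s] = V0[s];
      } else {
        vn[s] = best[s];
        double ch = std::fabs(best[s] - v[s]);
        if (ch > d) d = ch;
      }
    }
    std::swap(V, Vnew);
    deltas.push_back(d);
    resid = d;
    if (d < tol) break;
  }

  return List::create(_["V"] = V, _["Q"] = Q, _["iterations"] = iter,
                      _["residual"] = resid,
                      _["deltas"] = NumericVector(deltas.begin(), deltas.end()),
                      _["converged"] = resid < tol);
}
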