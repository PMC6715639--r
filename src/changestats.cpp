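#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Change statistics and Metropolis tie-toggle sampler for the multilevel
// ERGM over (A, X) conditional on the exogenous CLD B and attributes Y.
//
// All change statistics are oriented as z(tie present) - z(tie absent) and
// are evaluated in a state where the toggled tie is ABSENT; callers that
// hold the tie present must clear it first (the sampler does).
//
// Statistic codes match effect_catalogue() in R/configs.R.

struct SpecSet {
  std::vector<int> codes;
  std::vector<double> lambda;
  std::vector<int> attr; // 0 = none, else 1-based column of ymat
  // powers of r = 1 - 1/lambda, per spec, up to maxdeg
  std::vector< std::vector<double> > rpow;
};

static SpecSet make_specs(const IntegerVector& codes,
                          const NumericVector& lambdas,
                          const IntegerVector& attr_idx,
                          int maxdeg) {
  SpecSet s;
  int q = codes.size();
  s.codes.resize(q);
  s.lambda.resize(q);
  s.attr.resize(q);
  s.rpow.resize(q);
  for (int k = 0; k < q; ++k) {
    s.codes[k] = codes[k];
    s.lambda[k] = lambdas[k];
    s.attr[k] = attr_idx[k];
    double r = 1.0 - 1.0 / lambdas[k];
    s.rpow[k].resize(maxdeg + 2);
    s.rpow[k][0] = 1.0;
    for (int d = 1; d <= maxdeg + 1; ++d) s.rpow[k][d] = s.rpow[k][d - 1] * r;
  }
  return s;
}

// Degrees computed on demand; networks here are small (tens of nodes).
static inline int colsum(const IntegerMatrix& M, int j) {
  int s = 0;
  for (int i = 0; i < M.nrow(); ++i) s += M(i, j);
  return s;
}
static inline int rowsum(const IntegerMatrix& M, int i) {
  int s = 0;
  for (int j = 0; j < M.ncol(); ++j) s += M(i, j);
  return s;
}

// two-path count i -> k -> j in A
static inline int twopath(const IntegerMatrix& A, int i, int j) {
  int s = 0;
  for (int k = 0; k < A.nrow(); ++k) s += A(i, k) * A(k, j);
  return s;
}
// cyclic count for tie (i,j): j -> k -> i
static inline int cycpath(const IntegerMatrix& A, int i, int j) {
  int s = 0;
  for (int k = 0; k < A.nrow(); ++k) s += A(j, k) * A(k, i);
  return s;
}

// Delta for toggling A(i,j) (state: tie absent).
static double change_A(int code, const SpecSet& S, int q,
                       const IntegerMatrix& A, const IntegerMatrix& X,
                       const IntegerMatrix& B, const IntegerMatrix& Y,
                       int i, int j) {
  const std::vector<double>& rp = S.rpow[q];
  double lam = S.lambda[q];
  int nA = A.nrow();
  switch (code) {
  case 1: return 1.0;
  case 2: return (double)A(j, i);
  case 3: return (double)colsum(A, j);
  case 4: return lam * (1.0 - rp[colsum(A, j)]);
  case 5: return lam * (1.0 - rp[rowsum(A, i)]);
  case 6: {
    double dj = lam * rp[colsum(A, j)] * (1.0 - rp[rowsum(A, j)]);
    double di = lam * rp[rowsum(A, i)] * (1.0 - rp[colsum(A, i)]);
    return dj + di;
  }
  case 7: { // alternating transitive closure
    double d = lam * (1.0 - rp[twopath(A, i, j)]);
    for (int v = 0; v < nA; ++v) {
      if (A(i, v) && A(j, v)) d += rp[twopath(A, i, v)];
      if (A(v, j) && A(v, i)) d += rp[twopath(A, v, j)];
    }
    return d;
  }
  case 8: { // alternating cyclic closure
    double d = lam * (1.0 - rp[cycpath(A, i, j)]);
    for (int u = 0; u < nA; ++u) {
      if (A(u, i) && A(j, u)) d += rp[cycpath(A, u, i)];
    }
    for (int v = 0; v < nA; ++v) {
      if (A(j, v) && A(v, i)) d += rp[cycpath(A, j, v)];
    }
    return d;
  }
  case 9: {
    int c = S.attr[q] - 1;
    int yi = Y(i, c), yj = Y(j, c);
    return (yi >= 0 && yi == yj) ? 1.0 : 0.0;
  }
  case 14: { // ATXAX, A-side
    return lam * rp[rowsum(A, i)] * (1.0 - rp[rowsum(X, i)]);
  }
  case 19: { // L3AXBin: in-degree of j rises by one
    double d = 0.0;
    for (int v = 0; v < X.ncol(); ++v)
      if (X(j, v)) d += colsum(B, v);
    return d;
  }
  case 20: { // C4AXBentrainment
    double d = 0.0;
    for (int u = 0; u < X.ncol(); ++u) {
      if (!X(i, u)) continue;
      for (int v = 0; v < X.ncol(); ++v)
        if (B(u, v) && X(j, v)) d += 1.0;
    }
    return d;
  }
  case 21: { // C4AXBexchange
    double d = 0.0;
    for (int u = 0; u < X.ncol(); ++u) {
      if (!X(i, u)) continue;
      for (int v = 0; v < X.ncol(); ++v)
        if (B(v, u) && X(j, v)) d += 1.0;
    }
    return d;
  }
  case 22: { // C4AXBreciprocity: needs the mutual A dyad
    if (!A(j, i)) return 0.0;
    double d = 0.0;
    for (int u = 0; u < X.ncol(); ++u) {
      if (!X(i, u)) continue;
      for (int v = 0; v < X.ncol(); ++v)
        if (B(u, v) && B(v, u) && X(j, v)) d += 1.0;
    }
    return 2.0 * d;
  }
  default: return 0.0; // X-only statistics are unaffected by A toggles
  }
}

// Delta for toggling X(i,v) (state: tie absent).
static double change_X(int code, const SpecSet& S, int q,
                       const IntegerMatrix& A, const IntegerMatrix& X,
                       const IntegerMatrix& B, int i, int v) {
  const std::vector<double>& rp = S.rpow[q];
  double lam = S.lambda[q];
  int nA = X.nrow(), nB = X.ncol();
  switch (code) {
  case 10: return 1.0;
  case 11: return lam * (1.0 - rp[rowsum(X, i)]);
  case 12: return lam * (1.0 - rp[colsum(X, v)]);
  case 13: { // ACA over actor pairs sharing chosen variables
    double d = 0.0;
    for (int j = 0; j < nA; ++j) {
      if (j == i || !X(j, v)) continue;
      int s = 0;
      for (int u = 0; u < nB; ++u) s += X(i, u) * X(j, u);
      d += rp[s];
    }
    return d;
  }
  case 14: return lam * rp[rowsum(X, i)] * (1.0 - rp[rowsum(A, i)]);
  case 15: return (double)colsum(B, v);
  case 16: return (double)rowsum(B, v);
  case 17: { // TXBX
    double d = 0.0;
    for (int u = 0; u < nB; ++u)
      if (X(i, u)) d += B(u, v) + B(v, u);
    return d;
  }
  case 18: { // L3XBXreciprocity
    double d = 0.0;
    for (int j = 0; j < nA; ++j) {
      if (j == i) continue;
      for (int w = 0; w < nB; ++w)
        if (X(j, w) && B(v, w) && B(w, v)) d += 1.0;
    }
    return 2.0 * d;
  }
  case 19: return (double)colsum(A, i) * (double)colsum(B, v);
  case 20: {
    double d = 0.0;
    for (int j = 0; j < nA; ++j) {
      if (A(i, j)) { // toggled tie as the sender's action
        for (int w = 0; w < nB; ++w)
          if (X(j, w) && B(v, w)) d += 1.0;
      }
      if (A(j, i)) { // toggled tie as the receiver's action
        for (int u = 0; u < nB; ++u)
          if (X(j, u) && B(u, v)) d += 1.0;
      }
    }
    return d;
  }
  case 21: {
    double d = 0.0;
    for (int j = 0; j < nA; ++j) {
      if (A(i, j)) {
        for (int w = 0; w < nB; ++w)
          if (X(j, w) && B(w, v)) d += 1.0;
      }
      if (A(j, i)) {
        for (int u = 0; u < nB; ++u)
          if (X(j, u) && B(v, u)) d += 1.0;
      }
    }
    return d;
  }
  case 22: {
    double d = 0.0;
    for (int j = 0; j < nA; ++j) {
      if (j == i || !(A(i, j) && A(j, i))) continue;
      for (int w = 0; w < nB; ++w)
        if (X(j, w) && B(v, w) && B(w, v)) d += 1.0;
    }
    return 2.0 * d;
  }
  default: return 0.0; // A-only statistics are unaffected by X toggles
  }
}

static NumericVector all_changes(const SpecSet& S,
                                 const IntegerMatrix& A,
                                 const IntegerMatrix& X,
                                 const IntegerMatrix& B,
                                 const IntegerMatrix& Y,
                                 int layer, int i, int j) {
  int q = S.codes.size();
  NumericVector d(q);
  for (int k = 0; k < q; ++k) {
    d[k] = (layer == 0)
      ? change_A(S.codes[k], S, k, A, X, B, Y, i, j)
      : change_X(S.codes[k], S, k, A, X, B, i, j);
  }
  return d;
}

// [[Rcpp::export]]
NumericVector cpp_change_stats(IntegerMatrix A, IntegerMatrix X,
                               IntegerMatrix B, IntegerMatrix Y,
                               IntegerVector codes, NumericVector lambdas,
                               IntegerVector attr_idx,
                               int layer, int i, int j) {
  IntegerMatrix Ac = clone(A), Xc = clone(X);
  int maxdeg = std::max(std::max(A.nrow(), B.nrow()), X.ncol());
  SpecSet S = make_specs(codes, lambdas, attr_idx, maxdeg);
  // evaluate with the tie absent
  if (layer == 0) Ac(i, j) = 0; else Xc(i, j) = 0;
  return all_changes(S, Ac, Xc, B, Y, layer, i, j);
}

// Metropolis tie-toggle chain over (A, X). Returns sampled statistics
// (thinned), the final state, and the acceptance rate. Uses R's RNG so
// set.seed() in R gives reproducible chains.
// [[Rcpp::export]]
List cpp_mcmc(IntegerMatrix A0, IntegerMatrix X0, IntegerMatrix B,
              IntegerMatrix Y, IntegerVector codes, NumericVector lambdas,
              IntegerVector attr_idx, NumericVector theta,
              NumericVector z0, double probA,
              double burnin, double interval, int nsamples) {
  IntegerMatrix A = clone(A0), X = clone(X0);
  int nA = A.nrow(), nB = X.ncol();
  int q = codes.size();
  int maxdeg = std::max(std::max(nA, nB), B.nrow());
  SpecSet S = make_specs(codes, lambdas, attr_idx, maxdeg);

  std::vector<double> z(q);
  for (int k = 0; k < q; ++k) z[k] = z0[k];

  NumericMatrix stats(nsamples, q);
  double accepted = 0.0, total = 0.0;

  double total_updates = burnin + interval * (double)nsamples;
  long long n_up = (long long)total_updates;
  long long next_record = (nsamples > 0) ? (long long)(burnin + interval) : -1;
  int rec = 0;

  for (long long t = 1; t <= n_up; ++t) {
    int layer, i, j;
    if (unif_rand() < probA) {
      layer = 0;
      i = (int)(unif_rand() * nA);
      j = (int)(unif_rand() * (nA - 1));
      if (j >= i) ++j;
    } else {
      layer = 1;
      i = (int)(unif_rand() * nA);
      j = (int)(unif_rand() * nB);
    }
    int present = (layer == 0) ? A(i, j) : X(i, j);
    if (present) { if (layer == 0) A(i, j) = 0; else X(i, j) = 0; }
    NumericVector d = all_changes(S, A, X, B, Y, layer, i, j);
    double lp = 0.0;
    for (int k = 0; k < q; ++k) lp += theta[k] * d[k];
    if (!R_finite(lp)) stop("non-finite change statistic encountered");
    double sign = present ? -1.0 : 1.0;
    bool accept = (sign * lp >= 0.0) || (unif_rand() < std::exp(sign * lp));
    total += 1.0;
    if (accept) {
      accepted += 1.0;
      int newval = present ? 0 : 1;
      if (layer == 0) A(i, j) = newval; else X(i, j) = newval;
      for (int k = 0; k < q; ++k) z[k] += sign * d[k];
    } else {
      // restore a removed tie on rejection
      if (present) { if (layer == 0) A(i, j) = 1; else X(i, j) = 1; }
    }
    if (rec < nsamples && t >= next_record) {
      for (int k = 0; k < q; ++k) stats(rec, k) = z[k];
      ++rec;
      next_record = (long long)(burnin + interval * (double)(rec + 1));
    }
  }

  return List::create(
    _["stats"] = stats,
    _["A"] = A,
    _["X"] = X,
    _["z"] = NumericVector(z.begin(), z.end()),
    _["acceptance_rate"] = (total > 0.0) ? accepted / total : NA_REAL
  );
}
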