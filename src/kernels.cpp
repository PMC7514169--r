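#include <Rcpp.h>
using namespace Rcpp;

// Distance profile over the full enumerated state space.
//
// States are enumerated lexicographically with big-endian node order:
// 0-based index j decodes to digits s[0..n-1] with s[0] most significant.
// Entry j of the result is the d1 distance, summed over all ordered node
// pairs (diagonal included), between R and the relation induced on the
// nodes by reading U at the state pair the j-th data element assigns.
//
// The accumulation order (a outer, b inner, ascending) is fixed so that
// states with identical configurations produce bitwise-identical sums,
// which the exact <=-counting in the float entropy relies on.
// [[Rcpp::export]]
NumericVector cpp_distance_profile(int n, int m, NumericMatrix R,
                                   NumericMatrix U, bool symmetric = true) {
  double sized = std::pow((double)m, (double)n);
  if (sized > 2147483647.0) stop("state space too large for the kernel");
  int N = (int)(sized + 0.5);
  NumericVector out(N);
  std::vector<int> s(n, 0);
  if (symmetric) {
    // both R and U reflexive symmetric: the diagonal contributes 0 and
    // each unordered pair contributes twice; 2*x is exact in IEEE, so
    // this equals the full ordered-pair sum up to addition order
    int P = n * (n - 1) / 2;
    std::vector<int> pa(P), pb(P);
    std::vector<double> cost((size_t)P * m * m);
    int p = 0;
    for (int a = 0; a < n; ++a)
      for (int b = a + 1; b < n; ++b, ++p) {
        pa[p] = a; pb[p] = b;
        double r = R(a, b);
        double *c = &cost[(size_t)p * m * m];
        for (int sa = 0; sa < m; ++sa)
          for (int sb = 0; sb < m; ++sb)
            c[sa * m + sb] = 2.0 * std::fabs(r - U(sa, sb));
      }
    for (int j = 0; j < N; ++j) {
      double acc = 0.0;
      for (int q = 0; q < P; ++q)
        acc += cost[((size_t)q * m + s[pa[q]]) * m + s[pb[q]]];
      out[j] = acc;
      for (int a = n - 1; a >= 0; --a) {
        if (++s[a] < m) break;
        s[a] = 0;
      }
    }
    return out;
  }
  // general path: all ordered pairs including the diagonal
  std::vector<double> cost((size_t)n * n * m * m);
  for (int a = 0; a < n; ++a)
    for (int b = 0; b < n; ++b) {
      double r = R(a, b);
      double *c = &cost[((size_t)a * n + b) * m * m];
      for (int sa = 0; sa < m; ++sa)
        for (int sb = 0; sb < m; ++sb)
          c[sa * m + sb] = std::fabs(r - U(sa, sb));
    }
  for (int j = 0; j < N; ++j) {
    double acc = 0.0;
    for (int a = 0; a < n; ++a) {
      int sa = s[a];
      for (int b = 0; b < n; ++b)
        acc += cost[(((size_t)a * n + b) * m + sa) * m + s[b]];
    }
    out[j] = acc;
    // odometer increment, least-significant digit last (big-endian)
    for (int a = n - 1; a >= 0; --a) {
      if (++s[a] < m) break;
      s[a] = 0;
    }
  }
  return out;
}

// Distance profile at a derived level: each derived node's state is a
// function of the states of a tuple of base nodes, tabulated in redTab
// (one 0-based integer vector per tuple, length m^arity, mixed-radix
// big-endian over the tuple's base states). R1 is over derived nodes,
// U1 over the reduced repertoire.
// [[Rcpp::export]]
NumericVector cpp_derived_profile(int n, int m, List tuples, List redTab,
                                  NumericMatrix R1, NumericMatrix U1) {
  double sized = std::pow((double)m, (double)n);
  if (sized > 2147483647.0) stop("state space too large for the kernel");
  int N = (int)(sized + 0.5);
  int nd = tuples.size();
  int mr = U1.nrow();
  std::vector<std::vector<int>> tp(nd);
  std::vector<std::vector<int>> rt(nd);
  for (int t = 0; t < nd; ++t) {
    tp[t] = as<std::vector<int>>(tuples[t]);
    rt[t] = as<std::vector<int>>(redTab[t]);
  }
  std::vector<double> cost((size_t)nd * nd * mr * mr);
  for (int a = 0; a < nd; ++a)
    for (int b = 0; b < nd; ++b) {
      double r = R1(a, b);
      for (int sa = 0; sa < mr; ++sa)
        for (int sb = 0; sb < mr; ++sb)
          cost[(((size_t)a * nd + b) * mr + sa) * mr + sb] =
            std::fabs(r - U1(sa, sb));
    }
  NumericVector out(N);
  std::vector<int> s(n, 0), ds(nd, 0);
  for (int j = 0; j < N; ++j) {
    for (int t = 0; t < nd; ++t) {
      int idx = 0;
      for (size_t q = 0; q < tp[t].size(); ++q) idx = idx * m + s[tp[t][q]];
      ds[t] = rt[t][idx];
    }
    double acc = 0.0;
    for (int a = 0; a < nd; ++a)
      for (int b = 0; b < nd; ++b)
        acc += cost[(((size_t)a * nd + b) * mr + ds[a]) * mr + ds[b]];
    out[j] = acc;
    for (int a = n - 1; a >= 0; --a) {
      if (++s[a] < m) break;
      s[a] = 0;
    }
  }
  return out;
}

// Joint <=-counts for multi-relational float entropy: for each queried
// state (0-based row of profiles), count the states whose profile is
// <= the query's, simultaneously in every column.
// [[Rcpp::export]]
NumericVector cpp_count_le_joint(NumericMatrix profiles, IntegerVector query) {
  int N = profiles.nrow(), L = profiles.ncol(), E = query.size();
  NumericVector out(E);
  for (int e = 0; e < E; ++e) {
    int qi = query[e];
    long cnt = 0;
    for (int j = 0; j < N; ++j) {
      bool ok = true;
      for (int l = 0; l < L; ++l)
        if (profiles(j, l) > profiles(qi, l)) { ok = false; break; }
      if (ok) ++cnt;
    }
    out[e] = (double)cnt;
  }
  return out;
}
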