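#include <Rcpp.h>
using namespace Rcpp;

// Degree-preserving (edge-switching) null for a binary sample x event
// matrix. A switch picks two 1-cells (r1,c1), (r2,c2) with distinct rows
// and columns and empty diagonal partners, and rotates them; every switch
// preserves all row and column sums. Draws form a Markov chain: n_swaps
// attempted switches between consecutive sampled matrices, starting from
// the observed matrix. For every unordered column pair the function
// returns the observed overlap and the number of sampled null matrices
// with overlap >= and <= the observed one. Uses R's RNG stream, so
// set.seed() upstream makes results reproducible.
// [[Rcpp::export(name = ".perm_pair_overlaps")]]
List perm_pair_overlaps(IntegerMatrix x, int n_perm, int n_swaps) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix m = clone(x);

  std::vector<int> one_r, one_c;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (m(i, j) == 1) { one_r.push_back(i); one_c.push_back(j); }
  int n_ones = (int) one_r.size();

  int n_pairs = nc * (nc - 1) / 2;
  IntegerVector obs(n_pairs), ge(n_pairs), le(n_pairs);
  IntegerVector pair_a(n_pairs), pair_b(n_pairs);
  {
    int k = 0;
    for (int a = 0; a < nc - 1; ++a)
      for (int b = a + 1; b < nc; ++b, ++k) {
        pair_a[k] = a; pair_b[k] = b;
        int ov = 0;
        for (int i = 0; i < nr; ++i) ov += m(i, a) * m(i, b);
        obs[k] = ov;
      }
  }

  if (n_ones < 2) {
    for (int k = 0; k < n_pairs; ++k) { ge[k] = n_perm; le[k] = n_perm; }
    return List::create(_["pair_a"] = pair_a, _["pair_b"] = pair_b,
                        _["observed"] = obs, _["n_ge"] = ge, _["n_le"] = le);
  }

  for (int p = 0; p < n_perm; ++p) {
    for (int s = 0; s < n_swaps; ++s) {
      int e1 = (int) (unif_rand() * n_ones);
      int e2 = (int) (unif_rand() * n_ones);
      if (e1 >= n_ones) e1 = n_ones - 1;
      if (e2 >= n_ones) e2 = n_ones - 1;
      int r1 = one_r[e1], c1 = one_c[e1];
      int r2 = one_r[e2], c2 = one_c[e2];
      if (r1 == r2 || c1 == c2) continue;
      if (m(r1, c2) == 1 || m(r2, c1) == 1) continue;
      m(r1, c1) = 0; m(r2, c2) = 0;
      m(r1, c2) = 1; m(r2, c1) = 1;
      one_c[e1] = c2; one_c[e2] = c1;
    }
    int k = 0;
    for (int a = 0; a < nc - 1; ++a)
      for (int b = a + 1; b < nc; ++b, ++k) {
        int ov = 0;
        for (int i = 0; i < nr; ++i) ov += m(i, a) * m(i, b);
        if (ov >= obs[k]) ++ge[k];
        if (ov <= obs[k]) ++le[k];
      }
  }

  return List::create(_["pair_a"] = pair_a, _["pair_b"] = pair_b,
                      _["observed"] = obs, _["n_ge"] = ge, _["n_le"] = le);
}

// Row and column sums after one chain of switches — used by tests to
// assert margin preservation on actual permutation draws.
// [[Rcpp::export(name = ".perm_margin_check")]]
List perm_margin_check(IntegerMatrix x, int n_perm, int n_swaps) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix m = clone(x);
  std::vector<int> one_r, one_c;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (m(i, j) == 1) { one_r.push_back(i); one_c.push_back(j); }
  int n_ones = (int) one_r.size();
  bool margins_ok = true;
  IntegerVector rs0(nr), cs0(nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j) rs0[i] += m(i, j);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) cs0[j] += m(i, j);

  for (int p = 0; p < n_perm && n_ones >= 2; ++p) {
    for (int s = 0; s < n_swaps; ++s) {
      int e1 = (int) (unif_rand() * n_ones);
      int e2 = (int) (unif_rand() * n_ones);
      if (e1 >= n_ones) e1 = n_ones - 1;
      if (e2 >= n_ones) e2 = n_ones - 1;
      int r1 = one_r[e1], c1 = one_c[e1];
      int r2 = one_r[e2], c2 = one_c[e2];
      if (r1 == r2 || c1 == c2) continue;
      if (m(r1, c2) == 1 || m(r2, c1) == 1) continue;
      m(r1, c1) = 0; m(r2, c2) = 0;
      m(r1, c2) = 1; m(r2, c1) = 1;
      one_c[e1] = c2; one_c[e2] = c1;
    }
    for (int i = 0; i < nr && margins_ok; ++i) {
      int rs = 0;
      for (int j = 0; j < nc; ++j) rs += m(i, j);
      if (rs != rs0[i]) margins_ok = false;
    }
    for (int j = 0; j < nc && margins_ok; ++j) {
      int cs = 0;
      for (int i = 0; i < nr; ++i) cs += m(i, j);
      if (cs != cs0[j]) margins_ok = false;
    }
  }
  return List::create(_["margins_ok"] = margins_ok, _["final"] = m);
}
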