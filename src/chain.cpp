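#include <Rcpp.h>
using namespace Rcpp;

// Advance a day-restricted checkerboard swap chain by `nswaps` swaps.
//
// Proposal law matches the R-level single_swap(): rejection-sample a
// same-day event pair and an ordered column pair until a checkerboard is
// found (uniform over valid quadruples); after `max_tries` failures fall
// back to exhaustive enumeration, and no-op (counted) when no checkerboard
// exists. Uses R's RNG stream, so results are reproducible under set.seed().
//
// pair_a / pair_b are 1-based row indices of the precomputed same-day event
// pairs (swap-invariant along the chain).
// [[Rcpp::export]]
List advance_chain_cpp(IntegerMatrix gbi, IntegerVector pair_a,
                       IntegerVector pair_b, int nswaps, int max_tries) {
  IntegerMatrix m = clone(gbi);
  const int npairs = pair_a.size(), nc = m.ncol();
  int n_noop = 0;
  if (npairs == 0 || nc < 2)
    return List::create(_["gbi"] = m, _["n_noop"] = nswaps);
  for (int s = 0; s < nswaps; ++s) {
    bool done = false;
    for (int t = 0; t < max_tries; ++t) {
      int j = (int)(unif_rand() * npairs); if (j >= npairs) j = npairs - 1;
      const int e1 = pair_a[j] - 1, e2 = pair_b[j] - 1;
      int a = (int)(unif_rand() * nc); if (a >= nc) a = nc - 1;
      int b = (int)(unif_rand() * nc); if (b >= nc) b = nc - 1;
      if (a == b) continue;
      if (m(e1, a) == 1 && m(e2, a) == 0 && m(e1, b) == 0 && m(e2, b) == 1) {
        m(e1, a) = 0; m(e2, a) = 1; m(e1, b) = 1; m(e2, b) = 0;
        done = true; break;
      }
    }
    if (done) continue;
    // exhaustive fallback: weight pairs by their checkerboard counts
    std::vector<double> w(npairs);
    double tot = 0.0;
    for (int j = 0; j < npairs; ++j) {
      const int e1 = pair_a[j] - 1, e2 = pair_b[j] - 1;
      int pos = 0, neg = 0;
      for (int c = 0; c < nc; ++c) {
        const int d = m(e1, c) - m(e2, c);
        if (d > 0) ++pos; else if (d < 0) ++neg;
      }
      w[j] = (double)pos * (double)neg;
      tot += w[j];
    }
    if (tot <= 0.0) { ++n_noop; continue; }
    double u = unif_rand() * tot;
    int j = 0;
    for (; j < npairs - 1; ++j) { u -= w[j]; if (u <= 0) break; }
    const int e1 = pair_a[j] - 1, e2 = pair_b[j] - 1;
    std::vector<int> pos, neg;
    for (int c = 0; c < nc; ++c) {
      const int d = m(e1, c) - m(e2, c);
      if (d > 0) pos.push_back(c); else if (d < 0) neg.push_back(c);
    }
    int ia = pos[(int)(unif_rand() * pos.size()) % pos.size()];
    int ib = neg[(int)(unif_rand() * neg.size()) % neg.size()];
    m(e1, ia) = 0; m(e2, ia) = 1; m(e1, ib) = 1; m(e2, ib) = 0;
  }
  return List::create(_["gbi"] = m, _["n_noop"] = n_noop);
}
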