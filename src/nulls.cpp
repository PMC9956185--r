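#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance for one community pair.
// d is the full patristic matrix; ia/ib hold 0-based row indices of the taxa
// present in each community; wa/wb are the within-community relative weights
// (already renormalised to sum to 1).
static double bmntd_pair(const NumericMatrix& d,
                         const std::vector<int>& ia,
                         const std::vector<int>& ib,
                         const NumericVector& wa,
                         const NumericVector& wb) {
  const int na = ia.size(), nb = ib.size();
  double s = 0.0;
  for (int i = 0; i < na; ++i) {
    double m = R_PosInf;
    const int ri = ia[i];
    for (int j = 0; j < nb; ++j) {
      const double v = d(ri, ib[j]);
      if (v < m) m = v;
    }
    s += wa[i] * m;
  }
  for (int j = 0; j < nb; ++j) {
    double m = R_PosInf;
    const int cj = ib[j];
    for (int i = 0; i < na; ++i) {
      const double v = d(ia[i], cj);
      if (v < m) m = v;
    }
    s += wb[j] * m;
  }
  return 0.5 * s;
}

// [[Rcpp::export]]
double cpp_bmntd(NumericMatrix d, IntegerVector ia, IntegerVector ib,
                 NumericVector wa, NumericVector wb) {
  std::vector<int> va(ia.begin(), ia.end()), vb(ib.begin(), ib.end());
  return bmntd_pair(d, va, vb, wa, wb);
}

// Null distribution of betaMNTD under taxa-label randomisation: abundances
// stay put, phylogenetic positions are permuted.  perms is an n_taxa x reps
// matrix; column r maps taxon t to tip position perms(t, r) (0-based).
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(NumericMatrix d, IntegerVector ia, IntegerVector ib,
                             NumericVector wa, NumericVector wb,
                             IntegerMatrix perms) {
  const int reps = perms.ncol();
  const int na = ia.size(), nb = ib.size();
  NumericVector out(reps);
  std::vector<int> pa(na), pb(nb);
  for (int r = 0; r < reps; ++r) {
    for (int i = 0; i < na; ++i) pa[i] = perms(ia[i], r);
    for (int j = 0; j < nb; ++j) pb[j] = perms(ib[j], r);
    out[r] = bmntd_pair(d, pa, pb, wa, wb);
  }
  return out;
}

// Sequential weighted sampling without replacement; uses R's RNG.
// w is consumed (chosen weights zeroed).  Fills out with 0-based indices.
static void sample_noreplace(int k, std::vector<double>& w, std::vector<int>& out) {
  const int n = w.size();
  double total = 0.0;
  for (int i = 0; i < n; ++i) total += w[i];
  out.resize(k);
  for (int draw = 0; draw < k; ++draw) {
    double u = unif_rand() * total;
    int pick = -1;
    double acc = 0.0;
    for (int i = 0; i < n; ++i) {
      if (w[i] <= 0.0) continue;
      acc += w[i];
      pick = i;
      if (u <= acc) break;
    }
    out[draw] = pick;
    total -= w[pick];
    w[pick] = 0.0;
  }
}

// One null community: draw `rich` taxa from the pool without replacement with
// probability proportional to occurrence frequency; each drawn taxon receives
// one individual (so the null community has exactly the observed richness),
// and the remaining `tot - rich` individuals are allocated across the drawn
// taxa by sampling with replacement, probability proportional to regional
// relative abundance.  Writes counts into x.
static void null_community(const NumericVector& occ, const NumericVector& pool,
                           int rich, int tot, std::vector<double>& x) {
  std::vector<double> w(occ.begin(), occ.end());
  std::vector<int> taxa;
  sample_noreplace(rich, w, taxa);
  std::vector<double> p(rich);
  double ps = 0.0;
  for (int i = 0; i < rich; ++i) { p[i] = pool[taxa[i]]; ps += p[i]; }
  for (int i = 0; i < rich; ++i) p[i] /= ps;
  std::vector<int> counts(rich);
  const int extra = tot - rich;
  if (extra > 0) {
    rmultinom(extra, p.data(), rich, counts.data());
  } else {
    std::fill(counts.begin(), counts.end(), 0);
  }
  std::fill(x.begin(), x.end(), 0.0);
  for (int i = 0; i < rich; ++i) x[taxa[i]] = counts[i] + 1.0;
}

// Null Bray-Curtis distribution for the Raup-Crick model: each rep assembles
// the two communities independently and returns their Bray-Curtis value.
// [[Rcpp::export]]
NumericVector cpp_rc_null(NumericVector occ, NumericVector pool,
                          int rich_a, int tot_a, int rich_b, int tot_b,
                          int reps) {
  const int n = occ.size();
  NumericVector out(reps);
  std::vector<double> xa(n), xb(n);
  for (int r = 0; r < reps; ++r) {
    null_community(occ, pool, rich_a, tot_a, xa);
    null_community(occ, pool, rich_b, tot_b, xb);
    double num = 0.0;
    for (int i = 0; i < n; ++i) num += std::abs(xa[i] - xb[i]);
    out[r] = num / (double(tot_a) + double(tot_b));
  }
  return out;
}
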