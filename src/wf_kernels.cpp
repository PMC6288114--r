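#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Wright-Fisher frequency kernels and the admixture meiosis kernel.
//
// Pre-admixture phases evolve allele frequencies only (binomial resampling
// is the exact marginal of the individual-based model under linkage
// equilibrium); sites fixed or lost everywhere are dropped and
// infinite-sites mutation injects new singletons each generation.  All
// randomness goes through the R RNG, so set.seed() makes runs reproducible.

// One population: evolve p for `gens` generations of binomial resampling
// with Poisson(inj_lambda) new singleton sites per generation.  Sites lost
// or fixed are dropped (monomorphic sites carry no information here).
// [[Rcpp::export]]
NumericVector wf_onepop(NumericVector p0, int two_n, int gens,
                        double inj_lambda) {
  std::vector<double> p(p0.begin(), p0.end());
  const double n2 = static_cast<double>(two_n);
  for (int g = 0; g < gens; ++g) {
    size_t keep = 0;
    for (size_t s = 0; s < p.size(); ++s) {
      double q = R::rbinom(n2, p[s]) / n2;
      if (q > 0.0 && q < 1.0) p[keep++] = q;
    }
    p.resize(keep);
    int k = static_cast<int>(R::rpois(inj_lambda));
    for (int j = 0; j < k; ++j) p.push_back(1.0 / n2);
  }
  return wrap(p);
}

// Two diverging populations sharing a site list.  Sites monomorphic for
// the same allele in both populations are dropped; mutation injects
// singletons privately into each population.
// [[Rcpp::export]]
List wf_twopop(NumericVector p0, int two_n, int gens, double inj_lambda) {
  std::vector<double> p1(p0.begin(), p0.end());
  std::vector<double> p2(p0.begin(), p0.end());
  const double n2 = static_cast<double>(two_n);
  for (int g = 0; g < gens; ++g) {
    size_t keep = 0;
    for (size_t s = 0; s < p1.size(); ++s) {
      double q1 = R::rbinom(n2, p1[s]) / n2;
      double q2 = R::rbinom(n2, p2[s]) / n2;
      bool mono_same = (q1 == 0.0 && q2 == 0.0) || (q1 == 1.0 && q2 == 1.0);
      if (!mono_same) {
        p1[keep] = q1;
        p2[keep] = q2;
        ++keep;
      }
    }
    p1.resize(keep);
    p2.resize(keep);
    int k1 = static_cast<int>(R::rpois(inj_lambda));
    for (int j = 0; j < k1; ++j) { p1.push_back(1.0 / n2); p2.push_back(0.0); }
    int k2 = static_cast<int>(R::rpois(inj_lambda));
    for (int j = 0; j < k2; ++j) { p1.push_back(0.0); p2.push_back(1.0 / n2); }
  }
  return List::create(_["p1"] = wrap(p1), _["p2"] = wrap(p2));
}

// Meiosis for one generation of the admixture phase.
//
// src: sites x haplotypes matrix of founder-haplotype ids (site-major so a
// haplotype is a contiguous column).  For gamete i and locus l the gamete
// copies the column `hapA[i]` (or `hapB[i]` if start_b(i,l) == 1) up to an
// optional crossover: bp(i,l) is the 1-based row index of the first site
// taken from the other parental haplotype, 0 for no crossover.  Free
// recombination between loci is encoded by the per-locus start_b coins.
// [[Rcpp::export]]
IntegerMatrix meiosis_gametes(IntegerMatrix src, IntegerVector hapA,
                              IntegerVector hapB, IntegerMatrix start_b,
                              IntegerMatrix bp, IntegerVector locus_first,
                              IntegerVector locus_last) {
  const int S = src.nrow();
  const int G = hapA.size();
  const int L = locus_first.size();
  IntegerMatrix out(Rcpp::no_init(S, G));
  const int *ps = src.begin();
  int *po = out.begin();
  for (int i = 0; i < G; ++i) {
    const int a = hapA[i] - 1, b = hapB[i] - 1;
    int *oc = po + static_cast<size_t>(i) * S;
    for (int l = 0; l < L; ++l) {
      const int s0 = locus_first[l] - 1;
      const int s1 = locus_last[l] - 1;
      if (s1 < s0) continue;            // empty locus
      const int first = start_b(i, l) ? b : a;
      const int second = start_b(i, l) ? a : b;
      int cut = bp(i, l);               // 1-based first site from `second`
      int cut0 = (cut == 0) ? (s1 + 1) : (cut - 1);
      if (cut0 < s0) cut0 = s0;
      if (cut0 > s1 + 1) cut0 = s1 + 1;
      const int *c1 = ps + static_cast<size_t>(first) * S;
      const int *c2 = ps + static_cast<size_t>(second) * S;
      if (cut0 > s0)
        std::memcpy(oc + s0, c1 + s0, sizeof(int) * (cut0 - s0));
      if (cut0 <= s1)
        std::memcpy(oc + cut0, c2 + cut0, sizeof(int) * (s1 - cut0 + 1));
    }
  }
  return out;
}

// Realize alleles from founder haplotypes: out(s, i) = founder(s, src(s, i)).
// [[Rcpp::export]]
IntegerMatrix realize_alleles(IntegerMatrix founder, IntegerMatrix src) {
  const int S = src.nrow();
  const int G = src.ncol();
  IntegerMatrix out(Rcpp::no_init(S, G));
  const int *pf = founder.begin();
  const int *pc = src.begin();
  int *po = out.begin();
  for (int i = 0; i < G; ++i) {
    const int *sc = pc + static_cast<size_t>(i) * S;
    int *oc = po + static_cast<size_t>(i) * S;
    for (int s = 0; s < S; ++s) {
      oc[s] = pf[static_cast<size_t>(sc[s] - 1) * S + s];
    }
  }
  return out;
}
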