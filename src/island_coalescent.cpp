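#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Structured coalescent for two demes under Wright's symmetric island model,
// with infinite-alleles mutation. Time is scaled in units of 2N generations
// per deme: within-deme coalescence rate 1 per lineage pair, migration rate
// M/2 per lineage (M = 4Nm), mutation rate theta/2 per lineage (theta = 4Nu).
//
// A lineage whose next backward event is a mutation determines the allele of
// every sampled chromosome beneath it that is not yet assigned (the mutation
// nearest the leaves wins under infinite alleles), so the lineage can be
// removed from the genealogy at that point. Chromosomes still unassigned when
// a single lineage remains inherit the ancestral allele (label 0); each
// mutation gets a fresh positive label.
//
// Uses R's RNG throughout so results are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector cpp_island_alleles(int n1, int n2, double M, double theta) {
  if (n1 < 1 || n2 < 1) stop("both demes need at least one sampled chromosome");
  if (M <= 0) stop("migration parameter M must be positive");
  if (theta < 0) stop("mutation parameter theta must be non-negative");

  int n = n1 + n2;
  IntegerVector alleles(n, NA_INTEGER);
  std::vector<int> deme;                 // deme of each active lineage
  std::vector<std::vector<int> > leaves; // sampled chromosomes below lineage
  deme.reserve(2 * n);
  leaves.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    deme.push_back(i < n1 ? 0 : 1);
    leaves.push_back(std::vector<int>(1, i));
  }
  int next_allele = 1;

  while (deme.size() > 1) {
    int k = (int) deme.size();
    int k1 = 0;
    for (int i = 0; i < k; ++i) if (deme[i] == 0) ++k1;
    int k2 = k - k1;
    double rc1 = k1 * (k1 - 1) / 2.0;
    double rc2 = k2 * (k2 - 1) / 2.0;
    double rm = k * M / 2.0;
    double ru = k * theta / 2.0;
    double tot = rc1 + rc2 + rm + ru;
    double u = unif_rand() * tot;

    if (u < ru) {
      // mutation: freshest mutation on this lineage fixes its leaves' allele
      int i = (int) (unif_rand() * k);
      if (i >= k) i = k - 1;
      for (size_t j = 0; j < leaves[i].size(); ++j)
        alleles[leaves[i][j]] = next_allele;
      ++next_allele;
      deme[i] = deme.back(); deme.pop_back();
      leaves[i].swap(leaves.back()); leaves.pop_back();
    } else if (u < ru + rm) {
      int i = (int) (unif_rand() * k);
      if (i >= k) i = k - 1;
      deme[i] = 1 - deme[i];
    } else {
      int target = (u < ru + rm + rc1) ? 0 : 1;
      int kd = target == 0 ? k1 : k2;
      // choose an ordered pair uniformly within the deme
      int a = (int) (unif_rand() * kd);
      int b = (int) (unif_rand() * (kd - 1));
      if (b >= a) ++b;
      int ia = -1, ib = -1, seen = 0;
      for (int i = 0; i < k; ++i) {
        if (deme[i] == target) {
          if (seen == a) ia = i;
          if (seen == b) ib = i;
          ++seen;
        }
      }
      leaves[ia].insert(leaves[ia].end(), leaves[ib].begin(), leaves[ib].end());
      deme[ib] = deme.back(); deme.pop_back();
      leaves[ib].swap(leaves.back()); leaves.pop_back();
    }
  }
  // survivors trace to the MRCA without mutation: ancestral allele
  if (!deme.empty())
    for (size_t j = 0; j < leaves[0].size(); ++j)
      alleles[leaves[0][j]] = 0;
  return alleles;
}

// Batch simulation of independent loci; theta may vary per locus (Fdist-style
// nulls spread simulated loci across the He range by varying mutation).
// Returns an n_loci x (n1 + n2) matrix of allele labels.
// [[Rcpp::export]]
IntegerMatrix cpp_island_loci(int n_loci, int n1, int n2, double M,
                              NumericVector theta) {
  if (n_loci < 1) stop("n_loci must be at least 1");
  if (theta.size() != n_loci && theta.size() != 1)
    stop("theta must have length 1 or n_loci");
  IntegerMatrix out(n_loci, n1 + n2);
  for (int l = 0; l < n_loci; ++l) {
    double th = theta.size() == 1 ? theta[0] : theta[l];
    IntegerVector a = cpp_island_alleles(n1, n2, M, th);
    for (int j = 0; j < n1 + n2; ++j) out(l, j) = a[j];
    if (l % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
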