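#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-time Wright-Fisher machinery behind the synthetic population-marker
// generator: a single ancestral deme is burnt in to infinite-alleles
// mutation-drift balance (allele-count resampling), a mine deme is founded
// from it, and the post-founding generations are simulated at chromosome
// level for the selected site plus its linked markers (genic selection in the
// mine deme only, symmetric migration, crossover without interference,
// infinite-alleles mutation). Unlinked markers evolve by count-based WF with
// migration. All randomness goes through R's RNG.

namespace {

typedef std::vector<double> Counts; // allele counts indexed by allele label

// drop extinct alleles so the vector stays at the stationary allele number;
// labels are identity classes only, so relabeling between generations is
// harmless within a single deme
void prune(Counts &c) {
  Counts keep;
  keep.reserve(c.size());
  for (size_t i = 0; i < c.size(); ++i)
    if (c[i] > 0) keep.push_back(c[i]);
  if (keep.empty()) keep.push_back(0);
  c.swap(keep);
}

// joint compaction for two demes sharing one label space
void prune_pair(Counts &a, Counts &b) {
  size_t K = std::max(a.size(), b.size());
  a.resize(K, 0); b.resize(K, 0);
  Counts ka, kb;
  ka.reserve(K); kb.reserve(K);
  for (size_t i = 0; i < K; ++i) {
    if (a[i] > 0 || b[i] > 0) { ka.push_back(a[i]); kb.push_back(b[i]); }
  }
  if (ka.empty()) { ka.push_back(0); kb.push_back(0); }
  a.swap(ka); b.swap(kb);
}

// multinomial resampling of twoN copies from the (possibly fractional)
// weights in c, via the conditional-binomial construction
void resample_counts(Counts &c, int twoN) {
  int K = (int) c.size();
  double tot = 0;
  for (int i = 0; i < K; ++i) tot += c[i];
  int n_rem = twoN;
  double p_rem = tot;
  for (int i = 0; i < K; ++i) {
    double ci = c[i];
    int draw = 0;
    if (n_rem > 0 && ci > 0)
      draw = (ci >= p_rem) ? n_rem
                           : (int) R::rbinom(n_rem, ci / p_rem);
    c[i] = draw;
    n_rem -= draw;
    p_rem -= ci;
  }
}

// a uniformly chosen copy mutates to a brand-new allele appended at the end
void mutate_one(Counts &c, int twoN) {
  double pick = unif_rand() * twoN;
  double acc = 0;
  for (size_t i = 0; i < c.size(); ++i) {
    acc += c[i];
    if (pick < acc && c[i] > 0) { c[i] -= 1; break; }
  }
  c.push_back(1);
}

// one neutral WF generation on allele counts: resampling followed by
// Binomial(twoN, u) fresh mutations (single-deme label space)
void wf_generation(Counts &c, int twoN, double u) {
  resample_counts(c, twoN);
  int nmut = (int) R::rbinom(twoN, u);
  for (int j = 0; j < nmut; ++j) mutate_one(c, twoN);
  prune(c);
}

int sample_from_counts(const Counts &c, double tot) {
  double pick = unif_rand() * tot, acc = 0;
  for (size_t i = 0; i < c.size(); ++i) {
    acc += c[i];
    if (pick < acc) return (int) i;
  }
  return (int) c.size() - 1;
}

struct LinkedDeme {
  // chromosome-level state: sel[i] is the selected-site allele (0/1) of
  // chromosome i; mark[l][i] the allele at linked marker l
  std::vector<int> sel;
  std::vector<std::vector<int> > mark;
};

// form one gamete from parent individual `ind` of deme `d` (chromosomes
// 2*ind, 2*ind+1); rint[j] is the crossover probability between adjacent
// sites j and j+1 in map order; site 0 is the selected locus
void make_gamete(const LinkedDeme &d, int ind, const std::vector<double> &rint,
                 int &sel_out, std::vector<int> &mark_out) {
  int c0 = 2 * ind, c1 = c0 + 1;
  int cur = unif_rand() < 0.5 ? c0 : c1;
  sel_out = d.sel[cur];
  int L = (int) d.mark.size();
  for (int l = 0; l < L; ++l) {
    if (unif_rand() < rint[l]) cur = (cur == c0) ? c1 : c0;
    mark_out[l] = d.mark[l][cur];
  }
}

} // namespace

// [[Rcpp::export]]
List cpp_sweep_sim(int N, NumericVector r_linked, int n_unlinked,
                   double u, double m, double s, int founder_copies,
                   int generations, int burnin,
                   int n_mine_ind, int n_off_ind,
                   double min_final_freq, int max_restarts) {
  if (N < 2) stop("N must be at least 2");
  int twoN = 2 * N;
  int n_linked = (int) r_linked.size();
  if (founder_copies < 1 || founder_copies > twoN)
    stop("founder_copies must be in [1, 2N]");
  if (2 * n_mine_ind > twoN || 2 * n_off_ind > twoN)
    stop("sample size exceeds deme size");

  // ---- ancestral pool at mutation-drift balance (one count vector per locus)
  int n_loci = n_linked + n_unlinked;
  std::vector<Counts> anc(n_loci, Counts(1, (double) twoN));
  for (int g = 0; g < burnin; ++g) {
    for (int l = 0; l < n_loci; ++l) wf_generation(anc[l], twoN, u);
    if (g % 200 == 0) Rcpp::checkUserInterrupt();
  }
  int next_allele = 0;
  for (int l = 0; l < n_loci; ++l)
    next_allele = std::max(next_allele, (int) anc[l].size());
  // marker alleles are reported as l * stride + label to keep loci distinct
  // in the flat mutation counter below; instead track one global counter and
  // relabel fresh mutations from it
  int mut_counter = next_allele;

  // crossover probabilities between adjacent sites; marker map positions are
  // the recombination fractions to the selected site, sorted ascending
  std::vector<double> dist(r_linked.begin(), r_linked.end());
  std::vector<int> ord(n_linked);
  for (int i = 0; i < n_linked; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return dist[a] < dist[b]; });
  std::vector<double> rint(n_linked);
  for (int i = 0; i < n_linked; ++i)
    rint[i] = i == 0 ? dist[ord[0]] : dist[ord[i]] - dist[ord[i - 1]];

  NumericVector traj(generations + 1);
  int restarts = 0;
  bool established = false;
  LinkedDeme mine, off;

  while (!established) {
    // ---- founding: realize chromosomes from the ancestral pool (linkage
    // equilibrium across marker loci), selected allele on founder_copies
    // randomly chosen mine chromosomes
    mine.sel.assign(twoN, 0);
    off.sel.assign(twoN, 0);
    mine.mark.assign(n_linked, std::vector<int>(twoN));
    off.mark.assign(n_linked, std::vector<int>(twoN));
    for (int i = 0; i < n_linked; ++i) {
      const Counts &c = anc[ord[i]];
      for (int j = 0; j < twoN; ++j) {
        mine.mark[i][j] = sample_from_counts(c, twoN);
        off.mark[i][j] = sample_from_counts(c, twoN);
      }
    }
    for (int placed = 0; placed < founder_copies;) {
      int j = (int) (unif_rand() * twoN);
      if (mine.sel[j] == 0) { mine.sel[j] = 1; ++placed; }
    }

    traj[0] = (double) founder_copies / twoN;
    LinkedDeme new_mine, new_off;
    for (int g = 1; g <= generations; ++g) {
      // parent-selection weights: mine deme only, genic (1+s) per A copy
      std::vector<double> wmine(N), cum(N);
      double wtot = 0;
      for (int i = 0; i < N; ++i) {
        int a = mine.sel[2 * i] + mine.sel[2 * i + 1];
        wmine[i] = std::pow(1.0 + s, a);
        wtot += wmine[i];
        cum[i] = wtot;
      }
      new_mine.sel.assign(twoN, 0);
      new_off.sel.assign(twoN, 0);
      new_mine.mark.assign(n_linked, std::vector<int>(twoN));
      new_off.mark.assign(n_linked, std::vector<int>(twoN));
      std::vector<int> gm(n_linked);
      for (int deme = 0; deme < 2; ++deme) {
        LinkedDeme &nd = deme == 0 ? new_mine : new_off;
        for (int child = 0; child < N; ++child) {
          // each child is a migrant from the other deme with probability m
          bool migrant = unif_rand() < m;
          int src = migrant ? 1 - deme : deme;
          const LinkedDeme &sd = src == 0 ? mine : off;
          for (int gam = 0; gam < 2; ++gam) {
            int ind;
            if (src == 0) { // mine parents drawn by fitness
              double pick = unif_rand() * wtot;
              ind = (int) (std::lower_bound(cum.begin(), cum.end(), pick) -
                           cum.begin());
              if (ind >= N) ind = N - 1;
            } else {
              ind = (int) (unif_rand() * N);
              if (ind >= N) ind = N - 1;
            }
            int sl;
            make_gamete(sd, ind, rint, sl, gm);
            int chrom = 2 * child + gam;
            nd.sel[chrom] = sl;
            for (int l = 0; l < n_linked; ++l) {
              int al = gm[l];
              if (unif_rand() < u) al = mut_counter++;
              nd.mark[l][chrom] = al;
            }
          }
        }
      }
      mine.sel.swap(new_mine.sel); mine.mark.swap(new_mine.mark);
      off.sel.swap(new_off.sel); off.mark.swap(new_off.mark);
      int cnt = 0;
      for (int j = 0; j < twoN; ++j) cnt += mine.sel[j];
      traj[g] = (double) cnt / twoN;
      if (g % 25 == 0) Rcpp::checkUserInterrupt();
    }
    established = traj[generations] >= min_final_freq;
    if (!established) {
      if (++restarts > max_restarts)
        stop("selected allele failed to establish in %d foundings; "
             "increase s, founder_copies or max_restarts", restarts);
    }
  }

  // ---- unlinked loci: count-based two-deme WF with migration, same length
  std::vector<Counts> umine(n_unlinked), uoff(n_unlinked);
  for (int l = 0; l < n_unlinked; ++l) {
    umine[l] = anc[n_linked + l];
    uoff[l] = anc[n_linked + l];
  }
  for (int g = 0; g < generations; ++g) {
    for (int l = 0; l < n_unlinked; ++l) {
      Counts &a = umine[l], &b = uoff[l];
      size_t K = a.size(); // demes share one label space (see prune_pair)
      Counts mixa(K), mixb(K);
      for (size_t i = 0; i < K; ++i) {
        mixa[i] = (1 - m) * a[i] + m * b[i];
        mixb[i] = (1 - m) * b[i] + m * a[i];
      }
      // resample each deme in the shared space (no per-deme label append)
      resample_counts(mixa, twoN);
      resample_counts(mixb, twoN);
      a = mixa; b = mixb;
      // fresh mutations get distinct shared labels
      int mut_a = (int) R::rbinom(twoN, u);
      int mut_b = (int) R::rbinom(twoN, u);
      for (int j = 0; j < mut_a; ++j) {
        mutate_one(a, twoN);
        b.push_back(0);
      }
      for (int j = 0; j < mut_b; ++j) {
        mutate_one(b, twoN);
        a.push_back(0);
      }
      prune_pair(a, b);
    }
  }

  // ---- sampling: individuals = chromosome pairs (2i, 2i+1); mine sample
  // from the mine deme, off sample from the off deme
  auto sample_linked = [&](const LinkedDeme &d, int n_ind, IntegerMatrix &out,
                           IntegerVector &selv, int row0) {
    std::vector<int> idx(N);
    for (int i = 0; i < N; ++i) idx[i] = i;
    for (int i = 0; i < n_ind; ++i) { // partial Fisher-Yates
      int j = i + (int) (unif_rand() * (N - i));
      std::swap(idx[i], idx[j]);
    }
    for (int i = 0; i < n_ind; ++i) {
      for (int c = 0; c < 2; ++c) {
        int chrom = 2 * idx[i] + c;
        int row = row0 + 2 * i + c;
        for (int l = 0; l < n_linked; ++l) out(row, l) = d.mark[l][chrom];
        selv[row] = d.sel[chrom];
      }
    }
  };
  int n_chrom_out = 2 * (n_mine_ind + n_off_ind);
  IntegerMatrix linked_out(n_chrom_out, n_linked);
  IntegerVector sel_out(n_chrom_out);
  sample_linked(mine, n_mine_ind, linked_out, sel_out, 0);
  sample_linked(off, n_off_ind, linked_out, sel_out, 2 * n_mine_ind);

  IntegerMatrix unlinked_out(n_chrom_out, n_unlinked);
  for (int l = 0; l < n_unlinked; ++l) {
    Counts cm = umine[l], co = uoff[l]; // draw without replacement
    double totm = 0, toto = 0;
    for (size_t i = 0; i < cm.size(); ++i) totm += cm[i];
    for (size_t i = 0; i < co.size(); ++i) toto += co[i];
    for (int j = 0; j < 2 * n_mine_ind; ++j) {
      int al = sample_from_counts(cm, totm);
      cm[al] -= 1; totm -= 1;
      unlinked_out(j, l) = al;
    }
    for (int j = 0; j < 2 * n_off_ind; ++j) {
      int al = sample_from_counts(co, toto);
      co[al] -= 1; toto -= 1;
      unlinked_out(2 * n_mine_ind + j, l) = al;
    }
  }

  return List::create(
      _["linked"] = linked_out, _["unlinked"] = unlinked_out,
      _["selected"] = sel_out, _["trajectory"] = traj,
      _["marker_order"] = IntegerVector(ord.begin(), ord.end()),
      _["restarts"] = restarts);
}
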