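---
title: "Hitchhiking, outlier nulls and fine mapping: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hitchhiking, outlier nulls and fine mapping: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweeplink)
library(dplyr)
```

`sweeplink` studies a single evolutionary scenario from four angles: a
population recently founded in a harsh habitat fixes a beneficial allele,
and alleles tightly linked to it — including, in the motivating system, a
hybrid-incompatibility allele — hitchhike to high frequency. This vignette
is the package's own account of the models it implements, the parameters
that matter, and the choices made where the design was genuinely open. It
states no empirical result that the test suite and `scripts/acceptance.R`
do not themselves compute.

## The deterministic hitchhiking model

Two biallelic loci on one chromosome: locus A carries the selected allele
`A` at frequency `p`, locus B the focal neutral allele `B` at frequency `U`.
The state is the four haplotype frequencies `x_AB, x_Ab, x_aB, x_ab`. A
generation applies, in order:

1. **Genic selection** on `A`: every `A`-haplotype is weighted by `1 + s`
   and the vector renormalised by the mean fitness `1 + s p`, so the
   selected-allele marginal follows `p' = p(1+s)/(1+sp)` regardless of the
   neutral locus.
2. **Recombination** at fraction `r`: the post-selection disequilibrium
   `D = x_AB x_ab - x_Ab x_aB` decays by `r`, moving `r D` between coupling
   and repulsion haplotypes.

This is the haploid-equivalent multiplicative form of the classical
two-locus hitchhiking model. Diploid dominance schemes are deliberately out
of scope: the model class analysed in the hitchhiking literature is the
multiplicative one, and the analytic cross-check below only exists for it.
The order "selection, then recombination" is stated explicitly because the
two orders differ at order `s·r`; swapping them changes `delta_U` by less
than the analytic tolerance everywhere we evaluate, but a definition is
needed for reproducibility.

Initial conditions are parameterised by `p0`, `U0`, and `u_p`, the frequency
of `B` among `A`-haplotypes at onset. `u_p = 1` with `p0 = 1/(2N)` is the
hard-sweep condition (one founding haplotype); `u_p < 1` with larger `p0`
describes soft sweeps from standing variation. Feasibility requires
`p0·u_p <= U0 <= 1 - p0·(1 - u_p)`; `init_haplotypes()` rejects anything
else, naming the violated bound. The normalised disequilibrium `D'` is
reported alongside so initial association can be read on the familiar
0.5–1.0 scale.

**Stopping rules.** `T_fix` is the first generation with `p > 0.99` — the
conventional operational definition of fixation time for a deterministic
recursion that approaches 1 only asymptotically. Runs stop at
`p > 1 - 1e-9` (`run_threshold`), which is where "the maximum `delta_U`"
is evaluated; with `U0 = 0.05`, `u_p = 1` and `r = 0` that maximum is
`1 - U0 = 0.95`. `max_generations` (default 100,000) guards the neutral
and weak-selection corners; an unfinished run is flagged `complete = FALSE`
with `T_fix = NA` rather than erroring.

**Analytic cross-check.** For the hard-sweep initial condition the
association surviving the sweep is `p0^(r/s)`, giving

```
delta_U = (1 - U0) * p0^(r/s)
```

`analytic_hard_sweep()` implements this closed form; the test suite holds
the recursion to within 0.02 of it over `s` in {0.05, 0.1, 0.25} and `r` in
[0, 0.005] at `p0 = 1/2000`. The agreement is a genuine check of both
routes, because the recursion never evaluates the power law and the power
law never iterates the recursion.

**Numerical guards.** Haplotype frequencies are clipped to 0 when they fall
in `(-1e-15, 0)` and the vector renormalised; anything more negative is an
error, since it indicates a broken state rather than roundoff. Frequencies
are conserved to 1e-12 per step (tested).

## Diversity summaries and the Fst estimator

Within-population variation is summarised as the allele count `Na` and
Nei's unbiased expected heterozygosity `He = n/(n-1) (1 - sum p_i^2)` over
`n` sampled chromosomes. Individuals missing at a locus are dropped for
that locus only, so chromosome counts vary across loci exactly as they do
in real fragment-length datasets.

Differentiation is the Weir–Cockerham (1984) variance-components estimator
(theta), with the components `a` (among populations), `b` (among
individuals within populations) and `c` (within individuals) summed over
all alleles of a multiallelic locus. This estimator was chosen because it
is the one the Fdist outlier literature builds on; negative estimates are
legitimate small-sample outcomes and are reported as computed, flagged
rather than clipped. The implementation is validated in the tests against
an independent hand transcription of the component formulas on a fixed
two-population fixture, and against the structural facts that theta is 1
for fixed alternative alleles, near 0 for identical populations, and
invariant to allele relabeling.

## The island-model coalescent null

Outlier detection needs a null distribution for (He, Fst) pairs under
neutrality. Following the Fdist approach, loci are simulated under a
two-deme structured coalescent with Wright's symmetric island-model
migration and infinite-alleles mutation — the natural mutation model for
fragment-length markers, where each mutation creates a novel allele. Time
is scaled in units of `2N` generations per deme: coalescence at rate 1 per
within-deme lineage pair, migration at `M/2 = 2Nm` per lineage, mutation at
`theta/2 = 2Nu` per lineage. The infinite-alleles structure permits an
exact simplification: the first mutation encountered backward in time on a
lineage determines the allele of every unassigned sample below it, so the
lineage can be removed at that point; samples reaching the final common
ancestor unassigned share the ancestral allele.

**Spreading the null over He.** Fdist-style conditioning needs null loci
across the whole heterozygosity range. Mutation rates differ across real
markers, so `theta` is drawn log-uniformly per simulated locus from a
configurable range (default 0.05–10, spanning He from near 0 to ~0.9).

**Calibration.** The migration parameter is calibrated by bisection on
`log10(M)` over [1e-3, 1e4] so that the simulated mean Fst (over polymorphic
loci, 5,000 per evaluation by default) matches the neutral target — the
mean Weir–Cockerham Fst of the markers unlinked to the candidate region.
The final null (default 50,000 loci; 20,000 in the heavier tests) must land
within ±0.01 of the target. A target at or below the panmixia floor drives
`M` to its upper bound and is flagged; a target above the simulated value
at `M = 1e-3` is a calibration failure with diagnostics. The simulator is
cross-checked in the tests against a frozen mean-Fst value computed with an
independent coalescent engine at identical scaled parameters.

**Conditional p-values.** Each observed locus is compared to null loci
whose pooled He lies within ±0.05; the p-value is the upper-tail fraction
with null Fst at least the observed value. Windows widen by 0.05 (with a
warning) until they hold at least 500 null loci, so p-values are never
computed from a handful of points. Significance is flagged at 0.025 and
0.0025, the two conventional thresholds for this design. On loci drawn
from the null itself these p-values are uniform (tested: the flagged
fraction at 0.025 is 0.025 ± 0.01 over 10,000 loci) — which also means a
set of truly neutral markers is *expected* to show false flags at the
nominal rate. The end-to-end recovery test therefore requires the unlinked
flag count to stay within the binomial 95% bound for the nominal rate
(at most 1 of 11), and none at the stricter 0.0025 level, rather than
literal zero.

## Backcross fine mapping

In a backcross design the recombination fraction to a dominant trait locus
equals the recombinant fraction, so the map distance is `100·k/n` cM with
an exact Clopper–Pearson binomial CI. Recombinant calling compares each
individual's focal-marker genotype (`H` heterozygous introgression, `A`
homozygous recurrent) with the genotype implied by its phenotype under full
penetrance; phenotyping error is handled operationally, through the
replicate-confirmation policy (default: every replicate genotype and
phenotype must reproduce the discordant state; a majority policy is
available). The all-replicates policy is a declared convention — the
motivating study reports that repeated assays cut putative recombinants by
more than half without stating the rule.

Breakpoints are imputed as the open interval between the flanking
discordant informative markers; missing genotypes inherit the surrounding
run's state, or stay "unknown" between discordant markers. Marker-order
indices are 1-based; physical position labels are annotations only, never
used numerically, because the region such designs target is typically
unassembled. Double recombinants are retained but flagged. Locus
localization intersects per-recombinant half-interval constraints (the
locus lies on the side of each breakpoint matching the phenotype-implied
genotype) and errors on an empty intersection, naming the conflicting
individuals.

## Inviability analytics

Blocks of (by default) 60 seedlings are scored for the count with majority
necrotic tissue; per-line rates are replicate `n_inviable/block_size`
values. Carrier classification uses a single threshold at 0.30 — the
midpoint of the gap between the two empirically observed bands (roughly
5–15% background inviability vs 45–62% for carrier crosses) — with an
ambiguous zone of ±0.05 around it. Line comparisons use the
Wilcoxon/Mann–Whitney rank-sum with midranks, tie-corrected variance and a
continuity correction (the z form matches how such comparisons are
reported); for combined samples of 10 or fewer, the exact two-sided
p-value from full enumeration is reported alongside, and the tests verify
exact-mode agreement with enumeration for every layout up to combined n of
8. Reciprocal-cross asymmetry is a Pearson chi-square (1 df, no Yates
correction — the convention for these counts) on the 2×2 direction ×
viable/inviable table, with expected inviables allocated proportionally to
seedlings scored.

## What the generators emulate — and what they do not

`gen_mapping_population()` simulates the informative gametes of a
near-isogenic backcross: interval-specific crossover probabilities without
interference (immaterial at the sub-centimorgan distances involved),
dominant phenotype from the true trait genotype, per-replicate phenotyping
error, and truth labels for every crossover. The default map places the
founding marker 0.83 cM and the closest marker 0.32 cM from the trait
locus, with 4,340 individuals.

`gen_population_markers()` is a forward-time Wright–Fisher emulation of the
mine/off-mine design: an ancestral deme is burnt in to infinite-alleles
mutation-drift balance (allele-count resampling, default `10N`
generations); the mine deme is founded from it; a beneficial allele (one
copy by default — a hard sweep) is selected at `s = 0.25` in the mine deme
only, with symmetric migration `m = 0.01`, for 150 generations — the age of
the emulated habitat. Markers linked to the selected site (defaults at the
0.32–0.83 cM distances above) are simulated at chromosome level with
recombination and mutation; unlinked markers evolve by count-based WF with
migration. Because the emulated population is essentially fixed for the
selected allele, founding is re-drawn (bounded retries) when the allele is
lost to drift — the generator conditions on establishment, as the observed
data do.

Two generator choices deserve emphasis:

* **Deme size `N = 4000`.** At fixed `theta = 4Nu` (default 4, for
  equilibrium He near 0.8), `N` determines the per-generation mutation rate
  `u = theta/(4N)`. With `N` as small as 1,000, `u = 1e-3` regenerates
  heterozygosity of order `2ut ≈ 0.3` at swept loci within 150 generations
  and erases the sweep footprint; `N = 4000` keeps `u` at a realistic
  2.5e-4 for fragment-length markers, and the default scenario then shows
  the expected contrast (mine-sample He roughly halved at linked loci, Fst
  elevated only there).
* **Linkage equilibrium at founding.** Founders' marker alleles are drawn
  independently across loci from the ancestral pool. Real pericentromeric
  regions carry ancestral LD; the hard-sweep signature does not depend on
  it, but soft-sweep scenarios with structured founding haplotypes are
  outside what this generator can represent.

Consequently, passing tests demonstrate internal consistency and correct
recovery under the generator's assumptions — neutral equilibrium
demography, symmetric migration, no selection at the markers themselves,
no genotyping error in the population samples. They do not demonstrate
robustness to demographic model misspecification, mutation-model
violations (e.g. size homoplasy in fragment lengths), or ancestral LD.

`gen_inviability_blocks()` draws block counts binomially around per-line
true rates; the default 18-line specification mirrors the bimodal band
structure (nine lines per band, 2–8 replicate blocks each).

## Problem sizes, rounding, and the pipeline

The test suite runs the heavier simulations at deliberately chosen desk
scales: 20,000-locus nulls for calibration checks, 10,000 loci for p-value
uniformity, 200 seeded replicates for map-distance coverage at
`r` in {0.003, 0.008} and n = 4,000, and the full default scenario for the
end-to-end recovery run. `run_pipeline()` chains the stages with one global
seed fanned out as `seed + 1000 × stage index`, writes a manifest
(configuration, versions, seed, timings), and rounds report fields for
byte-stable text output: centimorgans to 2 decimals, He and Fst to 3,
p-values to 3 significant figures.

## Known limitations

* The hitchhiking model is deterministic and biallelic: no drift at the
  selected locus, no interference among multiple sweeping sites, no
  dominance. These are the standard simplifications of the model class, and
  the package's scope ends where they fail.
* The analytic hard-sweep solution is an approximation whose error grows
  with `r/s`; beyond `r/s ≈ 0.2` only the recursion should be trusted.
* The island-model null assumes equilibrium and symmetric migration. A
  very recently founded deme violates equilibrium; mean-matching on
  unlinked loci absorbs much of that in practice (and is exactly what the
  Fdist approach prescribes), but the tail shape is still the equilibrium
  model's.
* Genepop parsing covers the standard dialect (2- or 3-digit codes, POP
  blocks); exotic variants are rejected with line numbers rather than
  guessed at.
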