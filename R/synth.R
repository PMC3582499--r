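## Seeded generators that emulate the three study designs: a large backcross
## mapping population, mine/off-mine population marker samples shaped by a
## selective sweep, and replicate hybrid-inviability blocks. Each generator
## is a pure function of its arguments including the seed.

#' Default marker-and-trait map for the mapping-population generator
#'
#' A chain of fragment-length markers around a dominant tolerance locus; the
#' `r_next` column holds the recombination fraction to the next locus in
#' order. Distances emulate a fine-mapping design in which the founding
#' marker sits 0.83 cM from the trait locus and the closest marker 0.32 cM.
#'
#' @return A tibble with columns `locus`, `type` (`"marker"`/`"trait"`),
#'   `r_next`.
#' @export
default_map_loci <- function() {
  tibble(
    locus = c("M242", "S530", "S364", "S167", "S037", "TRAIT"),
    type = c(rep("marker", 5), "trait"),
    # cumulative distances to the trait locus: 0.83, 0.67, 0.46, 0.35, 0.32 cM
    r_next = c(0.0016, 0.0021, 0.0011, 0.0003, 0.0032, NA))
}

#' Generate a backcross mapping population with truth labels
#'
#' Simulates the informative gametes of a near-isogenic backcross: each
#' individual receives one recombinant gamete from the heterozygous parent,
#' built locus-by-locus with interval-specific crossover probabilities and no
#' interference, and a non-recombinant gamete from the recurrent parent.
#' Genotypes are therefore `"H"` (heterozygous introgression) or `"A"`
#' (homozygous recurrent). The binary tolerance phenotype follows the true
#' trait-locus genotype (dominant model) and is flipped independently per
#' replicate with probability `phenotyping_error`.
#'
#' @param n Number of individuals (default 4,340, the emulated design size).
#' @param loci Map tibble as in [default_map_loci()]; exactly one `"trait"`
#'   row, not at the margin-less extreme of an empty map.
#' @param phenotyping_error Per-replicate probability of a wrong phenotype
#'   call (default 0).
#' @param replicate_count Phenotype replicates per individual (default 2).
#' @param missing_rate Per-genotype missing-data probability (default 0).
#' @param seed RNG seed; identical seeds give identical output.
#' @return A list with `genotypes` (tibble: `individual`, `marker`,
#'   `genotype`), `phenotypes` (tibble: `individual`, `replicate`,
#'   `tolerant`), `truth` (tibble: `individual`, per-locus true states and
#'   `crossover_<interval>` logicals), and `loci`.
#' @export
#' @examples
#' pop <- gen_mapping_population(n = 500, seed = 42)
#' head(pop$genotypes)
gen_mapping_population <- function(n = 4340, loci = default_map_loci(),
                                   phenotyping_error = 0,
                                   replicate_count = 2,
                                   missing_rate = 0, seed = NULL) {
  if (sum(loci$type == "trait") != 1)
    abort("`loci` must contain exactly one trait locus")
  if (which(loci$type == "trait") == 0)
    abort("trait locus outside the marker range")
  if (!is.null(seed)) withr::local_seed(seed)
  L <- nrow(loci)
  r_int <- loci$r_next[-L]
  if (any(is.na(r_int) | r_int < 0 | r_int > 0.5))
    abort("`r_next` must be in [0, 0.5] for all but the last locus")

  # recombinant gamete from the heterozygous parent: start state is a fair
  # coin, crossovers per interval are independent Bernoulli(r)
  start <- rbinom(n, 1, 0.5)
  cross <- matrix(rbinom(n * (L - 1), 1,
                         rep(r_int, each = n)), nrow = n)
  states <- matrix(0L, n, L)
  states[, 1] <- start
  for (j in 2:L) states[, j] <- (states[, j - 1] + cross[, j - 1]) %% 2L
  geno_chr <- ifelse(states == 1L, "H", "A")

  trait_col <- which(loci$type == "trait")
  tol_true <- states[, trait_col] == 1L

  ids <- sprintf("ind_%04d", seq_len(n))
  marker_loci <- loci$locus[loci$type == "marker"]
  genotypes <- tibble(
    individual = rep(ids, times = length(marker_loci)),
    marker = rep(marker_loci, each = n),
    genotype = as.vector(geno_chr[, loci$type == "marker"]))
  if (missing_rate > 0) {
    drop <- runif(nrow(genotypes)) < missing_rate
    genotypes$genotype[drop] <- NA_character_
  }

  phenotypes <- tibble(
    individual = rep(ids, each = replicate_count),
    replicate = rep(seq_len(replicate_count), times = n),
    tolerant = rep(tol_true, each = replicate_count))
  if (phenotyping_error > 0) {
    flip <- runif(nrow(phenotypes)) < phenotyping_error
    phenotypes$tolerant <- xor(phenotypes$tolerant, flip)
  }

  truth <- tibble(individual = ids, tolerant_true = tol_true)
  for (j in seq_len(L - 1)) {
    truth[[paste0("crossover_", loci$locus[j], "_", loci$locus[j + 1])]] <-
      cross[, j] == 1L
  }
  truth$n_breakpoints <- rowSums(cross)
  list(genotypes = genotypes, phenotypes = phenotypes, truth = truth,
       loci = loci)
}

#' Generate mine / off-mine marker samples shaped by a selective sweep
#'
#' Forward-time Wright-Fisher emulation of a recently founded mine
#' population: an ancestral deme is burnt in to infinite-alleles
#' mutation-drift balance; the mine deme is founded from it and a beneficial
#' allele (`founder_copies` copies; 1 = hard sweep) is selected with
#' coefficient `s` in the mine deme only while symmetric migration `m`
#' connects the demes for `generations` generations. Markers linked to the
#' selected site (recombination fractions `r_linked`) are simulated at
#' chromosome level; unlinked markers evolve independently. Founding is
#' re-drawn until the selected allele reaches `min_final_freq` in the mine
#' deme (the emulated population is near-fixed for the selected allele).
#' Samples are returned as diploid genotypes for one mine and two off-mine
#' population labels.
#'
#' @param N Diploid deme size (default 4,000). At fixed `theta = 4 N u`,
#'   `N` sets the per-generation mutation rate `u`; the default keeps `u`
#'   near 2.5e-4 so diversity regenerated over the 150 post-founding
#'   generations stays realistic for fragment-length markers.
#' @param n_mine,n_off Individuals sampled from the mine and off-mine demes
#'   (defaults 108 and 72; the off-mine sample is split 33/39 between two
#'   population labels).
#' @param r_linked Recombination fractions of the linked markers to the
#'   selected site (default eight values in the 0.003-0.008 range).
#' @param n_unlinked Number of unlinked markers (default 11).
#' @param theta Scaled mutation rate `4 N u` (default 4, giving equilibrium
#'   heterozygosity near 0.8).
#' @param m Symmetric per-generation migration probability (default 0.01).
#' @param s Selection coefficient in the mine deme (default 0.25; 0 disables
#'   the sweep and skips the establishment condition).
#' @param founder_copies Copies of the selected allele at founding
#'   (default 1, a hard sweep; larger values emulate soft sweeps).
#' @param generations Post-founding generations (default 150).
#' @param burnin Ancestral burn-in generations (default `10 * N`).
#' @param min_final_freq Required final mine frequency of the selected
#'   allele (default 0.9; ignored when `s = 0`).
#' @param max_restarts Foundings attempted before giving up (default 200).
#' @param seed RNG seed.
#' @return A list with `markers` (long tibble: `population`, `individual`,
#'   `locus`, `allele_1`, `allele_2`, `locus_class`), `truth` (list:
#'   `trajectory` tibble of the mine selected-allele frequency, `r_linked`,
#'   `restarts`, `sample_selected` genotypes at the selected site).
#' @export
gen_population_markers <- function(N = 4000, n_mine = 108, n_off = 72,
                                   r_linked = c(0.0083, 0.0083, 0.0083,
                                                0.0083, 0.0067, 0.0046,
                                                0.0035, 0.0032),
                                   n_unlinked = 11, theta = 4, m = 0.01,
                                   s = 0.25, founder_copies = 1,
                                   generations = 150, burnin = 10 * N,
                                   min_final_freq = 0.9, max_restarts = 200,
                                   seed = NULL) {
  if (any(r_linked <= 0 | r_linked > 0.5))
    abort("`r_linked` must lie in (0, 0.5]")
  if (founder_copies < 1 || founder_copies > 2 * N)
    abort(sprintf("infeasible founder frequency: founder_copies must be in [1, %d]",
                  2 * N))
  if (!is.null(seed)) withr::local_seed(seed)
  u <- theta / (4 * N)
  sim <- cpp_sweep_sim(
    as.integer(N), as.numeric(r_linked), as.integer(n_unlinked),
    u, m, s, as.integer(founder_copies),
    as.integer(generations), as.integer(burnin),
    as.integer(n_mine), as.integer(n_off),
    if (s > 0) min_final_freq else 0, as.integer(max_restarts))

  # chromosome rows: mine individuals first, then off; map the sorted linked
  # columns back to the input order of r_linked
  n_linked <- length(r_linked)
  linked <- sim$linked[, order(sim$marker_order + 1L), drop = FALSE]
  loci_names <- c(sprintf("L%02d_link", seq_len(n_linked)),
                  sprintf("U%02d_unlink", seq_len(n_unlinked)))
  # allele labels are shifted to start at 1 (0 is the missing code in the
  # TSV and Genepop dialects)
  all_alleles <- cbind(linked, sim$unlinked) + 1L

  n_off1 <- floor(n_off * 33 / 72)
  pop_of_ind <- c(rep("mine", n_mine), rep("off1", n_off1),
                  rep("off2", n_off - n_off1))
  ids <- sprintf("%s_%03d", pop_of_ind,
                 c(seq_len(n_mine), seq_len(n_off1),
                   seq_len(n_off - n_off1)))
  a1 <- all_alleles[seq(1, nrow(all_alleles), by = 2), , drop = FALSE]
  a2 <- all_alleles[seq(2, nrow(all_alleles), by = 2), , drop = FALSE]
  n_ind <- length(ids)
  markers <- tibble(
    population = rep(pop_of_ind, times = length(loci_names)),
    individual = rep(ids, times = length(loci_names)),
    locus = rep(loci_names, each = n_ind),
    allele_1 = as.integer(a1),
    allele_2 = as.integer(a2),
    locus_class = rep(c(rep("linked", n_linked),
                        rep("unlinked", n_unlinked)), each = n_ind))

  truth <- list(
    trajectory = tibble(generation = seq_along(sim$trajectory) - 1L,
                        p_mine = as.numeric(sim$trajectory)),
    r_linked = r_linked,
    restarts = sim$restarts,
    sample_selected = as.integer(sim$selected))
  list(markers = markers, truth = truth)
}

#' Default line specification for the inviability-block generator
#'
#' Eighteen lines emulating the assay design: nine tolerant carrier lines
#' with true inviability rates spread over 0.45-0.62 and nine nontolerant
#' non-carrier lines over 0.05-0.15, with 2-8 replicate blocks each.
#'
#' @return A tibble with columns `line`, `tolerance_class`, `true_rate`,
#'   `n_blocks`.
#' @export
default_line_specs <- function() {
  tibble(
    line = sprintf("line_%02d", 1:18),
    tolerance_class = rep(c("tolerant", "nontolerant"), each = 9),
    true_rate = c(seq(0.45, 0.62, length.out = 9),
                  seq(0.05, 0.15, length.out = 9)),
    n_blocks = rep(c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 4L, 3L), 2))
}

#' Generate hybrid-inviability blocks with truth labels
#'
#' Each line contributes `n_blocks` blocks of `block_size` seedlings with
#' `n_inviable ~ Binomial(block_size, true_rate)`.
#'
#' @param line_specs Tibble as in [default_line_specs()].
#' @param block_size Seedlings scored per block (default 60).
#' @param seed RNG seed.
#' @return A list with `blocks` (tibble: `line`, `tolerance_class`,
#'   `direction`, `block_size`, `n_inviable`) and `truth` (the line specs).
#' @export
#' @examples
#' gen_inviability_blocks(seed = 3)$blocks
gen_inviability_blocks <- function(line_specs = default_line_specs(),
                                   block_size = 60, seed = NULL) {
  if (any(line_specs$true_rate < 0 | line_specs$true_rate > 1))
    abort("`true_rate` must lie in [0, 1]")
  if (block_size <= 0) abort("`block_size` must be positive")
  if (!is.null(seed)) withr::local_seed(seed)
  blocks <- line_specs %>%
    dplyr::rowwise() %>%
    dplyr::reframe(
      line = .data$line,
      tolerance_class = .data$tolerance_class,
      block = seq_len(.data$n_blocks),
      block_size = .env$block_size,
      n_inviable = rbinom(.data$n_blocks, .env$block_size, .data$true_rate))
  list(blocks = as_tibble(blocks), truth = line_specs)
}
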