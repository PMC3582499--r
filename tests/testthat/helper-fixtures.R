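# Shared fixtures, built in code.

# Two-population genotype fixture with allele counts {8 A, 2 B} vs {2 A, 8 B}
# (A = 1, B = 2), realized as AA,AA,AA,AB,AB and BB,BB,BB,AB,AB.
wc_fixture <- function() {
  tibble::tibble(
    population = rep(c("p1", "p2"), each = 5),
    individual = sprintf("i%02d", 1:10),
    locus = "loc",
    allele_1 = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 1L, 1L),
    allele_2 = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
}

# Published per-marker diversity values for the eight markers linked to the
# selected region: allele counts and expected heterozygosities per population.
linked_marker_table <- function() {
  tibble::tibble(
    locus = c("Sc103_749kb", "Sc86_144kb", "Sc86_387kb", "Sc341_99kb",
              "Sc84_530kb", "Sc84_364kb", "Sc84_167kb", "Sc84_37kb"),
    locus_class = "linked",
    na_off = c(13, 11, 4, 6, 16, 7, 17, 7),
    na_mine = c(9, 7, 2, 7, 9, 3, 4, 3),
    he_off = c(0.841, 0.848, 0.139, 0.712, 0.880, 0.716, 0.866, 0.813),
    he_mine = c(0.684, 0.738, 0.010, 0.689, 0.501, 0.121, 0.479, 0.349))
}

# reshape the table above into the locus_stats() layout
linked_marker_stats <- function() {
  tab <- linked_marker_table()
  dplyr::bind_rows(
    tibble::tibble(locus = tab$locus, locus_class = "linked",
                   population = "off", n_alleles = tab$na_off,
                   exp_het = tab$he_off),
    tibble::tibble(locus = tab$locus, locus_class = "linked",
                   population = "mine", n_alleles = tab$na_mine,
                   exp_het = tab$he_mine))
}

# small ordered-genotype helper for breakpoint tests
geno_df <- function(..., markers = NULL) {
  rows <- list(...)
  if (is.null(markers)) markers <- paste0("m", seq_along(rows[[1]]))
  purrr::imap_dfr(rows, function(g, i) {
    tibble::tibble(individual = paste0("ind", i), marker = markers,
                   genotype = g)
  })
}

# association-test fixture: n_H tolerant H individuals, n_A nontolerant A
# individuals, with `discordant` of the H group flipped to nontolerant and
# the same number of the A group flipped to tolerant
make_assoc_data <- function(n_H, n_A, discordant = 0) {
  ids <- sprintf("i%03d", seq_len(n_H + n_A))
  tol <- c(rep(TRUE, n_H), rep(FALSE, n_A))
  if (discordant > 0) {
    tol[seq_len(discordant)] <- FALSE
    tol[n_H + seq_len(discordant)] <- TRUE
  }
  list(
    geno = tibble::tibble(individual = ids, marker = "mk",
                          genotype = rep(c("H", "A"), c(n_H, n_A))),
    phen = tibble::tibble(individual = ids, tolerant = tol))
}

# independent scalar recursion for the selected-allele marginal
odds_recursion_p <- function(s, p0, n_gen) {
  o <- p0 / (1 - p0)
  p <- numeric(n_gen + 1)
  p[1] <- p0
  for (t in seq_len(n_gen)) {
    o <- o * (1 + s)
    p[t + 1] <- o / (1 + o)
  }
  p
}
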