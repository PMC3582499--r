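## Between-population differentiation: Weir & Cockerham (1984) variance
## components, summed over alleles of a multiallelic codominant locus.

# core estimator on two populations given per-individual genotype matrices
# (n_i x 2 allele labels); returns theta plus the variance components
wc_theta <- function(genos) {
  r <- length(genos)
  n <- vapply(genos, nrow, integer(1))
  if (any(n < 1)) abort("every population needs at least one individual")
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  if (nbar <= 1 || nc <= 0)
    abort("Weir-Cockerham estimator needs more than one individual per population")
  alleles <- sort(unique(unlist(genos)))
  a_sum <- b_sum <- c_sum <- 0
  for (al in alleles) {
    p_i <- vapply(genos, function(g) mean(g == al), numeric(1))
    h_i <- vapply(genos, function(g) mean(xor(g[, 1] == al, g[, 2] == al)),
                  numeric(1))
    pbar <- sum(n * p_i) / sum(n)
    s2 <- sum(n * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h_i) / sum(n)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    a_sum <- a_sum + a
    b_sum <- b_sum + b
    c_sum <- c_sum + cc
  }
  denom <- a_sum + b_sum + c_sum
  list(theta = if (denom == 0) NA_real_ else a_sum / denom,
       a = a_sum, b = b_sum, c = c_sum)
}

#' Weir-Cockerham Fst per locus for a two-population contrast
#'
#' Computes the Weir & Cockerham (1984) variance-components estimator of Fst
#' (theta) for every locus of a long marker table, summing the components over
#' alleles. Exactly two populations must remain after optional pooling;
#' individuals missing at a locus are dropped for that locus only. Negative
#' estimates are reported as computed but flagged. The pooled-sample unbiased
#' expected heterozygosity is returned alongside for conditioning in outlier
#' tests.
#'
#' @inheritParams locus_stats
#' @param pools Optional named list mapping a new population label to the old
#'   labels it absorbs, e.g. `list(off = c("off1", "off2"))`. Applied before
#'   the two-population check.
#' @return A tibble with columns `locus` (plus `locus_class` if present),
#'   `fst`, `he_pooled`, `n_chrom_1`, `n_chrom_2`, `negative`.
#' @export
#' @examples
#' d <- gen_population_markers(N = 100, burnin = 200, n_mine = 20,
#'                             n_off = 20, seed = 2)
#' wc_fst(d$markers, pools = list(off = c("off1", "off2")))
wc_fst <- function(data, pools = NULL) {
  if (!is.null(pools)) data <- pool_populations(data, pools)
  pops <- sort(unique(data$population))
  if (length(pops) != 2)
    abort(sprintf("Fst needs exactly two populations, got %d", length(pops)))
  keep_class <- "locus_class" %in% names(data)
  data %>%
    dplyr::group_by(.data$locus) %>%
    dplyr::group_modify(function(d, key) {
      d <- dplyr::filter(d, !is.na(.data$allele_1) & !is.na(.data$allele_2))
      genos <- lapply(pops, function(p) {
        as.matrix(d[d$population == p, c("allele_1", "allele_2")])
      })
      if (any(vapply(genos, nrow, integer(1)) < 1))
        abort(sprintf("locus %s has no data in one of the populations",
                      key$locus))
      est <- wc_theta(genos)
      pooled <- c(d$allele_1, d$allele_2)
      out <- tibble(
        fst = est$theta,
        he_pooled = expected_het(pooled),
        n_chrom_1 = 2L * nrow(genos[[1]]),
        n_chrom_2 = 2L * nrow(genos[[2]]),
        negative = !is.na(est$theta) && est$theta < 0)
      if (keep_class) out$locus_class <- d$locus_class[1]
      out
    }) %>%
    dplyr::ungroup()
}

#' Pool populations under new labels
#'
#' @inheritParams locus_stats
#' @param pools Named list: each element gives the old population labels that
#'   are merged under the element's name.
#' @return The data with `population` recoded.
#' @export
pool_populations <- function(data, pools) {
  for (new_label in names(pools)) {
    data$population[data$population %in% pools[[new_label]]] <- new_label
  }
  data
}

# fast path used by the island-model null: allele labels of a simulated
# locus, consecutive chromosomes paired into diploids
fst_he_from_chromosomes <- function(alleles, n1, n2) {
  g1 <- matrix(alleles[seq_len(n1)], ncol = 2, byrow = TRUE)
  g2 <- matrix(alleles[n1 + seq_len(n2)], ncol = 2, byrow = TRUE)
  est <- wc_theta(list(g1, g2))
  c(fst = est$theta, he = expected_het(alleles))
}
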