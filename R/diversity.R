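## Within-population marker diversity: allele counts and unbiased expected
## heterozygosity for codominant fragment-length markers.

#' Number of distinct alleles in a sample of chromosomes
#'
#' @param alleles Vector of allele calls (one entry per chromosome); `NA`
#'   marks missing calls and is dropped.
#' @return Integer count of distinct alleles.
#' @export
#' @examples
#' num_alleles(c(171, 171, 171, 174, 174, 177))
num_alleles <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  if (length(a) == 0) abort("all allele calls are missing")
  length(unique(a))
}

#' Unbiased expected heterozygosity
#'
#' Nei's gene diversity with the small-sample correction
#' `He = n / (n - 1) * (1 - sum(p_i^2))`, where `n` is the number of sampled
#' chromosomes and `p_i` the sample allele frequencies.
#'
#' @inheritParams num_alleles
#' @return Numeric in \[0, 1\]; exactly 0 for a monomorphic sample.
#' @export
#' @examples
#' expected_het(rep(c(1, 2), each = 5)) # (10/9) * (1 - 0.5)
expected_het <- function(alleles) {
  a <- alleles[!is.na(alleles)]
  n <- length(a)
  if (n < 2) abort("expected heterozygosity needs at least 2 chromosomes")
  p <- tabulate(factor(a)) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Per-locus, per-population diversity summaries
#'
#' Computes chromosomes sampled, number of alleles and unbiased expected
#' heterozygosity for every locus x population combination of a long marker
#' table. Individuals missing at a locus are dropped for that locus only, so
#' chromosome counts vary across loci.
#'
#' @param data A data frame with columns `population`, `individual`, `locus`,
#'   `allele_1`, `allele_2` (allele labels; `NA` = missing) and optionally
#'   `locus_class`.
#' @return A tibble with columns `locus`, `population` (plus `locus_class`
#'   when present), `n_chrom`, `n_alleles`, `exp_het`.
#' @export
#' @examples
#' d <- gen_population_markers(N = 100, burnin = 200, n_mine = 12,
#'                             n_off = 12, seed = 1)
#' locus_stats(d$markers)
locus_stats <- function(data) {
  required <- c("population", "individual", "locus", "allele_1", "allele_2")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    abort(paste0("`data` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  keep_class <- "locus_class" %in% names(data)
  long <- tidyr::pivot_longer(data, c("allele_1", "allele_2"),
                              names_to = NULL, values_to = "allele")
  grouping <- if (keep_class) c("locus", "locus_class", "population") else
    c("locus", "population")
  out <- long %>%
    dplyr::filter(!is.na(.data$allele)) %>%
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) %>%
    dplyr::summarise(
      n_chrom = dplyr::n(),
      n_alleles = num_alleles(.data$allele),
      exp_het = if (dplyr::n() >= 2) expected_het(.data$allele) else
        NA_real_,
      .groups = "drop")
  empty <- data %>%
    dplyr::distinct(.data$locus, .data$population) %>%
    dplyr::anti_join(out, by = c("locus", "population"))
  if (nrow(empty) > 0)
    abort(sprintf("no non-missing genotypes for locus %s in population %s",
                  empty$locus[1], empty$population[1]))
  out
}

#' Class-level summary of diversity statistics
#'
#' Averages per-locus diversity over marker classes (for example linked vs
#' unlinked to a selected site), per population: the mean and sample standard
#' deviation of the allele count and expected heterozygosity. A class
#' represented by a single locus reports `NA` standard deviations.
#'
#' @param stats A data frame with columns `locus_class`, `population`,
#'   `n_alleles`, `exp_het` (e.g. the output of [locus_stats()] on a tagged
#'   dataset).
#' @param classes Optional character vector of classes that must be present;
#'   an absent class is an error.
#' @return A tibble with one row per class x population: `n_loci`,
#'   `na_mean`, `na_sd`, `he_mean`, `he_sd`.
#' @export
summarize_classes <- function(stats, classes = NULL) {
  required <- c("locus_class", "population", "n_alleles", "exp_het")
  missing_cols <- setdiff(required, names(stats))
  if (length(missing_cols) > 0)
    abort(paste0("`stats` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  if (!is.null(classes)) {
    absent <- setdiff(classes, unique(stats$locus_class))
    if (length(absent) > 0)
      abort(paste0("empty marker class: ", paste(absent, collapse = ", ")))
  }
  stats %>%
    dplyr::group_by(.data$locus_class, .data$population) %>%
    dplyr::summarise(
      n_loci = dplyr::n(),
      na_mean = mean(.data$n_alleles),
      na_sd = if (dplyr::n() > 1) stats::sd(.data$n_alleles) else NA_real_,
      he_mean = mean(.data$exp_het),
      he_sd = if (dplyr::n() > 1) stats::sd(.data$exp_het) else NA_real_,
      .groups = "drop")
}
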