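## Backcross fine mapping. Genotypes in a near-isogenic backcross are coded
## "H" (heterozygous for the introgressed donor segment) or "A" (homozygous
## recurrent parent); the trait locus carries a fully penetrant dominant
## allele, so a tolerant plant is inferred "H" and a nontolerant plant "A"
## at the trait locus.

implied_trait_genotype <- function(tolerant) ifelse(tolerant, "H", "A")

#' Flag putative recombinants between a marker and a trait locus
#'
#' An individual whose genotype at the focal marker is discordant with the
#' genotype implied by its phenotype (dominant model) carries a putative
#' recombination event between the marker and the trait locus. Individuals
#' missing either the marker genotype or the phenotype are skipped; their
#' count is reported as a warning.
#'
#' @param geno A data frame with columns `individual`, `marker`, `genotype`
#'   (`"H"`, `"A"` or `NA`).
#' @param phen A data frame with columns `individual` and `tolerant`
#'   (logical); replicate rows per individual are reduced by majority vote.
#' @param focal_marker The marker to compare against the phenotype.
#' @return A tibble with columns `individual`, `marker_genotype`,
#'   `tolerant`, `implied_genotype`, `recombinant`.
#' @export
call_recombinants <- function(geno, phen, focal_marker) {
  g <- geno %>%
    dplyr::filter(.data$marker == focal_marker) %>%
    dplyr::select("individual", marker_genotype = "genotype")
  if (nrow(g) == 0)
    abort(sprintf("focal marker %s was not genotyped", focal_marker))
  ph <- phen %>%
    dplyr::group_by(.data$individual) %>%
    dplyr::summarise(tolerant = mean(.data$tolerant) >= 0.5,
                     .groups = "drop")
  d <- dplyr::inner_join(g, ph, by = "individual")
  skipped <- sum(is.na(d$marker_genotype) | is.na(d$tolerant))
  if (skipped > 0)
    warn(sprintf("%d individuals missing marker genotype or phenotype were skipped",
                 skipped))
  d %>%
    dplyr::filter(!is.na(.data$marker_genotype), !is.na(.data$tolerant)) %>%
    dplyr::mutate(
      implied_genotype = implied_trait_genotype(.data$tolerant),
      recombinant = .data$marker_genotype != .data$implied_genotype) %>%
    as_tibble()
}

#' Confirm putative recombinants with replicate assays
#'
#' A putative recombinant is confirmed only if its replicate genotype calls
#' and replicate phenotype calls all reproduce the discordant state
#' (`policy = "all"`, the default) or if a majority of each does
#' (`policy = "majority"`). Putative recombinants without replicates remain
#' unconfirmed and are flagged.
#'
#' @param calls Output of [call_recombinants()].
#' @param replicate_geno A data frame with columns `individual`, `replicate`,
#'   `genotype` (repeat genotyping at the focal marker).
#' @param replicate_phen A data frame with columns `individual`, `replicate`,
#'   `tolerant`.
#' @param policy `"all"` (every replicate must agree) or `"majority"`.
#' @return The putative recombinants with `n_geno_reps`, `n_phen_reps`,
#'   `confirmed` and `demotion` columns.
#' @export
confirm_recombinants <- function(calls, replicate_geno, replicate_phen,
                                 policy = c("all", "majority")) {
  policy <- match.arg(policy)
  agree <- function(x, target) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(NA)
    if (policy == "all") all(x == target) else mean(x == target) > 0.5
  }
  put <- dplyr::filter(calls, .data$recombinant)
  purrr::map_dfr(seq_len(nrow(put)), function(i) {
    row <- put[i, ]
    gg <- replicate_geno$genotype[replicate_geno$individual == row$individual]
    pp <- replicate_phen$tolerant[replicate_phen$individual == row$individual]
    g_ok <- agree(gg, row$marker_genotype)
    p_ok <- agree(pp, row$tolerant)
    demotion <- dplyr::case_when(
      is.na(g_ok) | is.na(p_ok) ~ "no replicates",
      !g_ok ~ "genotype replicate disagreed",
      !p_ok ~ "phenotype replicate disagreed",
      TRUE ~ NA_character_)
    dplyr::mutate(row,
                  n_geno_reps = sum(!is.na(gg)),
                  n_phen_reps = sum(!is.na(pp)),
                  confirmed = isTRUE(g_ok) && isTRUE(p_ok),
                  demotion = demotion)
  })
}

#' Backcross map distance with exact confidence interval
#'
#' In a backcross the recombination fraction equals the recombinant fraction,
#' so the map distance is `100 * n_recombinant / n_total` centimorgans. An
#' exact (Clopper-Pearson) binomial confidence interval is attached. The
#' point estimate is reported rounded to 2 decimals.
#'
#' @param n_recombinant Confirmed recombinants (vectorized).
#' @param n_total Population size (> 0).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with `n_recombinant`, `n_total`, `distance_cM`,
#'   `ci_lower_cM`, `ci_upper_cM`.
#' @export
#' @examples
#' map_distance(36, 4340) # 0.83 cM
#' map_distance(14, 4340) # 0.32 cM
map_distance <- function(n_recombinant, n_total, conf_level = 0.95) {
  if (any(n_total <= 0)) abort("`n_total` must be positive")
  if (any(n_recombinant < 0 | n_recombinant > n_total))
    abort("`n_recombinant` must lie in [0, n_total]")
  purrr::map2_dfr(n_recombinant, n_total, function(k, n) {
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    tibble(n_recombinant = k, n_total = n,
           distance_cM = round(100 * k / n, 2),
           ci_lower_cM = 100 * ci[1], ci_upper_cM = 100 * ci[2])
  })
}

# segments and breakpoints for one individual's ordered genotype vector
impute_one <- function(g) {
  L <- length(g)
  inf <- which(!is.na(g))
  if (length(inf) == 0) abort("all markers missing for an individual")
  runs <- rle(g[inf])
  n_runs <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  seg <- list()
  bp <- list()
  for (k in seq_len(n_runs)) {
    first_inf <- inf[starts[k]]
    last_inf <- inf[ends[k]]
    # leading/trailing missing markers inherit the flanking run's state
    start_idx <- if (k == 1) 1L else first_inf
    end_idx <- if (k == n_runs) L else last_inf
    seg[[length(seg) + 1]] <- tibble(
      start = start_idx, end = end_idx, state = runs$values[k])
    if (k < n_runs) {
      next_inf <- inf[starts[k + 1]]
      bp[[length(bp) + 1]] <- tibble(
        left = last_inf, right = next_inf,
        left_state = runs$values[k], right_state = runs$values[k + 1])
      if (next_inf - last_inf > 1) {
        # missing markers between discordant informative markers stay unknown
        seg[[length(seg) + 1]] <- tibble(
          start = last_inf + 1L, end = next_inf - 1L, state = "unknown")
      }
    }
  }
  list(segments = dplyr::bind_rows(seg) %>% dplyr::arrange(.data$start),
       breakpoints = if (length(bp)) dplyr::bind_rows(bp) else
         tibble(left = integer(), right = integer(),
                left_state = character(), right_state = character()),
       double_recombinant = n_runs > 2)
}

#' Impute introgression segments and breakpoints along ordered markers
#'
#' For each individual, maximal runs of heterozygous (`"H"`) and homozygous
#' (`"A"`) genotypes are imputed along the marker order; every breakpoint is
#' placed in the open interval between the flanking discordant informative
#' markers, and missing markers inherit the state of the surrounding run or
#' stay `"unknown"` when they fall between discordant markers. The imputed
#' segments tile the marker order exactly once. Individuals with more than
#' one breakpoint are flagged as double recombinants (with a warning).
#'
#' @param geno A data frame with columns `individual`, `marker`, `genotype`.
#' @param marker_order Character vector giving the marker order.
#' @return A list with `segments` (tibble: `individual`, `start`, `end`,
#'   `state` over 1-based order indices), `breakpoints` (tibble:
#'   `individual`, `left`, `right`, `left_state`, `right_state`) and
#'   `flags` (tibble: `individual`, `double_recombinant`).
#' @export
impute_breakpoints <- function(geno, marker_order) {
  inds <- unique(geno$individual)
  res <- purrr::map(inds, function(id) {
    g <- geno %>%
      dplyr::filter(.data$individual == id) %>%
      dplyr::slice(match(marker_order, .data$marker)) %>%
      dplyr::pull(.data$genotype)
    impute_one(g)
  })
  doubles <- purrr::map_lgl(res, "double_recombinant")
  if (any(doubles))
    warn(sprintf("%d individuals carry more than one imputed breakpoint",
                 sum(doubles)))
  list(
    segments = purrr::map2_dfr(res, inds, ~ dplyr::mutate(
      .x$segments, individual = .y, .before = 1)),
    breakpoints = purrr::map2_dfr(res, inds, ~ dplyr::mutate(
      .x$breakpoints, individual = .y, .before = 1)),
    flags = tibble(individual = inds, double_recombinant = doubles))
}

#' Localize a locus from recombinant breakpoint constraints
#'
#' Each informative recombinant places the locus on one side of its
#' breakpoint: the side whose imputed segment state matches the
#' phenotype-implied genotype at the locus. The locus interval is the
#' intersection of all such half-intervals, reported as the minimal
#' consistent open marker interval together with the individuals defining
#' each edge.
#'
#' @param constraints A data frame with columns `individual`, `side`
#'   (`"left_of"` or `"right_of"`) and `marker`.
#' @param marker_order Character vector giving the marker order.
#' @return A list with `lower_marker`, `upper_marker` (`NA` when unbounded),
#'   `lower_by`, `upper_by` (defining individuals), and `interval` indices.
#' @export
localize_locus <- function(constraints, marker_order) {
  if (nrow(constraints) == 0) abort("no constraints supplied")
  bad_side <- setdiff(unique(constraints$side), c("left_of", "right_of"))
  if (length(bad_side) > 0)
    abort(paste0("unknown constraint side: ", paste(bad_side, collapse = ", ")))
  idx <- match(constraints$marker, marker_order)
  if (anyNA(idx)) abort("constraint markers must appear in `marker_order`")
  lower_set <- constraints$side == "right_of"
  upper_set <- constraints$side == "left_of"
  lower <- if (any(lower_set)) max(idx[lower_set]) else 0L
  upper <- if (any(upper_set)) min(idx[upper_set]) else
    length(marker_order) + 1L
  if (lower >= upper) {
    culprits <- unique(c(
      constraints$individual[lower_set & idx == lower],
      constraints$individual[upper_set & idx == upper]))
    abort(paste0(
      "inconsistent localization constraints (empty interval); conflicting individuals: ",
      paste(culprits, collapse = ", ")))
  }
  list(
    lower_marker = if (lower >= 1) marker_order[lower] else NA_character_,
    upper_marker = if (upper <= length(marker_order)) marker_order[upper] else
      NA_character_,
    lower_by = unique(constraints$individual[lower_set & idx == lower]),
    upper_by = unique(constraints$individual[upper_set & idx == upper]),
    interval = c(lower = lower, upper = upper))
}

#' Marker-trait association with an exact test
#'
#' Builds the 2 x 2 contingency table of marker genotype (`H` / `A`) against
#' the binary phenotype and computes Fisher's exact two-sided p-value.
#' Degenerate margins (a genotype or phenotype class absent) yield p = 1 with
#' a warning.
#'
#' @inheritParams call_recombinants
#' @param marker Marker to test (genotyped in at least 10 individuals).
#' @return A one-row tibble with the four cell counts (`n_H_tol`,
#'   `n_H_nontol`, `n_A_tol`, `n_A_nontol`) and `p_value`.
#' @export
marker_trait_association <- function(geno, phen, marker) {
  d <- call_recombinants(geno, phen, marker)
  if (nrow(d) < 10)
    abort(sprintf("marker %s genotyped in fewer than 10 phenotyped individuals",
                  marker))
  tab <- table(factor(d$marker_genotype, levels = c("H", "A")),
               factor(d$tolerant, levels = c(TRUE, FALSE)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("degenerate margins: association test undefined, returning p = 1")
    p <- 1
  } else {
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  tibble(n_H_tol = tab["H", "TRUE"], n_H_nontol = tab["H", "FALSE"],
         n_A_tol = tab["A", "TRUE"], n_A_nontol = tab["A", "FALSE"],
         p_value = p)
}
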