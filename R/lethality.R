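## Hybrid-inviability assay analytics: fixed-size seedling blocks scored for
## the fraction of inviable (majority yellow/necrotic) offspring.

#' Per-line inviability rates from replicate blocks
#'
#' Groups scored blocks by line and returns the replicate rates
#' (`n_inviable / block_size`) and their mean.
#'
#' @param blocks A data frame with columns `line`, `block_size`,
#'   `n_inviable` (plus any annotation columns such as `tolerance_class`,
#'   which are carried through when constant within line).
#' @param lines Optional character vector of lines that must be present;
#'   a requested line with no blocks is an error.
#' @return A tibble with one row per line: `n_replicates`, `rates`
#'   (list-column), `mean_rate`.
#' @export
#' @examples
#' blocks <- tibble::tibble(line = c("L1", "L1"), block_size = 60,
#'                          n_inviable = c(3, 9))
#' inviability_rates(blocks)
inviability_rates <- function(blocks, lines = NULL) {
  if (any(blocks$block_size <= 0)) abort("`block_size` must be positive")
  if (any(blocks$n_inviable < 0 | blocks$n_inviable > blocks$block_size))
    abort("`n_inviable` must lie in [0, block_size]")
  if (!is.null(lines)) {
    absent <- setdiff(lines, unique(blocks$line))
    if (length(absent) > 0)
      abort(paste0("no blocks for line(s): ", paste(absent, collapse = ", ")))
  }
  carry <- intersect("tolerance_class", names(blocks))
  blocks %>%
    dplyr::group_by(.data$line) %>%
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      n_replicates = dplyr::n(),
      rates = list(.data$n_inviable / .data$block_size),
      mean_rate = mean(.data$n_inviable / .data$block_size),
      .groups = "drop")
}

#' Classify lines as incompatibility-allele carriers
#'
#' Crosses to a carrier line show high inviability while non-carrier lines
#' show a low background rate; the two bands are separated by a single
#' threshold on the mean replicate rate (default 0.30, the midpoint of the
#' gap between the empirical bands of roughly 5-15% and 45-62%). Lines whose
#' mean falls within `ambiguous_margin` of the threshold are labelled
#' ambiguous.
#'
#' @param line_rates Output of [inviability_rates()] (any data frame with a
#'   `mean_rate` column).
#' @param threshold Carrier threshold on the mean rate (default 0.30).
#' @param ambiguous_margin Half-width of the ambiguous band (default 0.05).
#' @return The input with `carrier_class` (`"carrier"`, `"non-carrier"` or
#'   `"ambiguous"`) and `distance_to_threshold` appended.
#' @export
classify_carrier <- function(line_rates, threshold = 0.30,
                             ambiguous_margin = 0.05) {
  line_rates %>%
    dplyr::mutate(
      distance_to_threshold = .data$mean_rate - threshold,
      carrier_class = dplyr::case_when(
        abs(.data$mean_rate - threshold) <= ambiguous_margin ~ "ambiguous",
        .data$mean_rate > threshold ~ "carrier",
        TRUE ~ "non-carrier")) %>%
    as_tibble()
}

# null distribution of the rank-sum of the first sample under exhaustive
# reassignment of the pooled values (midranks preserve ties)
ranksum_enumeration <- function(pooled_ranks, n1) {
  combos <- utils::combn(length(pooled_ranks), n1)
  colSums(matrix(pooled_ranks[combos], nrow = n1))
}

#' Two-sample rank-sum comparison of inviability rates
#'
#' Wilcoxon/Mann-Whitney rank-sum test with midrank tie handling. The
#' normal-approximation z statistic (tie-corrected variance, continuity
#' correction on by default) is always reported; when the combined sample
#' size is at most `exact_limit`, the exact two-sided p-value from full
#' enumeration of all reassignments is reported alongside.
#'
#' @param x,y Numeric vectors of replicate rates (each of length >= 2).
#' @param exact_limit Combined sample size up to which the exact enumeration
#'   is added (default 10).
#' @param continuity Apply the continuity correction to z (default TRUE).
#' @return A one-row tibble: `n1`, `n2`, `rank_sum`, `z`, `p_normal`,
#'   `p_exact` (`NA` beyond `exact_limit`), `method`.
#' @export
#' @examples
#' compare_lines_ranksum(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
compare_lines_ranksum <- function(x, y, exact_limit = 10,
                                  continuity = TRUE) {
  if (length(x) < 2 || length(y) < 2)
    abort("each line needs at least 2 replicates")
  n1 <- length(x)
  n2 <- length(y)
  N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled) # midranks
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (v <= 0) {
    z <- 0
    p_norm <- 1
  } else {
    cc <- if (continuity && W != mu) 0.5 * sign(W - mu) else 0
    z <- (W - mu - cc) / sqrt(v)
    p_norm <- 2 * stats::pnorm(-abs(z))
  }
  p_exact <- NA_real_
  if (N <= exact_limit) {
    null_w <- ranksum_enumeration(rk, n1)
    p_exact <- min(1, 2 * min(mean(null_w <= W), mean(null_w >= W)))
  }
  tibble(n1 = n1, n2 = n2, rank_sum = W, z = z, p_normal = p_norm,
         p_exact = p_exact,
         method = if (N <= exact_limit) "normal+exact" else "normal")
}

#' Reciprocal-cross asymmetry in hybrid inviability
#'
#' Pools the blocks of each cross direction and asks whether inviable
#' offspring are split between directions in proportion to the seedlings
#' scored per direction: expected counts allocate the pooled inviables
#' proportionally, and a Pearson chi-square with 1 df is computed on the
#' 2 x 2 (direction x viable/inviable) table, without continuity correction.
#' Flagged at p < 0.01.
#'
#' @param blocks A data frame with columns `direction` (exactly two levels),
#'   `block_size` and `n_inviable`.
#' @return A list of class `"reciprocal_test"`: `table` (per-direction
#'   observed and expected counts), `statistic`, `df`, `p_value`,
#'   `significant`.
#' @export
reciprocal_asymmetry <- function(blocks) {
  dirs <- unique(blocks$direction)
  if (length(dirs) != 2)
    abort("`blocks` must contain exactly two cross directions")
  by_dir <- blocks %>%
    dplyr::group_by(.data$direction) %>%
    dplyr::summarise(n_scored = sum(.data$block_size),
                     n_inviable = sum(.data$n_inviable), .groups = "drop")
  if (any(by_dir$n_scored == 0))
    abort("a cross direction has zero scored seedlings")
  total_inv <- sum(by_dir$n_inviable)
  total <- sum(by_dir$n_scored)
  by_dir$expected_inviable <- total_inv * by_dir$n_scored / total
  obs <- rbind(by_dir$n_inviable, by_dir$n_scored - by_dir$n_inviable)
  if (total_inv == 0 || total_inv == total) {
    stat <- 0
    p <- 1
  } else {
    ct <- stats::chisq.test(obs, correct = FALSE)
    stat <- unname(ct$statistic)
    p <- ct$p.value
  }
  structure(
    list(table = by_dir, statistic = stat, df = 1L, p_value = p,
         significant = p < 0.01),
    class = "reciprocal_test")
}

#' @export
print.reciprocal_test <- function(x, ...) {
  cat("Reciprocal-cross inviability asymmetry\n")
  print(x$table)
  cat(sprintf("  chi-square = %.3f (1 df), p = %.3g%s\n", x$statistic,
              x$p_value, if (x$significant) " **" else ""))
  invisible(x)
}

#' @rdname reciprocal_asymmetry
#' @param x A `"reciprocal_test"` object.
#' @param ... Unused.
#' @export
tidy.reciprocal_test <- function(x, ...) x$table

#' @rdname reciprocal_asymmetry
#' @export
glance.reciprocal_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         significant = x$significant)
}

#' Replicate-block inviability plot
#'
#' Replicate rates per line, coloured by tolerance class when available,
#' with the carrier threshold drawn as a dashed line.
#'
#' @param blocks A data frame with columns `line`, `block_size`,
#'   `n_inviable` and optionally `tolerance_class`.
#' @param threshold Carrier threshold drawn on the plot (default 0.30).
#' @return A ggplot object.
#' @export
plot_inviability <- function(blocks, threshold = 0.30) {
  blocks <- dplyr::mutate(blocks, rate = .data$n_inviable / .data$block_size)
  aes <- if ("tolerance_class" %in% names(blocks)) {
    ggplot2::aes(.data$line, .data$rate, colour = .data$tolerance_class)
  } else {
    ggplot2::aes(.data$line, .data$rate)
  }
  ggplot2::ggplot(blocks, aes) +
    ggplot2::geom_jitter(width = 0.1, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fraction inviable per block") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
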