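## Fdist-style island-model coalescent null for Fst outlier detection.
## Loci are simulated under a two-deme structured coalescent with
## infinite-alleles mutation; the migration parameter is calibrated so the
## simulated mean Fst matches the neutral mean estimated from unlinked
## markers, and observed loci are compared to the (He, Fst) cloud.

#' Simulate one locus under the two-deme island model
#'
#' Draws a single structured-coalescent genealogy for two demes under
#' Wright's symmetric island model and drops infinite-alleles mutations on
#' it: each mutation creates a novel allele and a sampled chromosome carries
#' the most recent mutation on its root path (the ancestral allele, label 0,
#' if none).
#'
#' @param n1,n2 Chromosomes sampled per deme.
#' @param M Scaled symmetric migration parameter (`4 N m`), positive.
#' @param theta Scaled mutation parameter (`4 N u`), positive.
#' @return A tibble with columns `deme`, `chromosome`, `allele`.
#' @export
#' @examples
#' set.seed(1)
#' coalesce_two_demes(10, 10, M = 1, theta = 1)
coalesce_two_demes <- function(n1, n2, M, theta) {
  if (M <= 0) abort("`M` must be positive")
  if (theta < 0) abort("`theta` must be non-negative")
  alleles <- cpp_island_alleles(as.integer(n1), as.integer(n2), M, theta)
  tibble(deme = rep(c(1L, 2L), c(n1, n2)),
         chromosome = c(seq_len(n1), seq_len(n2)),
         allele = as.integer(alleles))
}

#' Simulate many island-model loci and summarise them
#'
#' Batch version of [coalesce_two_demes()]: simulates `n_loci` independent
#' loci, pairs consecutive chromosomes into diploid individuals, and returns
#' the pooled expected heterozygosity and Weir-Cockerham Fst of each locus.
#' Monomorphic loci carry `NA` Fst. `theta` may be a single value or a range
#' `c(lo, hi)` from which per-locus values are drawn log-uniformly so the
#' null cloud spreads over the He axis (the Fdist device for conditioning on
#' heterozygosity).
#'
#' @inheritParams coalesce_two_demes
#' @param n_loci Number of independent loci.
#' @param theta Scalar, or length-2 range for log-uniform per-locus draws.
#' @return A tibble with columns `locus`, `he`, `fst`.
#' @export
sim_island_loci <- function(n_loci, n1, n2, M, theta = c(0.05, 10)) {
  if (n_loci < 1) abort("`n_loci` must be at least 1")
  if (M <= 0) abort("`M` must be positive")
  if (any(theta <= 0)) abort("`theta` must be positive")
  n1 <- as.integer(n1)
  n2 <- as.integer(n2)
  th <- if (length(theta) == 2) {
    exp(runif(n_loci, log(theta[1]), log(theta[2])))
  } else {
    rep(theta[1], n_loci)
  }
  mat <- cpp_island_loci(as.integer(n_loci), n1, n2, M, th)
  res <- matrix(NA_real_, n_loci, 2)
  for (l in seq_len(n_loci)) {
    a <- mat[l, ]
    if (length(unique(a)) < 2) {
      res[l, ] <- c(NA_real_, 0)
      next
    }
    v <- fst_he_from_chromosomes(a, n1, n2)
    res[l, ] <- v
  }
  tibble(locus = seq_len(n_loci), he = res[, 2], fst = res[, 1])
}

#' Calibrated island-model null distribution for Fst outlier tests
#'
#' Calibrates the migration parameter `M` by bisection on `log10(M)` over
#' `[1e-3, 1e4]` so the simulated mean Fst over polymorphic loci matches a
#' target neutral mean (normally the mean Weir-Cockerham Fst of markers
#' unlinked to the candidate region), then simulates `n_sims` loci at the
#' calibrated `M` and stores their `(He, Fst)` pairs. The simulated mean Fst
#' is required to land within `tol` of the target. A target at or below the
#' panmixia floor drives `M` to its upper bound and is flagged rather than
#' refined.
#'
#' @param observed_unlinked Either a data frame with an `fst` column (its mean
#'   over non-`NA` values is the target) or a single numeric target mean Fst.
#' @param sample_sizes Length-2 integer vector of chromosomes per deme,
#'   matched to the observed data.
#' @param n_sims Simulated loci stored in the null (default 50,000).
#' @param theta Per-locus mutation range, as in [sim_island_loci()].
#' @param loci_per_eval Loci per calibration evaluation (default 5,000).
#' @param tol Calibration tolerance on the mean Fst (default 0.01).
#' @param max_iter Maximum bisection iterations (default 40).
#' @return An object of class `"fdist_null"`: list with `pairs` (tibble of
#'   `he`, `fst`), `M`, `target_fst`, `mean_fst`, `n_sims`, `sample_sizes`,
#'   `at_bound` and the calibration trace. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
#' @examples
#' set.seed(7)
#' nul <- fdist_null(0.05, sample_sizes = c(60, 60), n_sims = 2000,
#'                   loci_per_eval = 1000)
#' glance(nul)
fdist_null <- function(observed_unlinked, sample_sizes, n_sims = 50000,
                       theta = c(0.05, 10), loci_per_eval = 5000,
                       tol = 0.01, max_iter = 40) {
  target <- if (is.data.frame(observed_unlinked)) {
    mean(observed_unlinked$fst, na.rm = TRUE)
  } else {
    as.numeric(observed_unlinked)
  }
  if (!is.finite(target)) abort("target mean Fst is not finite")
  n1 <- as.integer(sample_sizes[1])
  n2 <- as.integer(sample_sizes[2])

  mean_fst_at <- function(M, n_loci) {
    sims <- sim_island_loci(n_loci, n1, n2, M, theta)
    mean(sims$fst, na.rm = TRUE)
  }

  lo <- -3
  hi <- 4
  trace <- list()
  at_bound <- FALSE
  # a non-positive target cannot be bracketed: panmixia is the floor
  if (target <= 0) {
    warn("target mean Fst <= 0: calibration driven to the upper migration bound")
    m_star <- 10^hi
    at_bound <- TRUE
  } else {
    f_lo <- mean_fst_at(10^lo, loci_per_eval)
    if (f_lo < target - tol) {
      abort(sprintf(paste0(
        "calibration failed to bracket the target: mean Fst at M = 1e-3 ",
        "is %.4f but the target is %.4f"), f_lo, target))
    }
    trace[[1]] <- tibble(iter = 0L, M = 10^lo, mean_fst = f_lo)
    m_star <- NA_real_
    for (it in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      f_mid <- mean_fst_at(10^mid, loci_per_eval)
      trace[[it + 1L]] <- tibble(iter = it, M = 10^mid, mean_fst = f_mid)
      if (abs(f_mid - target) <= tol / 2) {
        m_star <- 10^mid
        break
      }
      if (f_mid > target) lo <- mid else hi <- mid
    }
    if (is.na(m_star)) {
      # bracket exhausted without hitting the inner tolerance: take the last
      # midpoint if it is within tol, otherwise report the failure
      last <- trace[[length(trace)]]
      if (abs(last$mean_fst - target) <= tol) {
        m_star <- last$M
      } else {
        abort(sprintf(paste0(
          "calibration did not converge in %d iterations: last mean Fst ",
          "%.4f vs target %.4f (last M = %.4g)"),
          max_iter, last$mean_fst, target, last$M))
      }
    }
    if (m_star >= 10^(4 - 1e-9)) at_bound <- TRUE
  }

  pairs <- sim_island_loci(n_sims, n1, n2, m_star, theta)
  structure(
    list(pairs = dplyr::select(pairs, "he", "fst"),
         M = m_star,
         target_fst = target,
         mean_fst = mean(pairs$fst, na.rm = TRUE),
         n_sims = n_sims,
         sample_sizes = c(n1, n2),
         theta = theta,
         at_bound = at_bound,
         calibration = dplyr::bind_rows(trace)),
    class = "fdist_null")
}

#' @export
print.fdist_null <- function(x, ...) {
  cat("Island-model Fst null distribution\n")
  cat(sprintf("  %d simulated loci, sample sizes %d + %d chromosomes\n",
              x$n_sims, x$sample_sizes[1], x$sample_sizes[2]))
  cat(sprintf("  calibrated M = %.4g (target mean Fst %.4f, simulated %.4f)%s\n",
              x$M, x$target_fst, x$mean_fst,
              if (x$at_bound) " [at migration bound]" else ""))
  invisible(x)
}

#' @rdname fdist_null
#' @param x,object An `"fdist_null"` object.
#' @param ... Unused.
#' @export
tidy.fdist_null <- function(x, ...) x$pairs

#' @rdname fdist_null
#' @export
glance.fdist_null <- function(x, ...) {
  tibble(M = x$M, target_fst = x$target_fst, mean_fst = x$mean_fst,
         n_sims = x$n_sims, at_bound = x$at_bound,
         prop_polymorphic = mean(!is.na(x$pairs$fst)))
}

#' @rdname fdist_null
#' @param observed Optional tibble of observed loci (columns `locus`, `fst`,
#'   `he_pooled`) overlaid on the null cloud.
#' @export
autoplot.fdist_null <- function(object, observed = NULL, ...) {
  pairs <- dplyr::filter(object$pairs, !is.na(.data$fst))
  p <- ggplot2::ggplot(pairs, ggplot2::aes(.data$he, .data$fst)) +
    ggplot2::geom_point(alpha = 0.08, size = 0.4, colour = "grey40") +
    ggplot2::labs(x = "pooled expected heterozygosity",
                  y = "Weir-Cockerham Fst",
                  title = "Island-model null with observed loci") +
    ggplot2::theme_minimal()
  if (!is.null(observed)) {
    p <- p + ggplot2::geom_point(
      data = observed,
      ggplot2::aes(.data$he_pooled, .data$fst),
      colour = "firebrick", size = 2)
  }
  p
}

#' Conditional upper-tail outlier p-values against an island-model null
#'
#' For each observed locus, the p-value is the fraction of simulated null
#' loci whose pooled heterozygosity lies within a window of the observed
#' value and whose Fst is at least the observed Fst (upper tail). Windows
#' start at `+- window` in He and widen by `window` until at least
#' `min_points` polymorphic null loci are captured (with a warning).
#' Significance is flagged at 0.025 and 0.0025.
#'
#' @param observed A data frame with columns `locus`, `fst` and `he_pooled`
#'   (as returned by [wc_fst()]).
#' @param null An `"fdist_null"` object with at least 1,000 pairs.
#' @param window He half-width of the conditioning window (default 0.05).
#' @param min_points Minimum null loci per window (default 500).
#' @return The observed table with `p_value`, `n_window`, `sig_0025`,
#'   `sig_00025` columns appended.
#' @export
outlier_pvalues <- function(observed, null, window = 0.05,
                            min_points = 500) {
  if (!inherits(null, "fdist_null")) abort("`null` must be an fdist_null object")
  pairs <- dplyr::filter(null$pairs, !is.na(.data$fst))
  if (nrow(pairs) < 1000)
    abort("the null needs at least 1,000 polymorphic simulated loci")
  widened <- FALSE
  p_one <- function(he_obs, fst_obs) {
    w <- window
    repeat {
      sel <- abs(pairs$he - he_obs) <= w
      if (sum(sel) >= min_points || w >= 1) break
      w <- w + window
      widened <<- TRUE
    }
    n_win <- sum(sel)
    if (n_win == 0) return(c(NA_real_, 0))
    c(mean(pairs$fst[sel] >= fst_obs), n_win)
  }
  res <- t(mapply(p_one, observed$he_pooled, observed$fst))
  if (widened)
    warn("some conditioning windows were widened to reach the minimum point count")
  observed$p_value <- res[, 1]
  observed$n_window <- as.integer(res[, 2])
  observed$sig_0025 <- !is.na(res[, 1]) & res[, 1] < 0.025
  observed$sig_00025 <- !is.na(res[, 1]) & res[, 1] < 0.0025
  as_tibble(observed)
}
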