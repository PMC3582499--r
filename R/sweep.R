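## Deterministic two-locus hitchhiking model (Maynard Smith & Haigh form).
## Locus A carries the selected allele A (frequency p); locus B carries the
## focal neutral allele B (frequency U). The four haplotype frequencies are
## x_AB, x_Ab, x_aB, x_ab. Each generation applies genic selection on A
## (haploid-equivalent multiplicative fitness 1 + s) and then recombination
## at fraction r, which decays the post-selection disequilibrium D by r.

#' Validate and bundle two-locus sweep parameters
#'
#' Collects the parameters of the deterministic hitchhiking recursion and
#' enforces their joint feasibility. `u_p` is the frequency of the focal
#' neutral allele among haplotypes that carry the selected allele at sweep
#' onset; `u_p = 1` with a rare selected allele is the hard-sweep initial
#' condition, smaller values describe soft sweeps from standing variation.
#'
#' @param s Selection coefficient per generation (>= 0; 0 is neutrality).
#' @param p0 Initial frequency of the selected allele, in (0, 1).
#' @param U0 Initial frequency of the neutral allele, in \[0, 1\].
#' @param u_p Initial frequency of the neutral allele among selected-allele
#'   haplotypes, in \[0, 1\]. Feasibility requires
#'   `p0 * u_p <= U0 <= 1 - p0 * (1 - u_p)`.
#' @param r Recombination fraction per generation, in \[0, 0.5\].
#' @param N Nominal population size; only used to define the new-mutation
#'   frequency `1 / (2 N)` in helper defaults.
#' @param fix_threshold Selected-allele frequency defining `T_fix`
#'   (default 0.99).
#' @param run_threshold Stopping frequency for a run to near fixation
#'   (default `1 - 1e-9`); must exceed `fix_threshold`.
#' @param max_generations Hard cap on iterated generations.
#' @return A list of class `"sweep_params"`.
#' @export
#' @examples
#' sweep_params(s = 0.25, p0 = 0.0005, U0 = 0.05, u_p = 1, r = 0)
sweep_params <- function(s, p0, U0, u_p, r, N = 1000,
                         fix_threshold = 0.99, run_threshold = 1 - 1e-9,
                         max_generations = 1e5) {
  if (!is.numeric(s) || s < 0) abort("`s` must be >= 0")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must lie strictly in (0, 1)")
  if (U0 < 0 || U0 > 1) abort("`U0` must lie in [0, 1]")
  if (u_p < 0 || u_p > 1) abort("`u_p` must lie in [0, 1]")
  if (r < 0 || r > 0.5) abort("`r` must lie in [0, 0.5]")
  if (fix_threshold >= run_threshold)
    abort("`fix_threshold` must be smaller than `run_threshold`")
  check_haplotype_feasible(p0, U0, u_p)
  structure(
    list(s = s, p0 = p0, U0 = U0, u_p = u_p, r = r, N = N,
         fix_threshold = fix_threshold, run_threshold = run_threshold,
         max_generations = max_generations),
    class = "sweep_params")
}

check_haplotype_feasible <- function(p0, U0, u_p) {
  lo <- p0 * u_p
  hi <- 1 - p0 * (1 - u_p)
  if (U0 < lo - 1e-12)
    abort(sprintf(
      "infeasible initial state: U0 = %g is below p0 * u_p = %g (haplotype x_aB would be negative)",
      U0, lo))
  if (U0 > hi + 1e-12)
    abort(sprintf(
      "infeasible initial state: U0 = %g exceeds 1 - p0 * (1 - u_p) = %g (haplotype x_ab would be negative)",
      U0, hi))
  invisible(TRUE)
}

#' Initial haplotype frequencies for a sweep
#'
#' Builds the four-haplotype state implied by the initial frequencies of the
#' selected allele (`p0`), the neutral allele (`U0`) and the neutral allele
#' among selected backgrounds (`u_p`).
#'
#' @inheritParams sweep_params
#' @return A one-row tibble with columns `x_AB`, `x_Ab`, `x_aB`, `x_ab`.
#' @export
#' @examples
#' init_haplotypes(0.05, 0.05, 1) # complete association: x_aB = 0
init_haplotypes <- function(p0, U0, u_p) {
  if (p0 <= 0 || p0 >= 1) abort("`p0` must lie strictly in (0, 1)")
  if (U0 < 0 || U0 > 1) abort("`U0` must lie in [0, 1]")
  if (u_p < 0 || u_p > 1) abort("`u_p` must lie in [0, 1]")
  check_haplotype_feasible(p0, U0, u_p)
  x_AB <- p0 * u_p
  x_Ab <- p0 * (1 - u_p)
  x_aB <- max(U0 - p0 * u_p, 0)
  x_ab <- max(1 - x_AB - x_Ab - x_aB, 0)
  tibble(x_AB = x_AB, x_Ab = x_Ab, x_aB = x_aB, x_ab = x_ab)
}

#' Marginal summaries of a haplotype state
#'
#' Derives the selected-allele frequency `p`, neutral-allele frequency `U`,
#' disequilibrium `D` and normalized disequilibrium `Dprime` from a
#' four-haplotype state. `Dprime = D / D_max`, where the bound depends on the
#' sign of `D`; it is 0 when the bound is 0.
#'
#' @param state A one-row data frame with columns `x_AB`, `x_Ab`, `x_aB`,
#'   `x_ab` (as returned by [init_haplotypes()]).
#' @return A one-row tibble with columns `p`, `U`, `D`, `Dprime`.
#' @export
hap_summary <- function(state) {
  p <- state$x_AB + state$x_Ab
  U <- state$x_AB + state$x_aB
  D <- state$x_AB * state$x_ab - state$x_Ab * state$x_aB
  if (D > 0) {
    dmax <- min(p * (1 - U), (1 - p) * U)
  } else {
    dmax <- min(p * U, (1 - p) * (1 - U))
  }
  dprime <- if (dmax <= 0) 0 else D / dmax
  tibble(p = p, U = U, D = D, Dprime = dprime)
}

#' One generation of the hitchhiking recursion
#'
#' Applies selection then recombination: every haplotype carrying the selected
#' allele is weighted by `(1 + s)` and all haplotypes are renormalized by the
#' mean fitness `1 + s p`; the post-selection disequilibrium `D_sel` then
#' decays at the recombination fraction, moving `r * D_sel` between coupling
#' and repulsion haplotypes.
#'
#' @param state One-row data frame of haplotype frequencies.
#' @param s Selection coefficient (>= 0).
#' @param r Recombination fraction in \[0, 0.5\].
#' @return A one-row tibble of updated haplotype frequencies (sums to 1).
#' @export
sweep_step <- function(state, s, r) {
  x <- c(state$x_AB, state$x_Ab, state$x_aB, state$x_ab)
  p <- x[1] + x[2]
  wbar <- 1 + s * p
  x <- x * c(1 + s, 1 + s, 1, 1) / wbar
  d_sel <- x[1] * x[4] - x[2] * x[3]
  x <- x + r * d_sel * c(-1, 1, 1, -1)
  if (any(x < -1e-15))
    abort("haplotype frequency fell below the numeric guard after a step")
  x[x < 0] <- 0
  x <- x / sum(x)
  tibble(x_AB = x[1], x_Ab = x[2], x_aB = x[3], x_ab = x[4])
}

#' Run a deterministic two-locus sweep
#'
#' Iterates [sweep_step()] from [init_haplotypes()] until the selected allele
#' exceeds `run_threshold` or `max_generations` is reached, recording the
#' per-generation `(p, U, Dprime)` series. The run is fully deterministic.
#' `T_fix` is the first generation with `p > fix_threshold` (`NA` if never
#' reached); `delta_U` is the final neutral-allele frequency minus `U0`.
#'
#' @param params Either a `"sweep_params"` object or `NULL`, in which case the
#'   remaining arguments are used.
#' @inheritParams sweep_params
#' @return An object of class `"sweep_fit"`: a list with `trajectory`
#'   (a tibble with columns `generation`, `p`, `U`, `Dprime`), `T_fix`,
#'   `delta_U`, `complete` (did `p` pass `fix_threshold`?) and `params`.
#'   Supports [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' fit <- run_sweep(s = 0.25, p0 = 0.0005, U0 = 0.05, u_p = 1, r = 0.001)
#' glance(fit)
run_sweep <- function(params = NULL, s, p0, U0, u_p, r, N = 1000,
                      fix_threshold = 0.99, run_threshold = 1 - 1e-9,
                      max_generations = 1e5) {
  if (is.null(params)) {
    params <- sweep_params(s = s, p0 = p0, U0 = U0, u_p = u_p, r = r, N = N,
                           fix_threshold = fix_threshold,
                           run_threshold = run_threshold,
                           max_generations = max_generations)
  } else if (!inherits(params, "sweep_params")) {
    params <- do.call(sweep_params, params)
  }

  x <- unlist(init_haplotypes(params$p0, params$U0, params$u_p),
              use.names = FALSE)
  max_g <- as.integer(params$max_generations)
  p_vec <- numeric(max_g + 1L)
  u_vec <- numeric(max_g + 1L)
  dp_vec <- numeric(max_g + 1L)

  s <- params$s
  r <- params$r
  g <- 0L
  t_fix <- NA_integer_
  repeat {
    p <- x[1] + x[2]
    U <- x[1] + x[3]
    D <- x[1] * x[4] - x[2] * x[3]
    dmax <- if (D > 0) min(p * (1 - U), (1 - p) * U) else
      min(p * U, (1 - p) * (1 - U))
    p_vec[g + 1L] <- p
    u_vec[g + 1L] <- U
    dp_vec[g + 1L] <- if (dmax <= 0) 0 else D / dmax
    if (is.na(t_fix) && p > params$fix_threshold) t_fix <- g
    if (p > params$run_threshold || g >= max_g) break
    wbar <- 1 + s * p
    x <- x * c(1 + s, 1 + s, 1, 1) / wbar
    d_sel <- x[1] * x[4] - x[2] * x[3]
    x <- x + r * d_sel * c(-1, 1, 1, -1)
    x[x < 0 & x > -1e-15] <- 0
    x <- x / sum(x)
    g <- g + 1L
  }

  keep <- seq_len(g + 1L)
  trajectory <- tibble(generation = keep - 1L, p = p_vec[keep],
                       U = u_vec[keep], Dprime = dp_vec[keep])
  structure(
    list(trajectory = trajectory,
         T_fix = t_fix,
         delta_U = u_vec[g + 1L] - params$U0,
         complete = !is.na(t_fix),
         params = params),
    class = "sweep_fit")
}

#' @export
print.sweep_fit <- function(x, ...) {
  cat("Deterministic two-locus sweep\n")
  cat(sprintf("  s = %g, p0 = %g, U0 = %g, u_p = %g, r = %g\n",
              x$params$s, x$params$p0, x$params$U0, x$params$u_p, x$params$r))
  cat(sprintf("  generations run: %d\n", nrow(x$trajectory) - 1L))
  if (x$complete) {
    cat(sprintf("  T_fix (p > %g): %d generations\n",
                x$params$fix_threshold, x$T_fix))
  } else {
    cat("  selected allele did not pass the fixation threshold\n")
  }
  cat(sprintf("  delta_U: %.4f\n", x$delta_U))
  invisible(x)
}

#' @rdname run_sweep
#' @param x A `"sweep_fit"` object.
#' @param ... Unused.
#' @export
tidy.sweep_fit <- function(x, ...) x$trajectory

#' @rdname run_sweep
#' @export
glance.sweep_fit <- function(x, ...) {
  tibble(T_fix = x$T_fix, delta_U = x$delta_U,
         generations = nrow(x$trajectory) - 1L, complete = x$complete,
         s = x$params$s, p0 = x$params$p0, U0 = x$params$U0,
         u_p = x$params$u_p, r = x$params$r)
}

#' @rdname run_sweep
#' @param object A `"sweep_fit"` object.
#' @export
autoplot.sweep_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trajectory, c("p", "U", "Dprime"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = NULL, colour = NULL,
                  title = "Two-locus hitchhiking trajectory") +
    ggplot2::theme_minimal()
}

#' Analytic hard-sweep hitchhiking solution
#'
#' Closed-form change in neutral-allele frequency for a neutral allele
#' initially in complete association with the selected allele (`u_p = 1`):
#' the association surviving the sweep is `p0^(r / s)`, so
#' `delta_U = (1 - U0) * p0^(r / s)`. At `r = 0` this is the complete
#' hitchhike `1 - U0`; it decays towards 0 as `r / s` grows.
#'
#' @inheritParams sweep_params
#' @return The predicted `delta_U` (numeric, vectorized over `r`).
#' @export
#' @examples
#' analytic_hard_sweep(s = 0.25, p0 = 5e-4, U0 = 0.05, r = 0.001)
analytic_hard_sweep <- function(s, p0, U0, r) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    abort("`s` must be a single positive selection coefficient")
  if (p0 <= 0 || p0 >= 1) abort("`p0` must lie strictly in (0, 1)")
  if (U0 < 0 || U0 > 1) abort("`U0` must lie in [0, 1]")
  if (any(r < 0 | r > 0.5)) abort("`r` must lie in [0, 0.5]")
  (1 - U0) * p0^(r / s)
}

#' Scan delta_U and T_fix over a recombination grid
#'
#' Runs one deterministic sweep per recombination fraction and returns a
#' plot-ready table. With `u_p >= U0`, `delta_U` is non-increasing in `r`.
#'
#' @param r_grid Numeric vector of recombination fractions in \[0, 0.5\].
#' @inheritParams sweep_params
#' @return A tibble with columns `r`, `delta_U`, `T_fix`.
#' @export
#' @examples
#' scan_recombination(c(0, 0.001, 0.005), s = 0.25, p0 = 5e-4, U0 = 0.05,
#'                    u_p = 1)
scan_recombination <- function(r_grid, s, p0, U0, u_p, N = 1000,
                               fix_threshold = 0.99,
                               run_threshold = 1 - 1e-9,
                               max_generations = 1e5) {
  if (length(r_grid) == 0) abort("`r_grid` must contain at least one value")
  if (any(r_grid < 0 | r_grid > 0.5)) abort("`r_grid` must lie in [0, 0.5]")
  purrr::map_dfr(r_grid, function(r) {
    fit <- run_sweep(s = s, p0 = p0, U0 = U0, u_p = u_p, r = r, N = N,
                     fix_threshold = fix_threshold,
                     run_threshold = run_threshold,
                     max_generations = max_generations)
    tibble(r = r, delta_U = fit$delta_U, T_fix = fit$T_fix)
  })
}
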