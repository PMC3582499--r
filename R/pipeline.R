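## End-to-end orchestration: generate synthetic inputs, run the analysis
## stages, and write text artifacts plus a manifest. One global seed fans out
## to per-stage child seeds (seed + 1000 * stage index) so stages are
## independently reproducible.

round_sig <- function(x, sig = 3) signif(x, sig)

#' Run the analysis pipeline on synthetic or provided inputs
#'
#' Executes the requested stages in order: `"markers"` (synthetic population
#' markers, diversity stats, Fst, island-model null, outlier p-values),
#' `"mapping"` (synthetic backcross, recombinant calling, map distances) and
#' `"blocks"` (synthetic inviability blocks, rates, carrier classes,
#' reciprocal test), plus `"sweep"` (deterministic recombination scan).
#' Every run writes a `manifest.json` (configuration echo, package and R
#' versions, seed, stage timings) next to the outputs. Numeric report fields
#' are rounded for byte-stable text output: centimorgans to 2 decimals,
#' He/Fst to 3 decimals, p-values to 3 significant figures.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Global seed; stage seeds are derived from it.
#' @param stages Character subset of
#'   `c("markers", "mapping", "blocks", "sweep")`.
#' @param config Named list of per-stage parameter overrides, merged over the
#'   defaults; may also be a path to a JSON file with the same structure.
#' @return Invisibly, a tibble of stage timings.
#' @export
#' @examples
#' \donttest{
#' out <- run_pipeline(tempfile("demo"), seed = 1,
#'                     stages = c("mapping", "blocks"))
#' }
run_pipeline <- function(out_dir, seed = 1,
                         stages = c("markers", "mapping", "blocks", "sweep"),
                         config = list()) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  run_stage <- function(name, f) {
    t0 <- Sys.time()
    tryCatch(f(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  stage_seed <- function(i) seed + 1000L * i
  cfg <- function(stage, defaults) {
    utils::modifyList(defaults, config[[stage]] %||% list())
  }

  if ("markers" %in% stages) run_stage("markers", function() {
    pars <- cfg("markers", list(N = 300, n_mine = 54, n_off = 36,
                                burnin = 3000, n_sims = 5000,
                                loci_per_eval = 2000))
    d <- gen_population_markers(
      N = pars$N, n_mine = pars$n_mine, n_off = pars$n_off,
      burnin = pars$burnin, seed = stage_seed(1L))
    write_markers_tsv(d$markers, file.path(out_dir, "markers.tsv"))
    stats <- locus_stats(d$markers)
    stats$exp_het <- round(stats$exp_het, 3)
    readr::write_tsv(stats, file.path(out_dir, "locus_stats.tsv"))
    pooled <- pool_populations(d$markers, list(off = c("off1", "off2")))
    fst <- wc_fst(pooled)
    set.seed(stage_seed(2L))
    nul <- fdist_null(
      dplyr::filter(fst, .data$locus_class == "unlinked"),
      sample_sizes = c(2 * pars$n_mine, 2 * pars$n_off),
      n_sims = pars$n_sims, loci_per_eval = pars$loci_per_eval)
    outl <- outlier_pvalues(fst, nul)
    outl$fst <- round(outl$fst, 3)
    outl$he_pooled <- round(outl$he_pooled, 3)
    outl$p_value <- round_sig(outl$p_value)
    readr::write_tsv(outl, file.path(out_dir, "fst_outliers.tsv"))
    jsonlite::write_json(
      list(M = nul$M, target_fst = round_sig(nul$target_fst),
           mean_fst = round_sig(nul$mean_fst), n_sims = nul$n_sims,
           n_outliers_0025 = sum(outl$sig_0025)),
      file.path(out_dir, "fdist_summary.json"), auto_unbox = TRUE)
  })

  if ("mapping" %in% stages) run_stage("mapping", function() {
    pars <- cfg("mapping", list(n = 4340, phenotyping_error = 0,
                                focal_marker = "M242"))
    pop <- gen_mapping_population(n = pars$n,
                                  phenotyping_error = pars$phenotyping_error,
                                  seed = stage_seed(3L))
    write_geno_matrix(pop$genotypes, file.path(out_dir, "genotypes.tsv"),
                      marker_order = pop$loci$locus[pop$loci$type == "marker"])
    calls <- call_recombinants(pop$genotypes, pop$phenotypes,
                               pars$focal_marker)
    dist <- map_distance(sum(calls$recombinant), nrow(calls))
    dist$ci_lower_cM <- round(dist$ci_lower_cM, 2)
    dist$ci_upper_cM <- round(dist$ci_upper_cM, 2)
    readr::write_tsv(dist, file.path(out_dir, "map_distance.tsv"))
  })

  if ("blocks" %in% stages) run_stage("blocks", function() {
    d <- gen_inviability_blocks(seed = stage_seed(4L))
    readr::write_tsv(d$blocks, file.path(out_dir, "blocks.tsv"))
    lines <- classify_carrier(inviability_rates(d$blocks))
    out <- dplyr::select(lines, -"rates")
    out$mean_rate <- round(out$mean_rate, 3)
    out$distance_to_threshold <- round(out$distance_to_threshold, 3)
    readr::write_tsv(out, file.path(out_dir, "line_inviability.tsv"))
  })

  if ("sweep" %in% stages) run_stage("sweep", function() {
    pars <- cfg("sweep", list(s = 0.25, p0 = 5e-4, U0 = 0.05, u_p = 1,
                              r_grid = seq(0, 0.005, length.out = 11)))
    scan <- scan_recombination(pars$r_grid, s = pars$s, p0 = pars$p0,
                               U0 = pars$U0, u_p = pars$u_p)
    scan$delta_U <- round(scan$delta_U, 4)
    readr::write_tsv(scan, file.path(out_dir, "sweep_scan.tsv"))
  })

  manifest <- list(
    package = "sweeplink",
    version = as.character(utils::packageVersion("sweeplink")),
    r_version = R.version.string,
    seed = seed,
    stages = stages,
    config = config,
    timings_sec = lapply(timings, function(x) round(x, 3)),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(tibble(stage = names(timings),
                   seconds = unlist(timings, use.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
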