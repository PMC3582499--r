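make_pop <- function(n = 200, r = 0.05, error = 0, seed = 1) {
  loci <- tibble::tibble(locus = c("mk", "TRAIT"),
                         type = c("marker", "trait"), r_next = c(r, NA))
  gen_mapping_population(n = n, loci = loci, phenotyping_error = error,
                         replicate_count = 3, seed = seed)
}

test_that("recombinant calling flags marker-phenotype discordance", {
  geno <- tibble::tibble(individual = c("a", "b", "c", "d"), marker = "mk",
                         genotype = c("H", "A", "H", NA))
  phen <- tibble::tibble(individual = c("a", "b", "c", "d"),
                         tolerant = c(TRUE, TRUE, FALSE, TRUE))
  expect_warning(calls <- call_recombinants(geno, phen, "mk"), "skipped")
  expect_equal(calls$recombinant[calls$individual == "a"], FALSE)
  expect_equal(calls$recombinant[calls$individual == "b"], TRUE)
  expect_equal(calls$recombinant[calls$individual == "c"], TRUE)
  expect_false("d" %in% calls$individual)
  expect_error(call_recombinants(geno, phen, "nope"), "not genotyped")
})

test_that("recombinant counts track the generating recombination fraction", {
  pop <- make_pop(n = 4340, r = 0.0083, seed = 42)
  calls <- call_recombinants(pop$genotypes, pop$phenotypes, "mk")
  k <- sum(calls$recombinant)
  band <- stats::qbinom(c(0.025, 0.975), 4340, 0.0083)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
  # calls agree exactly with the generator's truth labels at zero error
  truth <- pop$truth$crossover_mk_TRAIT[match(calls$individual,
                                              pop$truth$individual)]
  expect_equal(calls$recombinant, truth)
})

test_that("replicate confirmation demotes inconsistent putative recombinants", {
  calls <- tibble::tibble(individual = c("a", "b", "c"),
                          marker_genotype = c("A", "A", "A"),
                          tolerant = c(TRUE, TRUE, TRUE),
                          implied_genotype = "H", recombinant = TRUE)
  rg <- tibble::tibble(individual = rep(c("a", "b"), each = 3),
                       replicate = rep(1:3, 2),
                       genotype = c("A", "A", "A", "A", "H", "A"))
  rp <- tibble::tibble(individual = rep(c("a", "b"), each = 3),
                       replicate = rep(1:3, 2), tolerant = TRUE)
  out <- confirm_recombinants(calls, rg, rp)
  expect_true(out$confirmed[out$individual == "a"])
  expect_false(out$confirmed[out$individual == "b"])
  expect_match(out$demotion[out$individual == "b"], "genotype")
  expect_false(out$confirmed[out$individual == "c"])
  expect_match(out$demotion[out$individual == "c"], "no replicates")
  # majority policy rescues the 2/3-concordant line
  out2 <- confirm_recombinants(calls[2, ], rg, rp, policy = "majority")
  expect_true(out2$confirmed)
})

test_that("confirmation removes nearly all false positives caused by phenotyping error", {
  pop <- make_pop(n = 4000, r = 0.004, error = 0.01, seed = 9)
  first_rep <- dplyr::filter(pop$phenotypes, .data$replicate == 1)
  calls <- call_recombinants(pop$genotypes, first_rep, "mk")
  truth <- pop$truth$crossover_mk_TRAIT[match(calls$individual,
                                              pop$truth$individual)]
  false_pos <- calls$recombinant & !truth
  expect_gt(sum(false_pos), 0) # the error process must have produced some
  confirmed <- confirm_recombinants(
    calls, replicate_geno = tibble::tibble(
      individual = calls$individual, replicate = 1,
      genotype = calls$marker_genotype),
    replicate_phen = dplyr::filter(pop$phenotypes, .data$replicate > 1))
  still_false <- confirmed$confirmed &
    !pop$truth$crossover_mk_TRAIT[match(confirmed$individual,
                                        pop$truth$individual)]
  expect_lte(sum(still_false), 0.1 * sum(false_pos))
})

test_that("map distances reproduce the published point estimates", {
  expect_equal(map_distance(36, 4340)$distance_cM, 0.83)
  expect_equal(map_distance(14, 4340)$distance_cM, 0.32)
  zero <- map_distance(0, 1000)
  expect_equal(zero$distance_cM, 0)
  expect_equal(zero$ci_lower_cM, 0)
  expect_error(map_distance(3, 0), "positive")
  expect_error(map_distance(5, 4), "n_total")
})

test_that("the exact CI covers the truth at close to nominal rate", {
  set.seed(21)
  r_true <- 0.005
  n <- 1000
  draws <- stats::rbinom(1000, n, r_true)
  est <- map_distance(draws, rep(n, 1000))
  covered <- est$ci_lower_cM <= 100 * r_true & est$ci_upper_cM >= 100 * r_true
  expect_gte(mean(covered), 0.93)
})

test_that("breakpoint imputation places intervals and unknown segments correctly", {
  out <- impute_breakpoints(geno_df(c("H", "H", "A", "A")), paste0("m", 1:4))
  expect_equal(nrow(out$breakpoints), 1L)
  expect_equal(out$breakpoints$left, 2L)
  expect_equal(out$breakpoints$right, 3L)

  out2 <- impute_breakpoints(geno_df(c("H", NA, "A")), paste0("m", 1:3))
  expect_equal(out2$breakpoints$left, 1L)
  expect_equal(out2$breakpoints$right, 3L)
  expect_true(any(out2$segments$state == "unknown" &
                    out2$segments$start == 2 & out2$segments$end == 2))

  expect_warning(
    out3 <- impute_breakpoints(geno_df(c("A", "H", "A")), paste0("m", 1:3)),
    "more than one")
  expect_equal(nrow(out3$breakpoints), 2L)
  expect_true(out3$flags$double_recombinant)

  expect_error(impute_breakpoints(geno_df(c(NA, NA)), c("m1", "m2")),
               "all markers missing")
})

test_that("imputed segments tile the marker order exactly once", {
  set.seed(31)
  for (rep in 1:25) {
    L <- sample(3:10, 1)
    g <- sample(c("H", "A", NA), L, replace = TRUE,
                prob = c(0.4, 0.4, 0.2))
    if (all(is.na(g))) g[1] <- "H"
    out <- suppressWarnings(impute_breakpoints(geno_df(g), paste0("m", 1:L)))
    seg <- dplyr::arrange(out$segments, .data$start)
    covered <- unlist(purrr::map2(seg$start, seg$end, seq))
    expect_equal(covered, 1:L)
  }
})

test_that("locus localization intersects breakpoint constraints", {
  mk <- paste0("m", 1:6)
  cons <- tibble::tibble(individual = c("r1", "r2"),
                         side = c("right_of", "left_of"),
                         marker = c("m3", "m5"))
  loc <- localize_locus(cons, mk)
  expect_equal(loc$lower_marker, "m3")
  expect_equal(loc$upper_marker, "m5")
  expect_equal(loc$lower_by, "r1")

  # adding a consistent constraint can only narrow the interval
  cons2 <- dplyr::bind_rows(cons, tibble::tibble(
    individual = "r3", side = "right_of", marker = "m4"))
  loc2 <- localize_locus(cons2, mk)
  expect_gte(loc2$interval["lower"], loc$interval["lower"])
  expect_lte(loc2$interval["upper"], loc$interval["upper"])

  conflict <- tibble::tibble(individual = c("r1", "r2"),
                             side = c("right_of", "left_of"),
                             marker = c("m5", "m2"))
  expect_error(localize_locus(conflict, mk), "r1.*r2|r2.*r1")
})

test_that("localization recovers a known locus from error-free synthetic recombinants", {
  # truth: locus between markers 3 and 4 of a 6-marker chain
  loci <- tibble::tibble(
    locus = c("m1", "m2", "m3", "TRAIT", "m4", "m5", "m6"),
    type = c(rep("marker", 3), "trait", rep("marker", 3)),
    r_next = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01, NA))
  informative <- 0
  contains_truth <- 0
  for (seed in 1:200) {
    pop <- gen_mapping_population(n = 120, loci = loci,
                                  replicate_count = 1, seed = seed)
    imp <- suppressWarnings(
      impute_breakpoints(pop$genotypes, paste0("m", 1:6)))
    bp <- dplyr::inner_join(
      imp$breakpoints,
      dplyr::distinct(pop$phenotypes, .data$individual, .data$tolerant),
      by = "individual")
    bp <- dplyr::semi_join(
      bp, dplyr::filter(imp$flags, !.data$double_recombinant),
      by = "individual")
    if (nrow(bp) == 0) next
    informative <- informative + 1
    state <- ifelse(bp$tolerant, "H", "A")
    cons <- tibble::tibble(
      individual = bp$individual,
      side = ifelse(state == bp$left_state, "left_of", "right_of"),
      marker = ifelse(state == bp$left_state, paste0("m", bp$right),
                      paste0("m", bp$left)))
    loc <- localize_locus(cons, paste0("m", 1:6))
    if (loc$interval["lower"] <= 3 && loc$interval["upper"] >= 4)
      contains_truth <- contains_truth + 1
  }
  expect_gt(informative, 100)
  expect_equal(contains_truth, informative) # error-free calls never exclude it
})

test_that("marker-trait association matches hypergeometric enumeration", {
  perfect <- make_assoc_data(40, 40, discordant = 0)
  out <- marker_trait_association(perfect$geno, perfect$phen, "mk")
  expect_lt(out$p_value, 1e-15)

  indep <- tibble::tibble(individual = sprintf("i%02d", 1:80))
  geno <- tibble::tibble(individual = indep$individual, marker = "mk",
                         genotype = rep(c("H", "A"), each = 40))
  phen <- tibble::tibble(individual = indep$individual,
                         tolerant = rep(c(TRUE, FALSE), 40))
  expect_equal(marker_trait_association(geno, phen, "mk")$p_value, 1)

  # one discordant individual out of 80: oracle by direct hypergeometric sums
  one <- make_assoc_data(40, 40, discordant = 1)
  p_obs <- marker_trait_association(one$geno, one$phen, "mk")$p_value
  p_oracle <- local({
    # P(table at least as extreme), summing both tails of the hypergeometric
    # with margins 40/40 and 40 tolerant
    dens <- stats::dhyper(0:40, 40, 40, 40)
    sum(dens[dens <= stats::dhyper(39, 40, 40, 40) * (1 + 1e-7)])
  })
  expect_equal(p_obs, p_oracle, tolerance = 1e-10)

  degen <- tibble::tibble(individual = sprintf("i%02d", 1:12))
  geno_d <- tibble::tibble(individual = degen$individual, marker = "mk",
                           genotype = "H")
  phen_d <- tibble::tibble(individual = degen$individual,
                           tolerant = rep(c(TRUE, FALSE), 6))
  expect_warning(out_d <- marker_trait_association(geno_d, phen_d, "mk"),
                 "degenerate")
  expect_equal(out_d$p_value, 1)
})
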