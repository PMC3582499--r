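test_that("mapping-population generator honors degenerate settings and truth labels", {
  loci <- tibble::tibble(locus = c("mk", "TRAIT"),
                         type = c("marker", "trait"), r_next = c(0, NA))
  pop <- gen_mapping_population(n = 300, loci = loci, seed = 5)
  calls <- call_recombinants(pop$genotypes, pop$phenotypes, "mk")
  expect_equal(sum(calls$recombinant), 0L)
  expect_true(all(pop$truth$n_breakpoints == 0))

  # truth-vs-called confusion matrix is the identity at zero error
  pop2 <- gen_mapping_population(n = 1000, seed = 8)
  calls2 <- call_recombinants(pop2$genotypes, pop2$phenotypes, "M242")
  crosses <- pop2$truth[match(calls2$individual, pop2$truth$individual), ]
  truth_rec <- rowSums(as.matrix(
    crosses[, grepl("^crossover_", names(crosses))])) %% 2 == 1
  # recombinant between marker and trait = odd number of crossovers between
  expect_equal(calls2$recombinant, unname(truth_rec))
})

test_that("generators are pure functions of their seed", {
  a <- gen_mapping_population(n = 500, seed = 11)
  b <- gen_mapping_population(n = 500, seed = 11)
  expect_identical(a, b)
  c <- gen_mapping_population(n = 500, seed = 12)
  expect_false(identical(a$genotypes, c$genotypes))

  m1 <- gen_population_markers(N = 80, burnin = 200, n_mine = 10, n_off = 10,
                               generations = 40, seed = 21)
  m2 <- gen_population_markers(N = 80, burnin = 200, n_mine = 10, n_off = 10,
                               generations = 40, seed = 21)
  expect_identical(m1$markers, m2$markers)

  b1 <- gen_inviability_blocks(seed = 31)
  b2 <- gen_inviability_blocks(seed = 31)
  expect_identical(b1$blocks, b2$blocks)
})

test_that("inviability blocks follow the binomial law and honor bounds", {
  zero <- gen_inviability_blocks(tibble::tibble(
    line = "z", tolerance_class = "nontolerant", true_rate = 0,
    n_blocks = 4L), seed = 1)
  expect_true(all(zero$blocks$n_inviable == 0))

  many <- gen_inviability_blocks(tibble::tibble(
    line = "m", tolerance_class = "tolerant", true_rate = 0.5,
    n_blocks = 10000L), seed = 2)
  expect_equal(mean(many$blocks$n_inviable / 60), 0.5, tolerance = 0.01)

  expect_error(gen_inviability_blocks(tibble::tibble(
    line = "bad", tolerance_class = "x", true_rate = 1.2, n_blocks = 2L)),
    "true_rate")
})

test_that("paper-shaped defaults give the documented design sizes", {
  expect_equal(nrow(default_map_loci()), 6L)
  specs <- default_line_specs()
  expect_equal(nrow(specs), 18L)
  expect_true(all(specs$n_blocks >= 2 & specs$n_blocks <= 8))
  expect_true(all(specs$true_rate[specs$tolerance_class == "tolerant"] >= 0.45))
  expect_true(all(specs$true_rate[specs$tolerance_class == "nontolerant"] <= 0.15))
  # marker chain spans 0.83 cM from the founding marker to the trait locus
  expect_equal(sum(default_map_loci()$r_next, na.rm = TRUE), 0.0083)
})

test_that("without selection, linked and unlinked loci are exchangeable", {
  diffs <- vapply(1:12, function(seed) {
    d <- gen_population_markers(N = 60, burnin = 150, n_mine = 15,
                                n_off = 15, generations = 30, s = 0,
                                seed = seed)
    st <- locus_stats(d$markers)
    mine <- st[st$population == "mine", ]
    mean(mine$exp_het[mine$locus_class == "linked"]) -
      mean(mine$exp_het[mine$locus_class == "unlinked"])
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.05)
})

test_that("the default sweep scenario erodes diversity at linked loci only", {
  hits <- vapply(1:10, function(seed) {
    d <- gen_population_markers(N = 250, burnin = 2500, n_mine = 30,
                                n_off = 20, seed = seed)
    st <- locus_stats(d$markers)
    mine <- st[st$population == "mine", ]
    mean(mine$exp_het[mine$locus_class == "linked"]) <
      mean(mine$exp_het[mine$locus_class == "unlinked"])
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("the forward simulator rejects infeasible founder settings", {
  expect_error(gen_population_markers(N = 50, founder_copies = 0), "founder")
  expect_error(gen_population_markers(N = 50, founder_copies = 101),
               "founder")
  expect_error(gen_population_markers(N = 50, r_linked = c(0.1, 0.7)),
               "r_linked")
})

test_that("generator output round-trips through the package readers", {
  d <- gen_population_markers(N = 60, burnin = 150, n_mine = 8, n_off = 8,
                              generations = 20, seed = 44)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_markers_tsv(d$markers, tmp)
  back <- read_markers_tsv(tmp)
  expect_equal(as.data.frame(back[names(back) != "locus_class"]),
               as.data.frame(d$markers[names(d$markers) != "locus_class"]))

  gp <- withr::local_tempfile(fileext = ".gen")
  # genepop codes cap at 3 digits; compress labels first
  lv <- sort(unique(c(d$markers$allele_1, d$markers$allele_2)))
  small <- dplyr::mutate(
    d$markers,
    allele_1 = match(.data$allele_1, lv),
    allele_2 = match(.data$allele_2, lv))
  write_genepop(small, gp)
  back2 <- read_genepop(gp)
  expect_equal(nrow(back2), nrow(small))
  expect_equal(sort(unique(back2$locus)), sort(unique(small$locus)))
})
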