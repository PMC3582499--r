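test_that("init_haplotypes reproduces the defining arithmetic and rejects infeasible input", {
  expect_equal(unlist(init_haplotypes(0.05, 0.05, 1)),
               c(x_AB = 0.05, x_Ab = 0, x_aB = 0, x_ab = 0.95))
  expect_equal(unlist(init_haplotypes(0.0005, 0.05, 1)),
               c(x_AB = 0.0005, x_Ab = 0, x_aB = 0.0495, x_ab = 0.95))
  expect_error(init_haplotypes(0.05, 0.01, 1), "below p0 \\* u_p")
  expect_error(init_haplotypes(0.9, 0.5, 0), "exceeds")
  expect_error(init_haplotypes(1.2, 0.5, 1), "p0")
})

test_that("one recursion step applies selection then recombination correctly", {
  # neutral state at linkage equilibrium is a fixed point
  st <- init_haplotypes(0.3, 0.4, 0.4)
  expect_equal(unlist(sweep_step(st, s = 0, r = 0.1)), unlist(st),
               tolerance = 1e-12)
  # single-locus marginal after one selected step: p' = p(1+s)/(1+sp)
  st2 <- init_haplotypes(0.5, 0.5, 1)
  out <- sweep_step(st2, s = 0.25, r = 0)
  expect_equal(hap_summary(out)$p, 0.5 * 1.25 / 1.125, tolerance = 1e-12)
  # free recombination halves D in one neutral generation
  st3 <- init_haplotypes(0.4, 0.3, 0.6)
  d_before <- hap_summary(st3)$D
  d_after <- hap_summary(sweep_step(st3, s = 0, r = 0.5))$D
  expect_equal(d_after, 0.5 * d_before, tolerance = 1e-12)
})

test_that("run_sweep reaches fixation at the expected generation", {
  # odds multiply by (1+s) per generation; frozen from the scalar recursion
  fit <- run_sweep(s = 0.25, p0 = 0.0005, U0 = 0.05, u_p = 1, r = 0)
  expect_equal(fit$T_fix, 55L)
  fit2 <- run_sweep(s = 0.1, p0 = 0.5, U0 = 0.5, u_p = 0.5, r = 0.1)
  expect_equal(fit2$T_fix, 49L)
  # the maximum hitchhike: complete association, no recombination
  expect_equal(round(fit$delta_U, 2), 0.95)
})

test_that("an incomplete sweep is flagged and T_fix is absent", {
  fit <- run_sweep(s = 0.01, p0 = 0.001, U0 = 0.05, u_p = 1, r = 0,
                   max_generations = 50)
  expect_false(fit$complete)
  expect_true(is.na(fit$T_fix))
})

test_that("haplotype frequencies stay on the simplex and p matches the scalar recursion", {
  grid <- expand.grid(s = c(0, 0.1, 0.25), r = c(0, 0.005, 0.5),
                      u_p = c(0.5, 1))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    st <- init_haplotypes(0.05, 0.05, g$u_p)
    x <- st
    for (t in 1:30) {
      x <- sweep_step(x, g$s, g$r)
      expect_equal(sum(unlist(x)), 1, tolerance = 1e-12)
    }
    fit <- run_sweep(s = g$s, p0 = 0.05, U0 = 0.05, u_p = g$u_p, r = g$r,
                     max_generations = 40)
    expect_equal(fit$trajectory$p,
                 odds_recursion_p(g$s, 0.05, nrow(fit$trajectory) - 1),
                 tolerance = 1e-9)
  }
})

test_that("neutral dynamics leave both allele frequencies constant", {
  fit <- run_sweep(s = 0, p0 = 0.3, U0 = 0.4, u_p = 0.8, r = 0.2,
                   max_generations = 50)
  expect_true(all(abs(fit$trajectory$p - 0.3) < 1e-12))
  expect_true(all(abs(fit$trajectory$U - 0.4) < 1e-12))
})

test_that("delta_U respects its upper bound and grows with initial association", {
  # bound: delta_U <= 1 - U0 under every tried configuration
  for (u_p in seq(0.5, 1, by = 0.1)) {
    fit <- run_sweep(s = 0.25, p0 = 0.05, U0 = 0.05, u_p = u_p, r = 0.001)
    expect_lte(fit$delta_U, 1 - 0.05 + 1e-12)
  }
  # soft-sweep attenuation: delta_U non-decreasing in u_p at fixed s, r
  for (r in c(0.001, 0.005)) {
    dus <- vapply(seq(0.5, 1, by = 0.1), function(u_p) {
      run_sweep(s = 0.1, p0 = 0.05, U0 = 0.05, u_p = u_p, r = r)$delta_U
    }, numeric(1))
    expect_true(all(diff(dus) >= -1e-9))
  }
})

test_that("analytic hard-sweep solution has the right limits", {
  expect_equal(analytic_hard_sweep(0.25, 5e-4, 0.05, 0), 0.95)
  expect_lt(analytic_hard_sweep(0.05, 5e-4, 0.05, 0.5), 0.01)
  expect_error(analytic_hard_sweep(-0.1, 5e-4, 0.05, 0), "positive")
  expect_error(analytic_hard_sweep(0.1, 5e-4, 0.05, 0.6), "0.5")
})

test_that("scan_recombination emits a monotone plot-ready table", {
  one <- scan_recombination(0, s = 0.25, p0 = 0.05, U0 = 0.05, u_p = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$delta_U, 0.95, tolerance = 1e-6)

  scan <- scan_recombination(c(0, 0.005, 0.5), s = 0.25, p0 = 5e-4,
                             U0 = 0.05, u_p = 1)
  expect_true(all(diff(scan$delta_U) < 0))

  # no initial association, no hitchhike
  flat <- scan_recombination(c(0, 0.01, 0.5), s = 0.25, p0 = 0.05,
                             U0 = 0.05, u_p = 0.05)
  expect_true(all(abs(flat$delta_U) < 1e-6))

  expect_error(scan_recombination(numeric(0), s = 0.1, p0 = 0.1, U0 = 0.05,
                                  u_p = 1), "at least one")
})

test_that("sweep_fit accessors expose the trajectory and summary", {
  fit <- run_sweep(s = 0.25, p0 = 0.05, U0 = 0.05, u_p = 1, r = 0.001)
  expect_named(tidy(fit), c("generation", "p", "U", "Dprime"))
  g <- glance(fit)
  expect_equal(g$delta_U, fit$delta_U)
  expect_s3_class(autoplot(fit), "ggplot")
})
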