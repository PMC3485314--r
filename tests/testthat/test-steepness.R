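cfg <- load_config("abft_baseline")

test_that("population ages follow the survivorship distribution", {
  vr <- draw_vital_rates(cfg)
  # two equally likely ages
  vr2 <- vr; vr2$l <- c(1, 1, rep(0, 28))
  set.seed(501)
  pop <- simulate_population(vr2, cfg, N = 4000)
  p1 <- mean(pop$ages == 1)
  expect_true(all(pop$ages %in% 1:2))
  expect_within(p1, 0.5, 3 * sqrt(0.25 / 4000))
  # full survivorship curve: empirical frequencies match l(a)/sum(l)
  set.seed(502)
  pop <- simulate_population(vr, cfg, N = 1e5)
  emp <- tabulate(pop$ages, 30) / 1e5
  expected <- vr$l / sum(vr$l)
  expect_lt(max(abs(emp - expected)), 0.006)
})

test_that("spawning biomass scales linearly with population size", {
  vr <- draw_vital_rates(cfg)
  set.seed(503)
  b1 <- mean(replicate(40, simulate_population(vr, cfg, N = 500)$B_sim))
  b2 <- mean(replicate(40, simulate_population(vr, cfg, N = 1000)$B_sim))
  expect_within(b2 / b1, 2, 0.1)
})

test_that("simulate_population guards its preconditions", {
  vr <- draw_vital_rates(cfg)
  expect_error(simulate_population(vr, cfg, N = 50), "at least 100")
  immature <- modify_config(cfg, list(fecundity = list()))
  immature$fecundity$maturity <- rep(0, 30)
  expect_error(simulate_population(vr, immature, N = 500), "no mature age")
})

test_that("alpha is the discounted egg-per-biomass ratio", {
  pop <- structure(list(F_sim = 1.9e5, B_sim = 1), class = "population_sample")
  expect_equal(alpha_recruits(pop, 12.5), exp(-12.5) * 1.9e5)
  expect_equal(alpha_recruits(pop, 12.5), 0.708, tolerance = 1e-3)
  expect_lt(alpha_recruits(pop, 50), 1e-15)       # M_0 -> Inf gives alpha -> 0
  pop0 <- structure(list(F_sim = 0, B_sim = 0), class = "population_sample")
  expect_error(alpha_recruits(pop0, 1), "B_sim")
})

test_that("spawning biomass per recruit composes from the survivorship", {
  vr <- draw_vital_rates(cfg, noise = FALSE)
  expect_equal(spawning_biomass_per_recruit(vr), sum(vr$l * vr$W * vr$g))
  vr0 <- vr; vr0$g <- rep(0, 30)
  expect_equal(spawning_biomass_per_recruit(vr0), 0)
})

test_that("steepness hits its anchors and asymptote", {
  # replacement-level recruitment: alpha * sr * W_bpr = 1 gives exactly 0.2
  expect_equal(bh_steepness(1 / (0.5 * 470), 0.5, 470), 0.2)
  # printed-quantile composition: alpha 0.55, sr 0.5, W_bpr 470
  expect_equal(bh_steepness(0.55, 0.5, 470), 0.96998, tolerance = 1e-5)
  expect_equal(bh_steepness(Inf, 0.5, 470), 1)
  expect_equal(bh_steepness(0, 0.5, 470), 0)
  expect_error(bh_steepness(-1, 0.5, 470), ">= 0")
})

test_that("steepness is monotone in alpha and W_bpr, decreasing in M_0", {
  a <- seq(0.01, 2, length.out = 20)
  expect_true(all(diff(bh_steepness(a, 0.5, 470)) > 0))
  w <- seq(100, 900, length.out = 20)
  expect_true(all(diff(bh_steepness(0.5, 0.5, w)) > 0))
  pop <- structure(list(F_sim = 1.9e5, B_sim = 1), class = "population_sample")
  h_m0 <- vapply(seq(8, 20, 2), function(m0) {
    bh_steepness(alpha_recruits(pop, m0), 0.5, 470)
  }, numeric(1))
  expect_true(all(diff(h_m0) < 0))
})

test_that("alpha above 0.1 recruits/kg implies steepness above 0.8", {
  ens <- baseline_ensemble()
  idx <- ens$pops$alpha > 0.1
  expect_gt(sum(idx), 50)
  expect_true(all(ens$pops$h[idx] > 0.8))
})

test_that("alpha statistics are stable in the population size", {
  # paired design: identical vital rates, two population sizes, so any
  # difference is purely finite-population sampling noise
  set.seed(504)
  rel_diff <- replicate(100, {
    vr <- draw_vital_rates(cfg)
    a1 <- alpha_recruits(simulate_population(vr, cfg, 1000), 12.5)
    a2 <- alpha_recruits(simulate_population(vr, cfg, 4000), 12.5)
    (a2 - a1) / a1
  })
  expect_lt(median(abs(rel_diff)), 0.05)
  expect_within(mean(rel_diff), 0, 0.02)
})
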