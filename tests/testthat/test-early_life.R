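cfg <- load_config("abft_baseline")

# deterministic central trajectory: all stage parameters at their centers
central <- list(t_hatch = 1.5, t_ef = 3, w_ef = 21.7e-6, juv_noise = 1)

test_that("trajectory reproduces the printed stage anchors", {
  traj <- build_trajectory(cfg, fixed = central)
  par <- attr(traj, "params")
  # egg weight during incubation
  expect_equal(traj$dry_weight[1], 42.8e-6)
  expect_identical(traj$stage[1], "incubation")
  # weight at first exogenous feeding equals the sampled w_ef
  w_ff <- demopriors:::weight_at(par, par$t_ff)
  expect_equal(w_ff, 21.7e-6, tolerance = 1e-9)
  # juvenile stage: fl(60) = 41.20 + 2.37*60 mm, wet weight ~ 90 g
  wet60 <- 1.92e-6 * (41.20 + 2.37 * 60)^3.39
  expect_equal(wet60, 90.41, tolerance = 1e-3)
  w60 <- demopriors:::weight_at(par, par$t_ff + 60)
  expect_equal(w60, (1 - 0.85) * wet60, tolerance = 1e-9)
  expect_equal(nrow(traj), 180L)
})

test_that("trajectory is continuous at every stage boundary", {
  set.seed(201)
  for (i in 1:20) {
    par <- attr(build_trajectory(cfg), "params")
    bounds <- c(par$t_hatch, par$t_ff, par$t_ff + par$stage_days$power_end,
                par$t_ff + par$stage_days$exp_end,
                par$t_ff + par$stage_days$juv_end)
    for (b in bounds) {
      lo <- demopriors:::weight_at(par, b - 1e-9)
      hi <- demopriors:::weight_at(par, b + 1e-9)
      expect_equal(hi / lo, 1, tolerance = 1e-6)
    }
  }
})

test_that("trajectory shape: flat egg, declining yolk sac, then growth", {
  set.seed(202)
  for (i in 1:10) {
    traj <- build_trajectory(cfg)
    w <- traj$dry_weight
    expect_true(all(w > 0))
    expect_true(all(w[traj$stage == "incubation"] == 42.8e-6))
    ys <- which(traj$stage == "yolk_sac")
    if (length(ys) > 1) expect_true(all(diff(w[ys]) <= 0))
    post <- which(traj$dpef > 0)
    expect_true(all(diff(w[post]) > 0))
  }
})

test_that("allometric mortality follows the two printed regimes", {
  # small regime at egg weight: a * w^b with a = 2.2e-4, b = -0.85
  mu_egg <- daily_mortality(42.8e-6, cfg, residual_error = FALSE)
  expect_equal(mu_egg, 1.1368, tolerance = 1e-4)
  expect_gt(mu_egg, 1)                 # rates above 1/day near fertilization
  # the two regressions agree at the regime threshold to within 0.1%
  eps <- 1e-12
  lo <- daily_mortality(0.00504 - eps, cfg, residual_error = FALSE)
  hi <- daily_mortality(0.00504 + eps, cfg, residual_error = FALSE)
  expect_equal(lo, 0.019740, tolerance = 1e-4)
  expect_lt(abs(hi / lo - 1), 0.001)
  # monotone nonincreasing in weight (both exponents negative)
  w <- 10^seq(-6, 1, length.out = 50)
  mu <- daily_mortality(w, cfg, residual_error = FALSE)
  expect_true(all(diff(mu) <= 0))
  expect_error(daily_mortality(0, cfg), "positive")
  expect_error(daily_mortality(-1, cfg), "positive")
})

test_that("mean daily mortality drops below 0.02 per day by day 30", {
  set.seed(203)
  mu30 <- replicate(200, {
    traj <- build_trajectory(cfg)
    daily_mortality(traj$dry_weight[30], cfg, residual_error = FALSE)
  })
  expect_lt(mean(mu30), 0.02)
})

test_that("M_0 composes exactly from its parts", {
  set.seed(204)
  d <- draw_M0(cfg)
  expect_equal(d$M_0, d$M_fh + sum(d$M_d))
  expect_equal(d$M_y, sum(d$M_d))
  expect_true(all(d$M_d >= 0))
  expect_gt(d$S_0, 0); expect_lt(d$S_0, 1)
  expect_equal(d$S_0, exp(-d$M_0))
  # central fertilization/hatching loss is -log(0.5)
  dc <- draw_M0(cfg, fixed = c(central, list(m_fh = log(2))))
  expect_equal(dc$M_fh, 0.6931, tolerance = 1e-4)
})

test_that("most of M_0 accrues within the first days", {
  set.seed(205)
  shares <- replicate(300, {
    d <- draw_M0(cfg)
    (d$M_fh + sum(d$M_d[1:8])) / d$M_0
  })
  expect_within(median(shares), 0.8, 0.1)
})

test_that("the McGurk residual drives most of the M_0 dispersion", {
  cfg_noerr <- modify_config(cfg, list(early_life = list(
    mcgurk = list(residual_error = FALSE))))
  set.seed(206)
  with_err <- draw_M0_ensemble(cfg, 400)
  no_err <- draw_M0_ensemble(cfg_noerr, 400)
  expect_gt(var(with_err) / var(no_err), 5)
})

test_that("an informative M_0 override bypasses the trajectory model", {
  sc <- modify_config(cfg, list(early_life = list(
    m0_override = dist_normal(12.5, 1.25, lower = 0))))
  set.seed(207)
  m0 <- draw_M0_ensemble(sc, 2000)
  expect_within(mean(m0), 12.5, mc_tol(m0, 12.5, 0.02))
  expect_within(sd(m0), 1.25, 0.1)
  expect_null(draw_M0(sc)$trajectory)
})
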