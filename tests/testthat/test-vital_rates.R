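cfg <- load_config("abft_baseline")

test_that("noise-free schedules reproduce the printed means", {
  m <- sample_mortality_at_age(cfg, noise = FALSE)
  expect_equal(m$S[1], exp(-0.49))
  expect_equal(m$S[1], 0.6126, tolerance = 1e-4)
  expect_equal(m$M[9:30], rep(0.1, 22))
  expect_equal(m$l[1], 1)
  expect_true(all(diff(m$l) <= 0))
  expect_equal(m$l[3], exp(-0.49) * exp(-0.24))

  lw <- length_weight_at_age(cfg, noise = FALSE)
  # age 4: about the 110-115 cm fork length of median maturity
  expect_equal(lw$L[4], 115.43, tolerance = 1e-3)
  expect_equal(lw$W[4], 31.49, tolerance = 1e-3)
  # age 20: batch fecundity around 2.4e7 oocytes (20+ million printed)
  batch20 <- 61.44 * lw$W[20] * 1000
  expect_equal(batch20, 2.41e7, tolerance = 0.01)
})

test_that("mortality noise is unbiased and truncated at zero", {
  set.seed(301)
  M <- replicate(2000, sample_mortality_at_age(cfg)$M[1])
  expect_true(all(M >= 0))
  expect_within(mean(M), 0.49, mc_tol(M, 0.49, 0.02))
  expect_within(sd(M), 0.049, 0.005)
})

test_that("fecundity is zero before maturity and composes per the chain", {
  set.seed(302)
  vr <- draw_vital_rates(cfg)
  expect_equal(vr$F[1:3], c(0, 0, 0))
  expect_true(all(vr$F >= 0))
  expect_equal(vr$f_A, vr$bf * 1000 * vr$W * vr$n_batch)
  expect_equal(vr$F, 0.5 * vr$g * vr$f_A * vr$rf)
  # annual spawning case: rf = 1 everywhere gives F = sr * g * f_A
  fec <- fecundity_at_age(cfg, vr$W, vr$bf, vr$n_batch, rf = 1)
  expect_equal(fec$F, 0.5 * vr$g * fec$f_A)
})

test_that("spawning-frequency modes behave as declared", {
  set.seed(303)
  per_age <- spawning_frequency_draw(cfg, 30)
  expect_true(all(per_age %in% (1 / (1:4))))
  expect_gt(length(unique(per_age)), 1)

  cfg_d <- modify_config(cfg, list(fecundity = list(spe_mode = "per_draw")))
  per_draw <- spawning_frequency_draw(cfg_d, 30)
  expect_length(unique(per_draw), 1)

  cfg_e <- modify_config(cfg, list(fecundity = list(spe_mode = "expected")))
  expect_equal(spawning_frequency_draw(cfg_e, 5), rep(25 / 48, 5))

  # a spawning_frequency spec replaces 1/Spe (reduced-fecundity scenario)
  cfg_rf <- modify_config(cfg, list(fecundity = list(
    spawning_frequency = dist_uniform(0.25, 0.33))))
  rf <- spawning_frequency_draw(cfg_rf, 100)
  expect_true(all(rf >= 0.25 & rf <= 0.33))
})

test_that("expected fecundity rises with age; output is order 1e7 with CV ~ 1", {
  vrd <- draw_vital_rates(modify_config(cfg, list(fecundity = list(
    spe_mode = "expected"))), noise = FALSE)
  # bf and n_batch still random; condition on maturity plateau ages
  expect_true(all(diff(vrd$F[5:30]) > 0))

  # a 20-year female under individual-level skip spawning: mean ~ 1e7
  # oocytes per year with coefficient of variation close to 1
  cfg_pd <- modify_config(cfg, list(fecundity = list(spe_mode = "per_draw")))
  set.seed(304)
  out20 <- replicate(2000, {
    vr <- draw_vital_rates(cfg_pd)
    vr$f_A[20] * vr$rf[20]
  })
  expect_gt(mean(out20), 1e7)
  expect_lt(mean(out20), 2e8)
  expect_within(sd(out20) / mean(out20), 1, 0.3)
})

test_that("western maturity override only rescales fecundity", {
  west <- apply_scenario(cfg, "western_maturity")
  expect_equal(west$fecundity$maturity,
               c(rep(0, 8), 0.5, rep(1, 21)))
  set.seed(305); vr_b <- draw_vital_rates(cfg)
  set.seed(305); vr_w <- draw_vital_rates(west)
  expect_equal(vr_w$M, vr_b$M)
  expect_equal(vr_w$W, vr_b$W)
  expect_equal(vr_w$f_A, vr_b$f_A)
  expect_equal(vr_w$F[10:30], vr_b$F[10:30])
  expect_equal(vr_w$F[4:8], rep(0, 5))
})
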