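cfg <- load_config("abft_baseline")

test_that("ensembles are bit-reproducible given the seed", {
  a <- run_ensemble(cfg, seed = 99, n_draws = 120, n_pops = 100)
  b <- run_ensemble(cfg, seed = 99, n_draws = 120, n_pops = 100)
  expect_identical(a$draws, b$draws)
  expect_identical(a$pops, b$pops)
  expect_identical(summarize_ensemble(a), summarize_ensemble(b))
  c_ <- run_ensemble(cfg, seed = 100, n_draws = 120, n_pops = 100)
  expect_false(identical(a$draws$r, c_$draws$r))
})

test_that("summary table has the documented layout and quantile method", {
  ens <- baseline_ensemble()
  s <- summarize_ensemble(ens)
  expect_identical(rownames(s), c("M_0", "W_bpr", "alpha", "r", "h"))
  expect_identical(colnames(s), c("q5", "q25", "q50", "q75", "q95",
                                  "mean", "sd"))
  # quantiles nondecreasing left to right in every row
  expect_true(all(apply(s[, 1:5], 1, function(x) all(diff(x) >= 0))))
  # degenerate and tiny known arrays
  e2 <- ens
  e2$draws <- data.frame(draw = 1:5, M0 = rep(7, 5), r = 1:5,
                         W_bpr = rep(7, 5), h = rep(0.5, 5),
                         total_F = rep(1, 5))
  s2 <- suppressWarnings(summarize_ensemble(e2))  # constant column: sd = 0
  expect_equal(unlist(s2["M_0", 1:6]), rep(7, 6), ignore_attr = TRUE)
  expect_equal(s2["M_0", "sd"], 0)
  expect_equal(s2["r", "q50"], 3)
  expect_equal(s2["r", "mean"], 3)
})

test_that("M_0 dominates r: strong negative rank correlation", {
  ens <- baseline_ensemble()
  sp <- cor(ens$draws$M0, ens$draws$r, method = "spearman")
  expect_lte(sp, -0.95)
})

test_that("acceptance-rejection truncates from below, joint = per-quantity", {
  ens <- baseline_ensemble()
  f <- accept_reject(ens)
  expect_true(all(f$draws$r >= 0))
  expect_true(all(f$pops$h >= 0.2))
  expect_gt(mean(f$draws$r), mean(ens$draws$r))
  expect_lt(sd(f$draws$r), sd(ens$draws$r))
  rej <- attr(f, "rejection")
  expect_gt(rej["draws"], 0.05); expect_lt(rej["draws"], 0.25)
  # r < 0 and h < 0.2 coincide through the Euler-Lotka relation (r >= 0
  # iff alpha*sr*W_bpr >= 1 iff h >= 0.2), so the two filter modes keep
  # exactly the same Leslie draws
  fq <- accept_reject(ens, mode = "per_quantity")
  expect_identical(ens$draws$r >= 0, ens$draws$h >= 0.2)
  expect_identical(fq$draws, f$draws)
  # no-op case when nothing violates the constraints
  clean <- ens
  clean$draws <- ens$draws[ens$draws$r >= 0 & ens$draws$h >= 0.2, ]
  clean$pops <- ens$pops[ens$pops$h >= 0.2, ]
  keep <- accept_reject(clean)
  expect_equal(keep$draws, clean$draws)
  # an all-rejected ensemble errors
  broken <- ens
  broken$draws$r <- -1; broken$draws$h <- 0; broken$pops$h <- 0
  expect_error(accept_reject(broken), "rejected every draw")
})

test_that("copula coupling hits the target rank correlation, marginals intact", {
  ens <- run_ensemble(cfg, seed = 7, n_draws = 1500, n_pops = 300)
  for (rho in c(0.7, 0.9)) {
    cor_ens <- demopriors:::repair_correlated(ens, rho)
    got <- cor(cor_ens$draws$M0, cor_ens$draws$total_F, method = "spearman")
    expect_within(got, rho, 0.02)
    # marginals are exact permutations of the independent ensemble
    expect_identical(sort(cor_ens$draws$M0), sort(ens$draws$M0))
    expect_identical(sort(cor_ens$draws$total_F), sort(ens$draws$total_F))
    expect_equal(sort(cor_ens$pops$alpha * exp(cor_ens$pops$M0)),
                 sort(ens$pops$alpha * exp(ens$pops$M0)))
    # M_0 still drives r
    expect_lte(cor(cor_ens$draws$M0, cor_ens$draws$r, method = "spearman"),
               -0.95)
  }
  # independence limit reproduces the uncoupled summary within tolerance
  ind <- demopriors:::repair_correlated(ens, 0)
  expect_within(mean(ind$draws$r), mean(ens$draws$r),
                mc_tol(ens$draws$r, mean(ens$draws$r), 0.05))
  expect_error(demopriors:::repair_correlated(ens, 1.2), "rho")
})

test_that("a scenario id routes through run_ensemble", {
  ens <- run_ensemble(cfg, scenario = "tef_fixed_2", seed = 5, n_draws = 150,
                      n_pops = 100)
  expect_identical(ens$scenario, "tef_fixed_2")
  expect_error(run_ensemble(cfg, scenario = "nope", seed = 1, n_draws = 10,
                            n_pops = 100), "unknown scenario")
})
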