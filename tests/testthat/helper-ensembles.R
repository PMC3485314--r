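# Shared fixtures: one moderate baseline ensemble reused across files
# (built lazily, once per test run) and a Monte-Carlo tolerance helper.

baseline_cfg <- function() load_config("abft_baseline")

.ens_cache <- new.env(parent = emptyenv())

# Baseline ensemble at reduced scale: 2500 Leslie draws, 600 populations.
baseline_ensemble <- function() {
  if (is.null(.ens_cache$base)) {
    .ens_cache$base <- run_ensemble(baseline_cfg(), seed = 42,
                                    n_draws = 2500, n_pops = 1500,
                                    pop_size = 1000)
  }
  .ens_cache$base
}

# +/- max(2 * MC standard error, rel * reference), the package-wide
# Monte-Carlo tolerance for ensemble statistics.
mc_tol <- function(x, ref, rel = 0.05) {
  max(2 * stats::sd(x) / sqrt(length(x)), rel * abs(ref))
}

expect_within <- function(value, ref, tol) {
  expect_lt(abs(value - ref), tol)
}
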