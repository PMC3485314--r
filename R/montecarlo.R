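#' Monte-Carlo ensembles of demographic quantities
#'
#' [run_ensemble()] orchestrates the two seeded ensembles: `n_draws_r`
#' draws of (`M_0`, vital rates, Leslie matrix, `r`) and `n_pops`
#' replicate populations for (`alpha`, `W_bpr`, `h`).  Each r-draw also
#' records its own per-recruit compound `h`, which makes the
#' acceptance-rejection filters and Table-style summaries available on
#' both sub-ensembles.
#'
#' @name montecarlo
NULL

#' Run the seeded baseline (or scenario) ensemble
#'
#' @param cfg configuration (default the shipped baseline).
#' @param scenario optional scenario id or [builtin_scenarios()] object
#'   applied to `cfg` first; correlated-sampling scenarios re-pair the
#'   ensemble at their rank correlation after the independent run.
#' @param seed integer seed; the ensemble is bit-reproducible given the
#'   seed.
#' @param n_draws,n_pops,pop_size override the configured Monte-Carlo
#'   sizes.
#' @return an `ensemble_result` with data frames `draws` (`M0`, `r`,
#'   `W_bpr`, `h`, `total_F` per Leslie draw) and `pops` (`M0`, `alpha`,
#'   `W_bpr`, `h` per replicate population), plus the fecundity/survival
#'   draw matrices used for correlated re-pairing.
#' @examples
#' \donttest{
#' ens <- run_ensemble(seed = 1, n_draws = 200, n_pops = 100)
#' summary(ens)
#' }
#' @export
run_ensemble <- function(cfg = load_config("abft_baseline"), scenario = NULL,
                         seed = NULL, n_draws = NULL, n_pops = NULL,
                         pop_size = NULL) {
  rho <- NULL
  scenario_id <- "baseline"
  if (!is.null(scenario)) {
    sc <- resolve_scenario(scenario)
    cfg <- apply_scenario(cfg, sc)
    rho <- sc$rho
    scenario_id <- sc$id
  }
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n_draws <- n_draws %||% cfg$mc$n_draws_r
  n_pops <- n_pops %||% cfg$mc$n_pops
  pop_size <- pop_size %||% cfg$mc$pop_size
  A <- cfg$terminal_age
  sr <- cfg$fecundity$sex_ratio

  m0_draw <- m0_sampler(cfg)
  draws <- data.frame(draw = seq_len(n_draws), M0 = NA_real_, r = NA_real_,
                      W_bpr = NA_real_, h = NA_real_, total_F = NA_real_)
  Fmat <- matrix(NA_real_, n_draws, A)
  Smat <- matrix(NA_real_, n_draws, A)
  for (i in seq_len(n_draws)) {
    res <- tryCatch({
      m0 <- m0_draw()
      vr <- draw_vital_rates(cfg)
      r <- growth_rate(build_leslie(vr$F, vr$S[-A], m0))
      wbpr <- spawning_biomass_per_recruit(vr)
      abar <- exp(-m0) * sum(vr$F * vr$l)
      list(m0 = m0, r = r, wbpr = wbpr, h = abar / (4 + abar),
           F = vr$F, S = vr$S)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop("Leslie draw ", i, " (seed ", seed %||% "unset", ") failed: ",
           conditionMessage(res), call. = FALSE)
    }
    draws$M0[i] <- res$m0; draws$r[i] <- res$r
    draws$W_bpr[i] <- res$wbpr; draws$h[i] <- res$h
    draws$total_F[i] <- sum(res$F)
    Fmat[i, ] <- res$F; Smat[i, ] <- res$S
  }

  pops <- data.frame(pop = seq_len(n_pops), M0 = NA_real_, alpha = NA_real_,
                     W_bpr = NA_real_, h = NA_real_, total_F = NA_real_)
  for (k in seq_len(n_pops)) {
    res <- tryCatch({
      m0 <- m0_draw()
      vr <- draw_vital_rates(cfg)
      pop <- simulate_population(vr, cfg, pop_size)
      alpha <- alpha_recruits(pop, m0)
      wbpr <- spawning_biomass_per_recruit(vr)
      list(m0 = m0, alpha = alpha, wbpr = wbpr,
           h = bh_steepness(alpha, sr, wbpr), total_F = sum(vr$F))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      stop("population replicate ", k, " (seed ", seed %||% "unset",
           ") failed: ", conditionMessage(res), call. = FALSE)
    }
    pops$M0[k] <- res$m0; pops$alpha[k] <- res$alpha
    pops$W_bpr[k] <- res$wbpr; pops$h[k] <- res$h
    pops$total_F[k] <- res$total_F
  }

  ens <- structure(
    list(draws = draws, pops = pops, Fmat = Fmat, Smat = Smat,
         cfg = cfg, scenario = scenario_id, seed = seed,
         n_draws = n_draws, n_pops = n_pops, pop_size = pop_size,
         rho = NULL, filtered = FALSE),
    class = "ensemble_result"
  )
  if (!is.null(rho)) ens <- repair_correlated(ens, rho) else ens
}

#' Correlated (copula) re-sampling of M_0 and fecundity
#'
#' Re-pairs the empirical `M_0` marginal with the empirical
#' total-fecundity marginal through a Gaussian-copula rank coupling at
#' Spearman rank correlation `rho`, then recomputes `r` and `h` for the
#' new pairs.  Both marginals are preserved exactly (the coupling is a
#' permutation of the independent draws).
#'
#' @param cfg configuration.
#' @param rho target Spearman rank correlation in `[-1, 1]`.
#' @param seed integer seed.
#' @param ... passed to [run_ensemble()] (`n_draws`, `n_pops`, ...).
#' @return an `ensemble_result` with re-paired draws.
#' @export
correlated_draws <- function(cfg = load_config("abft_baseline"), rho,
                             seed = NULL, ...) {
  ens <- run_ensemble(cfg, seed = seed, ...)
  repair_correlated(ens, rho)
}

# Gaussian-copula rank coupling: returns for each slot i the ranks to use
# from two independently sorted marginals.
copula_ranks <- function(n, rho) {
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  rho_g <- 2 * sin(pi * rho / 6)     # Spearman -> Gaussian (Pearson) rho
  z1 <- stats::rnorm(n)
  z2 <- rho_g * z1 + sqrt(1 - rho_g^2) * stats::rnorm(n)
  list(r1 = rank(z1, ties.method = "first"),
       r2 = rank(z2, ties.method = "first"))
}

repair_correlated <- function(ens, rho) {
  cfg <- ens$cfg
  A <- cfg$terminal_age
  # Leslie draws: couple M_0 with the total-fecundity rank of the
  # vital-rate draw, then recompute r/W_bpr/h for the new pairs.
  n <- ens$n_draws
  rk <- copula_ranks(n, rho)
  m0_new <- sort(ens$draws$M0)[rk$r1]
  vr_idx <- order(ens$draws$total_F)[rk$r2]
  draws <- data.frame(draw = seq_len(n), M0 = m0_new, r = NA_real_,
                      W_bpr = NA_real_, h = NA_real_,
                      total_F = ens$draws$total_F[vr_idx])
  Fmat <- ens$Fmat[vr_idx, , drop = FALSE]
  Smat <- ens$Smat[vr_idx, , drop = FALSE]
  lmat <- cbind(1, t(apply(Smat[, -A, drop = FALSE], 1, cumprod)))
  for (i in seq_len(n)) {
    draws$r[i] <- growth_rate(build_leslie(Fmat[i, ], Smat[i, -A], m0_new[i]))
    wbpr_terms <- lmat[i, ]   # survivorship of the re-paired vital rates
    abar <- exp(-m0_new[i]) * sum(Fmat[i, ] * wbpr_terms)
    draws$h[i] <- abar / (4 + abar)
  }
  draws$W_bpr <- ens$draws$W_bpr[vr_idx]
  # population replicates: alpha scales by exp(-(M0_new - M0_old))
  k <- ens$n_pops
  rkp <- copula_ranks(k, rho)
  m0p <- sort(ens$pops$M0)[rkp$r1]
  pidx <- order(ens$pops$total_F)[rkp$r2]
  pops <- ens$pops[pidx, ]
  pops$alpha <- pops$alpha * exp(-(m0p - pops$M0))
  pops$M0 <- m0p
  pops$h <- bh_steepness(pops$alpha, cfg$fecundity$sex_ratio, pops$W_bpr)
  pops$pop <- seq_len(k)
  rownames(pops) <- NULL
  ens$draws <- draws; ens$pops <- pops
  ens$Fmat <- Fmat; ens$Smat <- Smat
  ens$rho <- rho
  ens
}

#' Acceptance-rejection correction of the priors
#'
#' Discards draws inconsistent with the assessment models for which the
#' priors are intended: `r < 0` (declining population in the surplus
#' production model) and `h < 0.2` (below the Beverton-Holt lower
#' bound).  In this model the two constraints coincide draw-by-draw
#' (`r < 0` iff `alpha * sr * W_bpr < 1` iff `h < 0.2`, by the
#' Euler-Lotka relation at `lambda = 1`), so the `"joint"` mode (default)
#' and the `"per_quantity"` mode (r-filter on the Leslie ensemble,
#' h-filter on the population ensemble) differ only through
#' finite-population noise.
#'
#' @param ens an `ensemble_result`.
#' @param mode `"joint"` or `"per_quantity"`.
#' @return the filtered `ensemble_result`; attribute `"rejection"` holds
#'   the rejected fractions.
#' @export
accept_reject <- function(ens, mode = c("joint", "per_quantity")) {
  mode <- match.arg(mode)
  keep_d <- if (mode == "joint") {
    ens$draws$r >= 0 & ens$draws$h >= 0.2
  } else {
    ens$draws$r >= 0
  }
  keep_p <- ens$pops$h >= 0.2
  if (!any(keep_d) || !any(keep_p)) {
    stop("acceptance-rejection rejected every draw")
  }
  rejection <- c(draws = mean(!keep_d), pops = mean(!keep_p))
  ens$draws <- ens$draws[keep_d, ]
  ens$Fmat <- ens$Fmat[keep_d, , drop = FALSE]
  ens$Smat <- ens$Smat[keep_d, , drop = FALSE]
  ens$pops <- ens$pops[keep_p, ]
  ens$filtered <- TRUE
  attr(ens, "rejection") <- rejection
  ens
}

#' Summary table of an ensemble
#'
#' Quantiles (5/25/50/75/95%, linear interpolation between order
#' statistics), mean and standard deviation of each demographic
#' quantity, one row per quantity in the order `M_0`, `W_bpr`, `alpha`,
#' `r`, `h`.  `M_0` and `r` are taken from the Leslie-draw ensemble;
#' `W_bpr`, `alpha` and `h` from the population ensemble.  Spearman rank
#' correlations among the quantities are attached as attribute
#' `"spearman"`.
#'
#' @param ens an `ensemble_result`.
#' @return a `data.frame` with columns `q5, q25, q50, q75, q95, mean, sd`.
#' @export
summarize_ensemble <- function(ens) {
  qty <- list(M_0 = ens$draws$M0, W_bpr = ens$pops$W_bpr,
              alpha = ens$pops$alpha, r = ens$draws$r, h = ens$pops$h)
  if (any(!vapply(qty, length, 1L))) stop("empty ensemble")
  probs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  tab <- t(vapply(qty, function(x) {
    c(stats::quantile(x, probs, type = 7, names = FALSE), mean(x),
      stats::sd(x))
  }, numeric(7)))
  colnames(tab) <- c("q5", "q25", "q50", "q75", "q95", "mean", "sd")
  out <- as.data.frame(tab)
  sp <- list(
    draws = stats::cor(ens$draws[, c("M0", "r", "h")], method = "spearman"),
    pops = stats::cor(ens$pops[, c("M0", "alpha", "h")], method = "spearman")
  )
  attr(out, "spearman") <- sp
  attr(out, "quantile_method") <- "type 7 (linear interpolation)"
  class(out) <- c("ensemble_summary", "data.frame")
  out
}

#' @export
summary.ensemble_result <- function(object, ...) summarize_ensemble(object)

#' @export
print.ensemble_result <- function(x, ...) {
  cat(sprintf("<ensemble_result> scenario '%s'%s: %d Leslie draws, %d populations%s\n",
              x$scenario, if (!is.null(x$rho)) sprintf(" (rho = %.2f)", x$rho)
              else "", nrow(x$draws), nrow(x$pops),
              if (x$filtered) " [accept-reject filtered]" else ""))
  print(summarize_ensemble(x))
  invisible(x)
}

#' @export
print.ensemble_summary <- function(x, digits = 3, ...) {
  print.data.frame(round(as.data.frame(x), digits), ...)
  sp <- attr(x, "spearman")
  if (!is.null(sp)) {
    cat(sprintf("Spearman(M_0, r) = %.3f | Spearman(M_0, h) = %.3f\n",
                sp$draws["M0", "r"], sp$pops["M0", "h"]))
  }
  invisible(x)
}
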