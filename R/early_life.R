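#' Early-life growth and mortality (age 0)
#'
#' The first year of life is modeled on a daily grid over
#' `horizon_days` (180) days post-fertilization.  Dry weight follows five
#' stages: (i) constant egg weight during incubation; (ii) linear weight
#' loss from egg weight to the weight at first exogenous feeding during
#' the yolk-sac stage; (iii) power growth (exponent `k1`) over the first
#' 20 days post exogenous feeding (dpef); (iv) exponential growth from 20
#' to 60 dpef with the rate solved for continuity with the juvenile
#' curve; (v) the juvenile fork-length/weight curve from 60 to 150 dpef;
#' after 150 dpef, linear interpolation to the end-of-year-0 weight
#' implied by the von Bertalanffy growth curve.  Daily mortality is the
#' McGurk allometric rate evaluated at the daily dry weight, with
#' multiplicative lognormal residual noise drawn independently each day.
#'
#' @name early_life
NULL

# Realized stage parameters for one cohort trajectory.  `fixed` pins any
# of t_hatch, t_ef, w_ef, juv_noise for deterministic evaluation.
trajectory_params <- function(cfg, fixed = list()) {
  el <- cfg$early_life
  pick <- function(name, spec) {
    if (!is.null(fixed[[name]])) fixed[[name]] else sample_dist(spec)
  }
  t_hatch <- pick("t_hatch", el$t_hatch)
  t_ef <- pick("t_ef", el$t_ef)
  w_ef <- pick("w_ef", el$w_ef)
  juv_noise <- if (!is.null(fixed$juv_noise)) {
    fixed$juv_noise
  } else {
    z <- stats::rnorm(1, 1, el$juvenile$cv)
    while (z <= 0) z <- stats::rnorm(1, 1, el$juvenile$cv)
    z
  }
  jv <- el$juvenile
  dry <- 1 - el$hydration_factor
  fl <- function(d) jv$fl_intercept + jv$fl_slope * d          # mm at d dpef
  juv_dry <- function(d) dry * jv$lw_factor * fl(d)^jv$lw_exponent * juv_noise
  sd_ <- el$stage_days
  t_ff <- t_hatch + t_ef                # first exogenous feeding (days pf)
  w_power_end <- w_ef * (sd_$power_end + 1)^el$k1
  w_exp_end <- juv_dry(sd_$exp_end)
  if (!is.finite(w_power_end) || !is.finite(w_exp_end) ||
      w_exp_end <= w_power_end) {
    stop("exponential-growth stage: no positive growth-rate solution ",
         "(weight at ", sd_$exp_end, " dpef does not exceed the power-stage ",
         "endpoint)")
  }
  k2 <- log(w_exp_end / w_power_end) / (sd_$exp_end - sd_$power_end)
  # end-of-year-0 dry weight from the adult growth curves
  vb <- cfg$growth$vb
  lw <- cfg$growth$length_weight
  L1 <- vb$linf * (1 - exp(-vb$k * (1 - vb$t0)))
  w_year_end <- dry * 1000 * lw$b * L1^lw$c                      # kg -> dry g
  list(t_hatch = t_hatch, t_ef = t_ef, t_ff = t_ff, w_egg = el$w_egg,
       w_ef = w_ef, k1 = el$k1, k2 = k2, juv_noise = juv_noise,
       juv_dry = juv_dry, stage_days = sd_, horizon = el$horizon_days,
       w_power_end = w_power_end, w_year_end = w_year_end)
}

# Piecewise dry weight (g) at continuous age x (days post-fertilization).
weight_at <- function(par, x) {
  sd_ <- par$stage_days
  d <- x - par$t_ff                     # days post exogenous feeding
  t150 <- par$t_ff + sd_$juv_end
  w <- numeric(length(x))
  i1 <- x <= par$t_hatch
  w[i1] <- par$w_egg
  i2 <- x > par$t_hatch & d <= 0
  w[i2] <- par$w_egg + (par$w_ef - par$w_egg) * (x[i2] - par$t_hatch) / par$t_ef
  i3 <- d > 0 & d <= sd_$power_end
  w[i3] <- par$w_ef * (d[i3] + 1)^par$k1
  i4 <- d > sd_$power_end & d <= sd_$exp_end
  w[i4] <- par$w_power_end * exp(par$k2 * (d[i4] - sd_$power_end))
  i5 <- d > sd_$exp_end & d <= sd_$juv_end
  w[i5] <- par$juv_dry(d[i5])
  i6 <- d > sd_$juv_end
  w150 <- par$juv_dry(sd_$juv_end)
  w[i6] <- w150 + (par$w_year_end - w150) * (x[i6] - t150) /
    (par$horizon - t150)
  bad <- which(!is.finite(w) | w <= 0)
  if (length(bad)) {
    stop("non-finite or nonpositive dry weight at day ", x[bad[1]],
         " (stage '", stage_label(par, x[bad[1]]), "')")
  }
  w
}

stage_label <- function(par, x) {
  d <- x - par$t_ff
  sd_ <- par$stage_days
  ifelse(x <= par$t_hatch, "incubation",
  ifelse(d <= 0, "yolk_sac",
  ifelse(d <= sd_$power_end, "power_growth",
  ifelse(d <= sd_$exp_end, "exponential_growth",
  ifelse(d <= sd_$juv_end, "juvenile", "interpolation")))))
}

#' Build one daily dry-weight trajectory
#'
#' Draws the stochastic stage parameters (`t_hatch`, `t_ef`, `w_ef`, the
#' juvenile growth noise) and evaluates the piecewise growth model on
#' days 1..180 post-fertilization.  The trajectory is continuous at every
#' stage boundary by construction.
#'
#' @param cfg a [load_config()] configuration.
#' @param fixed optional named list pinning `t_hatch`, `t_ef`, `w_ef`
#'   and/or `juv_noise` to given values (useful for deterministic checks).
#' @return a `growth_trajectory`: a data frame with columns `day`, `dpef`,
#'   `stage`, `dry_weight` (g), carrying the realized stage parameters as
#'   attribute `"params"`.
#' @examples
#' cfg <- load_config("abft_baseline")
#' set.seed(1)
#' traj <- build_trajectory(cfg)
#' head(traj, 3)
#' @export
build_trajectory <- function(cfg, fixed = list()) {
  par <- trajectory_params(cfg, fixed)
  day <- seq_len(par$horizon)
  out <- data.frame(
    day = day,
    dpef = day - par$t_ff,
    stage = stage_label(par, day),
    dry_weight = weight_at(par, day)
  )
  structure(out, params = par, class = c("growth_trajectory", "data.frame"))
}

#' Allometric daily mortality rate
#'
#' Mean rate from the McGurk dry-weight regressions,
#' `mu = a * w^b` below the regime threshold (0.00504 g dry) and
#' `mu = a' * w^b'` above it; the realized rate multiplies the mean by a
#' lognormal residual `exp(Z)`, `Z ~ N(0, sigma)` with the
#' regime-appropriate sigma, drawn independently for each element.
#'
#' @param w dry weight(s), g; must be positive.
#' @param cfg configuration (McGurk block).
#' @param residual_error draw the lognormal residual? Defaults to the
#'   configuration switch; `FALSE` returns the mean rate.
#' @return rate(s), per day.
#' @export
daily_mortality <- function(w, cfg,
                            residual_error = cfg$early_life$mcgurk$residual_error) {
  if (any(!is.finite(w) | w <= 0)) stop("dry weight must be positive")
  mg <- cfg$early_life$mcgurk
  small <- w < mg$weight_threshold
  mu <- ifelse(small, mg$small$a * w^mg$small$b, mg$large$a * w^mg$large$b)
  if (!residual_error) return(mu)
  sigma <- ifelse(small, mg$small$sigma, mg$large$sigma)
  mu * exp(stats::rnorm(length(w), 0, sigma))
}

# Fertilization + hatching mortality on the instantaneous scale.
sample_m_fh <- function(cfg) {
  el <- cfg$early_life
  if (el$fert_hatch_mode == "survival") {
    -log(sample_dist(el$fh_survival))
  } else {
    sample_dist(el$m_fh)
  }
}

#' Draw one cumulative young-of-the-year mortality
#'
#' Combines the fertilization/hatching loss `M_fh` with the sum of
#' realized daily mortality rates over days 1..180 post-fertilization
#' evaluated on one stochastic growth trajectory:
#' `M_0 = M_fh + sum(M_d(x))`.  When the configuration carries an
#' informative `m0_override` distribution, `M_0` is drawn from it
#' directly (negative draws truncated at 0 by the override spec).
#'
#' @param cfg configuration.
#' @param fixed passed to [build_trajectory()]; may additionally pin
#'   `m_fh`.
#' @return an `early_life_draw`: list with `trajectory`, `M_fh`, `M_d`
#'   (daily rates), `M_y` (their sum), `M_0` and `S_0 = exp(-M_0)`.
#' @export
draw_M0 <- function(cfg, fixed = list()) {
  el <- cfg$early_life
  if (!is.null(el$m0_override)) {
    m0 <- sample_dist(el$m0_override)
    return(structure(list(trajectory = NULL, M_fh = NA_real_, M_d = NULL,
                          M_y = NA_real_, M_0 = m0, S_0 = exp(-m0)),
                     class = "early_life_draw"))
  }
  traj <- build_trajectory(cfg, fixed)
  m_fh <- if (!is.null(fixed$m_fh)) fixed$m_fh else sample_m_fh(cfg)
  m_d <- daily_mortality(traj$dry_weight, cfg)
  m0 <- m_fh + sum(m_d)
  structure(list(trajectory = traj, M_fh = m_fh, M_d = m_d,
                 M_y = sum(m_d), M_0 = m0, S_0 = exp(-m0)),
            class = "early_life_draw")
}

#' @export
print.early_life_draw <- function(x, ...) {
  cat(sprintf("<early_life_draw> M_0 = %.3f (M_fh = %.3f, M_y = %.3f), S_0 = %.3g\n",
              x$M_0, x$M_fh, x$M_y, x$S_0))
  invisible(x)
}

# Lean sampler for ensembles: returns only M_0.  Mirrors draw_M0() but
# avoids building the labeled data frame (hot loop).
m0_sampler <- function(cfg) {
  el <- cfg$early_life
  if (!is.null(el$m0_override)) {
    spec <- el$m0_override
    return(function() sample_dist(spec))
  }
  mg <- el$mcgurk
  function() {
    par <- trajectory_params(cfg)
    w <- weight_at(par, seq_len(par$horizon))
    small <- w < mg$weight_threshold
    mu <- ifelse(small, mg$small$a * w^mg$small$b, mg$large$a * w^mg$large$b)
    if (mg$residual_error) {
      sigma <- ifelse(small, mg$small$sigma, mg$large$sigma)
      mu <- mu * exp(stats::rnorm(length(w), 0, sigma))
    }
    sample_m_fh(cfg) + sum(mu)
  }
}

#' Ensemble of young-of-the-year mortalities
#'
#' @param cfg configuration.
#' @param n number of independent draws.
#' @return numeric vector of `M_0` values (per 180 days, reported on the
#'   annual scale as in the summary tables).
#' @export
draw_M0_ensemble <- function(cfg, n) {
  f <- m0_sampler(cfg)
  vapply(seq_len(n), function(i) f(), numeric(1))
}
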