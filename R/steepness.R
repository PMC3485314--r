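#' Steepness of the Beverton-Holt stock-recruitment relationship
#'
#' Steepness `h` is the fraction of unfished recruitment obtained when
#' spawning biomass is reduced to 20% of its unfished level.  It is
#' computed from the maximum recruits per unit spawning biomass `alpha`
#' (slope of the stock-recruit curve at the origin, estimated on a
#' simulated unfished age-structured population), the sex ratio `sr`, and
#' the unfished spawning biomass per recruit `W_bpr`:
#' `h = a / (4 + a)` with `a = alpha * sr * W_bpr`.  `h = 0.2` at
#' replacement (`a = 1`) and `h -> 1` as `alpha -> Inf`.
#'
#' @name steepness
NULL

#' Simulate an unfished age-structured population
#'
#' Ages are drawn with probability proportional to survivorship `l(a)`
#' (stationary unfished age structure); each individual receives a
#' length/weight draw at its age and a maturity probability from the
#' ogive.  `B_sim` is the expected-maturity female spawning biomass
#' `sum(g(x_n) * W(x_n))`; `F_sim` the total annual oocyte production
#' `sum(g(x_n) * bf * 1000 W(x_n) * N_batch * rf_n)` with batch
#' fecundity and batch number shared by the cohort and the spawning
#' frequency `rf_n` drawn per individual (per the configured mode).
#'
#' @param vr a [draw_vital_rates()] draw (supplies `l`).
#' @param cfg configuration.
#' @param N number of individuals (>= 100).
#' @return a `population_sample`: list with `ages`, `W` (kg), `g`,
#'   `F_sim` (oocytes), `B_sim` (kg).
#' @export
simulate_population <- function(vr, cfg, N = cfg$mc$pop_size) {
  if (N < 100) stop("population size N must be at least 100")
  A <- cfg$terminal_age
  if (all(cfg$fecundity$maturity == 0)) {
    stop("no mature age class in 1..A: spawning biomass undefined")
  }
  ages <- sample.int(A, N, replace = TRUE, prob = vr$l)
  lw <- length_weight_at_age(cfg, ages)
  g <- cfg$fecundity$maturity[ages]
  rf <- spawning_frequency_draw(cfg, N)
  B_sim <- sum(g * lw$W)
  F_sim <- sum(g * vr$bf * (1000 * lw$W) * vr$n_batch * rf)
  structure(list(ages = ages, W = lw$W, g = g, F_sim = F_sim, B_sim = B_sim),
            class = "population_sample")
}

#' Recruits per unit spawning biomass
#'
#' `alpha = exp(-M_0) * F_sim / B_sim`: eggs produced per kg of spawning
#' biomass, discounted by survival through the age-0 year.
#'
#' @param pop a [simulate_population()] sample.
#' @param M_0 cumulative age-0 mortality.
#' @return recruits per kg.
#' @export
alpha_recruits <- function(pop, M_0) {
  if (pop$B_sim <= 0) stop("B_sim is 0: simulated population has no mature biomass")
  exp(-M_0) * pop$F_sim / pop$B_sim
}

#' Unfished spawning biomass per recruit
#'
#' `W_bpr = sum_{a=1}^{A} l(a) * W_f(a) * g(a)` (kg of mature female
#' biomass a recruit is expected to produce over its life under natural
#' mortality only).
#'
#' @param vr a [draw_vital_rates()] draw.
#' @return kg per recruit.
#' @export
spawning_biomass_per_recruit <- function(vr) {
  sum(vr$l * vr$W * vr$g)
}

#' Beverton-Holt steepness
#'
#' @param alpha recruits per kg spawning biomass (>= 0).
#' @param sr sex ratio.
#' @param W_bpr spawning biomass per recruit, kg (>= 0).
#' @return steepness in `(0, 1)`; exactly 0.2 when
#'   `alpha * sr * W_bpr == 1`.
#' @export
bh_steepness <- function(alpha, sr, W_bpr) {
  if (any(alpha < 0) || any(W_bpr < 0)) stop("alpha and W_bpr must be >= 0")
  a <- alpha * sr * W_bpr
  ifelse(is.infinite(a), 1, a / (4 + a))
}

#' One steepness draw
#'
#' Draws `M_0` and a full set of vital rates, simulates one replicate
#' population and composes `alpha`, `W_bpr` and `h`.
#'
#' @param cfg configuration.
#' @param N population size.
#' @return list with `M_0`, `alpha`, `W_bpr`, `h`.
#' @export
draw_steepness <- function(cfg, N = cfg$mc$pop_size) {
  m0 <- draw_M0(cfg)$M_0
  vr <- draw_vital_rates(cfg)
  pop <- simulate_population(vr, cfg, N)
  alpha <- alpha_recruits(pop, m0)
  wbpr <- spawning_biomass_per_recruit(vr)
  list(M_0 = m0, alpha = alpha, W_bpr = wbpr,
       h = bh_steepness(alpha, cfg$fecundity$sex_ratio, wbpr))
}
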