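#' Post-recruitment vital rates
#'
#' One Monte-Carlo draw of the post-recruit demography: instantaneous
#' natural mortality at age with Gaussian noise (CV 10%, truncated at 0),
#' survivorship from recruitment, von Bertalanffy lengths with Gaussian
#' individual noise, the length-weight conversion, and absolute annual
#' fecundity at age built from relative batch fecundity, batch number and
#' spawning periodicity.
#'
#' @name vital_rates
NULL

#' Sample mortality-at-age, survival and survivorship
#'
#' `M(i) ~ N(mu_M(i), cv * mu_M(i))` truncated at 0; `S(i) = exp(-M(i))`;
#' survivorship `l(1) = 1`, `l(a) = prod_{j<a} S(j)`.
#'
#' @param cfg configuration.
#' @param noise `FALSE` returns the mean rates exactly.
#' @return list with vectors `M`, `S`, `l` (length `A`).
#' @export
sample_mortality_at_age <- function(cfg, noise = TRUE) {
  mu <- cfg$post_recruit$mean
  M <- if (noise && cfg$post_recruit$cv > 0) {
    pmax(stats::rnorm(length(mu), mu, cfg$post_recruit$cv * mu), 0)
  } else {
    mu
  }
  S <- exp(-M)
  l <- c(1, cumprod(S[-length(S)]))
  list(M = M, S = S, l = l)
}

#' Length and weight at age
#'
#' Mean fork length from the von Bertalanffy curve
#' `L(i) = L_inf * (1 - exp(-k * (i - t0)))`, with Gaussian noise of CV
#' `length_cv` truncated at 0; weight `W = b * L^c` in kg (length in cm).
#'
#' @param cfg configuration.
#' @param ages integer vector of ages in `1..A`.
#' @param noise `FALSE` returns the curve means.
#' @return list with `L` (cm) and `W` (kg).
#' @export
length_weight_at_age <- function(cfg, ages = seq_len(cfg$terminal_age),
                                 noise = TRUE) {
  if (any(ages < 1 | ages > cfg$terminal_age)) {
    stop("ages must lie in 1..terminal_age")
  }
  vb <- cfg$growth$vb
  Lbar <- vb$linf * (1 - exp(-vb$k * (ages - vb$t0)))
  L <- if (noise && cfg$growth$length_cv > 0) {
    x <- stats::rnorm(length(ages), Lbar, cfg$growth$length_cv * Lbar)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), Lbar[bad],
                             cfg$growth$length_cv * Lbar[bad])
      bad <- bad[x[bad] <= 0]
    }
    x
  } else {
    Lbar
  }
  lw <- cfg$growth$length_weight
  list(L = L, W = lw$b * L^lw$c)
}

#' Draw annual spawning frequencies
#'
#' The spawning periodicity `Spe` (years between reproductive events) is
#' converted to an annual spawning frequency `1/Spe`.  Three modes:
#' `"per_age"` draws an independent `Spe` for every age class (skip
#' spawning as an individual-level process, so age classes average over
#' independent skipping states); `"per_draw"` shares a single `Spe`
#' across all ages of the draw (fully synchronized skipping);
#' `"expected"` uses the deterministic mean frequency `E[1/Spe]`.  When
#' the configuration sets a `spawning_frequency` distribution (e.g. the
#' reduced-fecundity scenario), it replaces `1/Spe` under the same modes.
#'
#' @param cfg configuration.
#' @param n number of frequencies (ages or individuals).
#' @return numeric vector of length `n` of annual spawning frequencies.
#' @export
spawning_frequency_draw <- function(cfg, n) {
  fec <- cfg$fecundity
  rf_spec <- fec$spawning_frequency
  one <- if (is.null(rf_spec)) {
    function(m) 1 / sample_dist(fec$spe, m)
  } else {
    function(m) sample_dist(rf_spec, m)
  }
  switch(fec$spe_mode,
    per_age = one(n),
    per_draw = rep(one(1L), n),
    expected = {
      rep(if (is.null(rf_spec)) {
        p <- fec$spe$params
        if (fec$spe$family == "discrete_uniform") {
          sum(p$prob / p$values)
        } else {
          1 / dist_mean(fec$spe)
        }
      } else {
        dist_mean(rf_spec)
      }, n)
    }
  )
}

#' Absolute fecundity at age
#'
#' Annual fecundity `f_A(i) = bf * (1000 * W_f(i)) * N_batch` (oocytes;
#' weight converted kg to g) and the Leslie fecundity
#' `F(i) = sr * g(i) * f_A(i) * rf(i)`, the expected number of age-0
#' females produced per female of age `i` per year, with `rf` the annual
#' spawning frequency (`1/Spe`).  All oocytes are counted as eggs
#' (hydrated-oocyte assumption).
#'
#' @param cfg configuration.
#' @param W weights at age, kg (length `A`).
#' @param bf relative batch fecundity, oocytes per gram.
#' @param n_batch number of batches per spawning season.
#' @param rf annual spawning frequency per age (recycled if scalar).
#' @return list with `f_A` and `F` (length `A`).
#' @export
fecundity_at_age <- function(cfg, W, bf, n_batch, rf) {
  g <- cfg$fecundity$maturity
  if (length(W) != length(g)) stop("weight vector must have length A")
  f_A <- bf * (1000 * W) * n_batch
  F_ <- cfg$fecundity$sex_ratio * g * f_A * rep_len(rf, length(W))
  list(f_A = f_A, F = F_)
}

#' One full draw of the post-recruit vital rates
#'
#' @param cfg configuration.
#' @param noise disable all Gaussian noise terms for deterministic
#'   evaluation of the mean schedules.
#' @return a `vital_rates_draw`: list with `M`, `S`, `l`, `L`, `W`
#'   (per-age vectors), maturity `g`, `bf`, `n_batch`, `rf` (annual
#'   spawning frequency per age), annual fecundity `f_A` and Leslie
#'   fecundity `F`.
#' @examples
#' cfg <- load_config("abft_baseline")
#' set.seed(1)
#' vr <- draw_vital_rates(cfg)
#' round(vr$F[1:6])
#' @export
draw_vital_rates <- function(cfg, noise = TRUE) {
  A <- cfg$terminal_age
  mort <- sample_mortality_at_age(cfg, noise = noise)
  lw <- length_weight_at_age(cfg, noise = noise)
  bf <- sample_dist(cfg$fecundity$bf)
  n_batch <- sample_dist(cfg$fecundity$n_batch)
  rf <- spawning_frequency_draw(cfg, A)
  fec <- fecundity_at_age(cfg, lw$W, bf, n_batch, rf)
  structure(
    c(mort, lw,
      list(g = cfg$fecundity$maturity, bf = bf, n_batch = n_batch, rf = rf,
           f_A = fec$f_A, F = fec$F)),
    class = "vital_rates_draw"
  )
}

#' @export
print.vital_rates_draw <- function(x, ...) {
  A <- length(x$M)
  cat(sprintf("<vital_rates_draw> A = %d | bf = %.1f oocytes/g, N_batch = %.1f\n",
              A, x$bf, x$n_batch))
  cat(sprintf("  survivorship l(A) = %.4f | W(A) = %.0f kg | F range [%.3g, %.3g]\n",
              x$l[A], x$W[A], min(x$F), max(x$F)))
  invisible(x)
}
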