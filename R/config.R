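#' Life-history configuration
#'
#' A `lh_config` object holds every parameter of the demographic model:
#' the early-life (age-0) growth and mortality block, post-recruitment
#' mortality-at-age, growth and fecundity parameters, and Monte-Carlo
#' settings.  The shipped preset `"abft_baseline"` is the Atlantic bluefin
#' tuna parameterization; every random trait is a [dist_spec()].
#'
#' Structure (top-level fields):
#' \describe{
#'   \item{terminal_age}{number of post-recruit age classes `A` (years).}
#'   \item{post_recruit}{`mean` (length-`A` vector of mean instantaneous
#'     mortality rates, per year) and `cv` (Gaussian noise CV).}
#'   \item{early_life}{egg/larval/juvenile growth and mortality block; see
#'     [build_trajectory()] and [draw_M0()].}
#'   \item{growth}{von Bertalanffy parameters (`vb`), `length_cv`, and the
#'     length-weight relationship `W = b * L^c` (kg from cm).}
#'   \item{fecundity}{sex ratio, maturity ogive, spawning periodicity
#'     `spe`, relative batch fecundity `bf` (oocytes per gram), and batch
#'     number `n_batch`; see [fecundity_at_age()].}
#'   \item{mc}{`n_draws_r` Leslie-matrix draws, `n_pops` replicate
#'     populations for steepness, and `pop_size` individuals each.}
#' }
#'
#' @name lh_config
NULL

# Canonical baseline parameter set (Atlantic bluefin tuna).
abft_baseline_config <- function() {
  A <- 30L
  cfg <- list(
    preset = "abft_baseline",
    terminal_age = A,
    post_recruit = list(
      mean = c(0.49, 0.24, 0.24, 0.24, 0.24, 0.20, 0.175, 0.125,
               rep(0.1, 22)),
      cv = 0.10
    ),
    early_life = list(
      # fertilization + hatching loss, instantaneous scale: 50% survival
      fert_hatch_mode = "instantaneous",
      m_fh = dist_normal(log(2), 0.10 * log(2), lower = 0,
                         units = "dimensionless"),
      # alternative: survival-scale specification of the same process
      fh_survival = dist_normal(0.5, 0.05, lower = 1e-6, upper = 1 - 1e-6,
                                units = "proportion"),
      w_egg = 42.8e-6,                                   # dry g
      w_ef = dist_normal(21.7e-6, 4e-6, lower = 0, units = "dry g"),
      t_hatch = dist_uniform(1, 2, units = "days"),
      t_ef = dist_uniform(2, 4, units = "days"),
      k1 = 1.851,
      juvenile = list(fl_intercept = 41.20, fl_slope = 2.37,  # fork length mm
                      lw_factor = 1.92e-6, lw_exponent = 3.39, # wet g from mm
                      cv = 0.10),
      hydration_factor = 0.85,
      mcgurk = list(
        small = list(a = 2.2e-4, b = -0.85, sigma = 0.80),
        large = list(a = 5.26e-3, b = -0.25, sigma = 0.86),
        weight_threshold = 0.00504,                      # dry g
        residual_error = TRUE
      ),
      horizon_days = 180L,
      stage_days = list(power_end = 20, exp_end = 60, juv_end = 150),
      m0_override = NULL
    ),
    growth = list(
      vb = list(linf = 314.90, k = 0.089, t0 = -1.13),
      length_cv = 0.10,
      length_weight = list(b = 1.96e-5, c = 3.0092)
    ),
    fecundity = list(
      sex_ratio = 0.5,
      maturity = c(0, 0, 0, 0.5, rep(1, A - 4L)),
      spe = dist_discrete(1:4, units = "years"),
      spe_mode = "per_age",
      spawning_frequency = NULL,   # dist_spec replacing 1/Spe when set
      bf = dist_normal(61.44, 48.33, lower = 0, units = "oocytes/g"),
      n_batch = dist_uniform(2, 10)
    ),
    mc = list(n_draws_r = 10000L, n_pops = 1000L, pop_size = 1000L)
  )
  structure(cfg, class = "lh_config")
}

config_presets <- function() c("abft_baseline")

#' Load a life-history configuration
#'
#' @param source either the name of a shipped preset (`"abft_baseline"`)
#'   or the path of a YAML document.  A document may name a `preset` to
#'   start from (default `"abft_baseline"`) and override any subset of
#'   fields; distribution-valued fields are written as
#'   `{family: ..., params: ...}` mappings.  Unknown keys are rejected.
#' @return a validated `lh_config`.
#' @examples
#' cfg <- load_config("abft_baseline")
#' cfg$terminal_age
#' @export
load_config <- function(source = "abft_baseline") {
  if (inherits(source, "lh_config")) return(validate_config(source))
  if (!is.character(source) || length(source) != 1L) {
    stop("'source' must be a preset name or a file path")
  }
  if (source %in% config_presets()) {
    return(validate_config(abft_baseline_config()))
  }
  if (!file.exists(source)) {
    stop("unknown preset or missing file: '", source, "'")
  }
  doc <- tryCatch(yaml::read_yaml(source), error = function(e) {
    stop("cannot parse config document '", source, "': ",
         conditionMessage(e), call. = FALSE)
  })
  preset <- doc$preset %||% "abft_baseline"
  if (!preset %in% config_presets()) stop("unknown preset: '", preset, "'")
  doc$preset <- NULL
  cfg <- modify_config(abft_baseline_config(), doc)
  cfg$preset <- preset
  validate_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fields whose values are distribution specifications.
.dist_fields <- c("m_fh", "fh_survival", "w_ef", "t_hatch", "t_ef",
                  "m0_override", "spe", "spawning_frequency", "bf", "n_batch")

#' Override configuration fields
#'
#' Deep-merges a named list of overrides into a configuration.  Keys must
#' already exist in the configuration (unknown keys raise an error naming
#' the offending key); values for distribution-valued fields may be
#' `dist_spec` objects or their serialized list form.
#'
#' @param cfg a `lh_config`.
#' @param overrides named list, possibly nested.
#' @return the modified (unvalidated) `lh_config`.
#' @export
modify_config <- function(cfg, overrides) {
  merge1 <- function(base, over, path) {
    for (key in names(over)) {
      here <- if (nzchar(path)) paste0(path, ".", key) else key
      if (!key %in% names(base)) {
        stop("unknown configuration key: '", here, "'", call. = FALSE)
      }
      val <- over[[key]]
      if (key %in% .dist_fields) {
        base[key] <- list(if (is.null(val)) NULL else as_dist_spec(val))
      } else if (is.list(val) && is.list(base[[key]]) &&
                 !is.null(names(base[[key]]))) {
        base[[key]] <- merge1(base[[key]], val, here)
      } else {
        base[[key]] <- val
      }
    }
    base
  }
  out <- merge1(unclass(cfg), overrides, "")
  structure(out, class = "lh_config")
}

#' Validate a life-history configuration
#'
#' Enforces the structural invariants: mortality vector of length `A`
#' with nonnegative rates, maturity ogive in `[0, 1]` and nondecreasing,
#' sex ratio in `(0, 1]`, hydration factor in `(0, 1)`, `A >= 2`, and
#' validity of every embedded distribution specification.  Errors name
#' the offending field.
#'
#' @param cfg a `lh_config`.
#' @return `cfg`, invisibly classed, after validation.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "lh_config")) stop("not an 'lh_config' object")
  fail <- function(field, msg) {
    stop("invalid configuration: field '", field, "' ", msg, call. = FALSE)
  }
  A <- cfg$terminal_age
  if (!is.numeric(A) || A < 2 || A != round(A)) {
    fail("terminal_age", "must be an integer >= 2")
  }
  mu <- cfg$post_recruit$mean
  if (length(mu) != A) fail("post_recruit.mean", paste0("must have length ", A))
  if (any(mu < 0)) fail("post_recruit.mean", "rates must be >= 0")
  if (cfg$post_recruit$cv < 0) fail("post_recruit.cv", "must be >= 0")
  g <- cfg$fecundity$maturity
  if (length(g) != A) fail("fecundity.maturity", paste0("must have length ", A))
  if (any(g < 0 | g > 1)) fail("fecundity.maturity", "must lie in [0, 1]")
  if (any(diff(g) < 0)) fail("fecundity.maturity", "must be nondecreasing")
  sr <- cfg$fecundity$sex_ratio
  if (sr <= 0 || sr > 1) fail("fecundity.sex_ratio", "must lie in (0, 1]")
  hf <- cfg$early_life$hydration_factor
  if (hf <= 0 || hf >= 1) fail("early_life.hydration_factor",
                               "must lie in (0, 1)")
  if (cfg$early_life$w_egg <= 0) fail("early_life.w_egg", "must be > 0")
  if (!cfg$early_life$fert_hatch_mode %in% c("instantaneous", "survival")) {
    fail("early_life.fert_hatch_mode",
         "must be 'instantaneous' or 'survival'")
  }
  if (!cfg$fecundity$spe_mode %in% c("per_age", "per_draw", "expected")) {
    fail("fecundity.spe_mode", "must be 'per_age', 'per_draw' or 'expected'")
  }
  sd_ <- cfg$early_life$stage_days
  if (!(sd_$power_end < sd_$exp_end && sd_$exp_end < sd_$juv_end)) {
    fail("early_life.stage_days", "must satisfy power_end < exp_end < juv_end")
  }
  if (cfg$early_life$horizon_days < sd_$juv_end) {
    fail("early_life.horizon_days", "must reach beyond the juvenile stage")
  }
  for (f in .dist_fields) {
    spec <- cfg$early_life[[f]] %||% cfg$fecundity[[f]]
    if (!is.null(spec)) {
      tryCatch(validate_dist(spec), error = function(e) {
        fail(f, conditionMessage(e))
      })
    }
  }
  with(cfg$mc, {
    if (n_draws_r < 1 || n_pops < 1 || pop_size < 1) {
      fail("mc", "draw counts must be positive")
    }
  })
  invisible(cfg)
}

#' Serialize a configuration
#'
#' `config_as_list()` converts to plain lists (distribution fields in
#' their serialized form); `write_config()` writes YAML that
#' [load_config()] reads back to an identical configuration.
#'
#' @param cfg a `lh_config`.
#' @return a plain nested list.
#' @export
config_as_list <- function(cfg) {
  walk <- function(x) {
    if (inherits(x, "dist_spec")) return(dist_as_list(x))
    if (is.list(x)) return(lapply(x, walk))
    x
  }
  walk(unclass(cfg))
}

#' @rdname config_as_list
#' @param path output file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(config_as_list(validate_config(cfg)), path,
                   precision = 15L)
  invisible(path)
}

#' Reduce (or extend) the number of post-recruit age classes
#'
#' Truncates the mortality-at-age vector and the maturity ogive to a new
#' terminal age (extension pads with the last value).
#'
#' @param cfg a `lh_config`.
#' @param A new terminal age (integer >= 2).
#' @return the modified configuration.
#' @export
set_terminal_age <- function(cfg, A) {
  A <- as.integer(A)
  resize <- function(v) c(v, rep(v[length(v)], max(0, A - length(v))))[seq_len(A)]
  cfg$terminal_age <- A
  cfg$post_recruit$mean <- resize(cfg$post_recruit$mean)
  cfg$fecundity$maturity <- resize(cfg$fecundity$maturity)
  validate_config(cfg)
  cfg
}

#' @export
print.lh_config <- function(x, ...) {
  cat("<lh_config> preset:", x$preset %||% "(custom)", "\n")
  cat("  terminal age:", x$terminal_age, " |  maturity a50 ~",
      which(x$fecundity$maturity >= 0.5)[1], "\n")
  cat("  early-life horizon:", x$early_life$horizon_days, "days;",
      "McGurk residual error:", x$early_life$mcgurk$residual_error, "\n")
  cat("  spawning periodicity mode:", x$fecundity$spe_mode, "\n")
  cat("  Monte Carlo: n_draws_r =", x$mc$n_draws_r, ", n_pops =",
      x$mc$n_pops, ", pop_size =", x$mc$pop_size, "\n")
  invisible(x)
}
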