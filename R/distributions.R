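#' Declarative distribution specifications for life-history traits
#'
#' Every stochastic life-history trait in a [lh_config()] is described by a
#' `dist_spec`: a distribution family, its parameters, optional truncation
#' bounds and a free-text unit label.  Sampling respects the truncation
#' bounds by rejection, so a truncated specification never yields values
#' outside its support.
#'
#' @param family one of `"constant"`, `"normal"`, `"uniform"`,
#'   `"discrete_uniform"`.
#' @param params named list of family parameters: `value` (constant),
#'   `mean`/`sd` (normal), `min`/`max` (uniform), `values`/`prob`
#'   (discrete_uniform; `prob` defaults to equal weights).
#' @param lower,upper optional truncation bounds.
#' @param units free-text unit label carried along for reporting.
#' @return an object of class `dist_spec`.
#' @seealso [sample_dist()], the convenience constructors [dist_constant()],
#'   [dist_normal()], [dist_uniform()], [dist_discrete()].
#' @export
dist_spec <- function(family, params, lower = -Inf, upper = Inf, units = "") {
  family <- match.arg(family, c("constant", "normal", "uniform",
                                "discrete_uniform"))
  spec <- structure(
    list(family = family, params = params, lower = lower, upper = upper,
         units = units),
    class = "dist_spec"
  )
  validate_dist(spec)
  spec
}

#' @rdname dist_spec
#' @param value constant value.
#' @export
dist_constant <- function(value, units = "") {
  dist_spec("constant", list(value = value), units = units)
}

#' @rdname dist_spec
#' @param mean,sd normal mean and standard deviation (`sd > 0`).
#' @export
dist_normal <- function(mean, sd, lower = -Inf, upper = Inf, units = "") {
  dist_spec("normal", list(mean = mean, sd = sd), lower, upper, units)
}

#' @rdname dist_spec
#' @param min,max uniform bounds (`min < max`).
#' @export
dist_uniform <- function(min, max, units = "") {
  dist_spec("uniform", list(min = min, max = max), units = units)
}

#' @rdname dist_spec
#' @param values support of a discrete distribution.
#' @param prob probabilities attached to `values`; equal weights if `NULL`.
#' @export
dist_discrete <- function(values, prob = NULL, units = "") {
  if (is.null(prob)) prob <- rep(1 / length(values), length(values))
  dist_spec("discrete_uniform", list(values = values, prob = prob),
            units = units)
}

#' Validate a distribution specification
#'
#' Checks the family-specific parameter invariants (positive sd, ordered
#' uniform bounds, probabilities summing to one within 1e-12), the ordering
#' of truncation bounds, and that the truncated region retains at least
#' probability mass 1e-6 (so rejection sampling terminates).
#'
#' @param spec a `dist_spec`.
#' @return `spec`, invisibly; errors on violation.
#' @export
validate_dist <- function(spec) {
  if (!inherits(spec, "dist_spec")) stop("not a 'dist_spec' object")
  p <- spec$params
  bad <- function(msg) stop("invalid dist_spec (", spec$family, "): ", msg,
                            call. = FALSE)
  if (!is.numeric(spec$lower) || !is.numeric(spec$upper)) {
    bad("truncation bounds must be numeric")
  }
  if (spec$lower >= spec$upper) bad("truncation requires lower < upper")
  switch(spec$family,
    constant = {
      if (!is.numeric(p$value) || length(p$value) != 1L || !is.finite(p$value))
        bad("'value' must be a finite number")
      if (p$value < spec$lower || p$value > spec$upper)
        bad("constant value outside truncation bounds")
    },
    normal = {
      if (!is.numeric(p$mean) || !is.numeric(p$sd)) bad("needs 'mean' and 'sd'")
      if (p$sd <= 0) bad("sd must be > 0")
      mass <- stats::pnorm(spec$upper, p$mean, p$sd) -
        stats::pnorm(spec$lower, p$mean, p$sd)
      if (mass < 1e-6) bad("truncation region has probability < 1e-6")
    },
    uniform = {
      if (!is.numeric(p$min) || !is.numeric(p$max)) bad("needs 'min' and 'max'")
      if (p$min >= p$max) bad("uniform requires min < max")
      ov <- (min(p$max, spec$upper) - max(p$min, spec$lower)) / (p$max - p$min)
      if (ov < 1e-6) bad("truncation region has probability < 1e-6")
    },
    discrete_uniform = {
      if (length(p$values) != length(p$prob)) bad("values/prob length mismatch")
      if (any(p$prob < 0)) bad("negative probability")
      if (abs(sum(p$prob) - 1) > 1e-12) bad("probabilities must sum to 1")
      inside <- p$values >= spec$lower & p$values <= spec$upper
      if (sum(p$prob[inside]) < 1e-6)
        bad("truncation region has probability < 1e-6")
    }
  )
  invisible(spec)
}

#' Draw from a distribution specification
#'
#' Sampling uses the current R random-number stream, so draws are
#' deterministic for a given `set.seed()`.  Values falling outside the
#' truncation bounds are redrawn (rejection) until inside; infeasible
#' truncations are rejected at validation time.
#'
#' @param spec a `dist_spec`.
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @examples
#' set.seed(1)
#' sample_dist(dist_normal(61.44, 48.33, lower = 0), 5)
#' @export
sample_dist <- function(spec, n = 1L) {
  validate_dist(spec)
  p <- spec$params
  if (spec$family == "constant") return(rep(p$value, n))
  draw <- switch(spec$family,
    normal = function(m) stats::rnorm(m, p$mean, p$sd),
    uniform = function(m) stats::runif(m, p$min, p$max),
    discrete_uniform = function(m) {
      p$values[sample.int(length(p$values), m, replace = TRUE, prob = p$prob)]
    }
  )
  x <- draw(n)
  out <- which(x < spec$lower | x > spec$upper)
  while (length(out)) {
    x[out] <- draw(length(out))
    out <- out[x[out] < spec$lower | x[out] > spec$upper]
  }
  x
}

#' Analytic mean of a distribution specification
#'
#' Used by the deterministic "expected" spawning-frequency mode and by
#' summary reporting.  Truncation is ignored for the normal family only
#' when the truncated mass exceeds 0.999 (the shipped truncations are far
#' from the bulk); otherwise the truncated mean is computed exactly.
#'
#' @param spec a `dist_spec`.
#' @return scalar mean.
#' @keywords internal
#' @export
dist_mean <- function(spec) {
  validate_dist(spec)
  p <- spec$params
  switch(spec$family,
    constant = p$value,
    uniform = {
      lo <- max(p$min, spec$lower); hi <- min(p$max, spec$upper)
      (lo + hi) / 2
    },
    normal = {
      a <- (spec$lower - p$mean) / p$sd
      b <- (spec$upper - p$mean) / p$sd
      z <- stats::pnorm(b) - stats::pnorm(a)
      p$mean + p$sd * (stats::dnorm(a) - stats::dnorm(b)) / z
    },
    discrete_uniform = {
      inside <- p$values >= spec$lower & p$values <= spec$upper
      sum(p$values[inside] * p$prob[inside]) / sum(p$prob[inside])
    }
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- vapply(x$params, function(v) paste(signif(unlist(v), 6), collapse = ","),
              character(1))
  trunc <- if (is.finite(x$lower) || is.finite(x$upper)) {
    sprintf(" [%s, %s]", format(x$lower), format(x$upper))
  } else ""
  cat(sprintf("<dist_spec> %s(%s)%s %s\n", x$family,
              paste(names(p), p, sep = "=", collapse = ", "), trunc, x$units))
  invisible(x)
}

# Re-create a dist_spec from its serialized (plain list) form.
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(validate_dist(x))
  if (is.numeric(x) && length(x) == 1L) return(dist_constant(x))
  if (!is.list(x) || is.null(x$family)) {
    stop("cannot interpret value as a distribution specification")
  }
  dist_spec(x$family, x$params,
            lower = if (is.null(x$lower)) -Inf else x$lower,
            upper = if (is.null(x$upper)) Inf else x$upper,
            units = if (is.null(x$units)) "" else x$units)
}

# Serialized (YAML-friendly) form of a dist_spec.
dist_as_list <- function(spec) {
  out <- list(family = spec$family, params = spec$params)
  if (is.finite(spec$lower)) out$lower <- spec$lower
  if (is.finite(spec$upper)) out$upper <- spec$upper
  if (nzchar(spec$units)) out$units <- spec$units
  out
}
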