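#' Leslie matrix and intrinsic population growth rate
#'
#' The population projection matrix has fecundities in the first row and
#' survival probabilities on the first sub-diagonal; the intrinsic growth
#' rate is `r = log(lambda)` with `lambda` the dominant eigenvalue.
#'
#' Two census conventions are provided, and they share the same dominant
#' eigenvalue (the standard pre-/post-breeding equivalence):
#' \describe{
#'   \item{`"collapsed"`}{pre-breeding census, `A x A`: first row
#'     `exp(-M_0) * F(i)` (an egg must survive the age-0 year before it is
#'     counted as a recruit), sub-diagonal `S(1..A-1)`.}
#'   \item{`"age0"`}{post-breeding census, `(A+1) x (A+1)` with an explicit
#'     age-0 class: first-row entry for parents of class `j-1` is
#'     `surv(j-1) * F(j)` (the parent survives the year, then spawns at age
#'     `j`), with `surv(0) = exp(-M_0)`; sub-diagonal
#'     `exp(-M_0), S(1..A-1)`.}
#' }
#'
#' @name leslie
NULL

#' Build the Leslie projection matrix
#'
#' @param fecundity length-`A` vector `F(i)`: expected age-0 females per
#'   female of age `i` per year (see [fecundity_at_age()]).
#' @param survival length-`A-1` vector of post-recruit annual survival
#'   probabilities `S(1..A-1)`.
#' @param M_0 cumulative age-0 instantaneous mortality (>= 0).
#' @param convention census convention, `"collapsed"` (default) or
#'   `"age0"`; see [leslie].
#' @return a `leslie_matrix` (a plain numeric matrix with attributes).
#' @examples
#' T2 <- build_leslie(c(2, 1.2), 0.5, M_0 = 0.1)
#' growth_rate(T2)
#' @export
build_leslie <- function(fecundity, survival, M_0,
                         convention = c("collapsed", "age0")) {
  convention <- match.arg(convention)
  A <- length(fecundity)
  if (length(survival) != A - 1L) {
    stop("survival must have length A - 1 = ", A - 1L)
  }
  if (!is.finite(M_0) || M_0 < 0) stop("M_0 must be finite and >= 0")
  if (any(fecundity < 0) || any(survival < 0)) {
    stop("fecundities and survivals must be nonnegative")
  }
  S0 <- exp(-M_0)
  if (convention == "collapsed") {
    T_ <- matrix(0, A, A)
    T_[1, ] <- S0 * fecundity
    if (A > 1L) T_[cbind(2:A, 1:(A - 1L))] <- survival
  } else {
    surv <- c(S0, survival)                 # survival out of classes 0..A-1
    T_ <- matrix(0, A + 1L, A + 1L)
    T_[1, 1:A] <- surv * fecundity          # parent survives, spawns F(j)
    T_[cbind(2:(A + 1L), 1:A)] <- surv
  }
  structure(T_, convention = convention, M_0 = M_0, class = c("leslie_matrix",
                                                              "matrix"))
}

#' Intrinsic population growth rate from a projection matrix
#'
#' `r = log(lambda)` with `lambda` the spectral radius.  For a
#' nonnegative matrix the dominant eigenvalue is real (Perron-Frobenius);
#' the eigen route certifies this, the power-iteration route iterates to
#' a fixed tolerance and reports non-convergence.
#'
#' @param T_ square nonnegative matrix.
#' @param method `"eigen"` (dense eigendecomposition, default) or
#'   `"power"` (power iteration).
#' @param tol convergence tolerance for the power method.
#' @param max_iter iteration cap for the power method.
#' @return scalar `r`.
#' @export
growth_rate <- function(T_, method = c("eigen", "power"), tol = 1e-10,
                        max_iter = 100000L) {
  method <- match.arg(method)
  if (!is.matrix(T_) || nrow(T_) != ncol(T_)) stop("T_ must be square")
  if (any(T_ < 0)) stop("T_ must be nonnegative")
  if (all(T_ == 0)) stop("zero matrix has no growth rate")
  lambda <- if (method == "eigen") {
    ev <- eigen(unclass(T_), only.values = TRUE)$values
    lam <- max(Mod(ev))
    dom <- ev[which.max(Mod(ev))]
    if (abs(Im(dom)) > 1e-8 * max(lam, 1)) {
      stop("dominant eigenvalue is not certified real")
    }
    lam
  } else {
    spectral_radius_power(unclass(T_), tol = tol, max_iter = max_iter)
  }
  if (lambda <= 0) {
    stop("spectral radius is 0: no reproductive path through the matrix")
  }
  log(lambda)
}

# Power iteration for the spectral radius of a nonnegative matrix.
# Convergence is judged on the eigen-residual ||T v - lambda v||, which
# bounds the eigenvalue error far more tightly than successive-iterate
# differences.
spectral_radius_power <- function(T_, tol = 1e-10, max_iter = 100000L) {
  n <- nrow(T_)
  v <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    w <- as.vector(T_ %*% v)
    nw <- sum(abs(w))
    if (nw == 0) stop("power iteration collapsed to zero after ", it,
                      " iterations (nilpotent matrix?)")
    lambda <- sum(w * v) / sum(v * v)        # Rayleigh quotient
    if (max(abs(w - lambda * v)) <= tol * max(1, lambda)) {
      return(lambda)
    }
    v <- w / nw
  }
  stop("power iteration did not converge within ", max_iter, " iterations")
}

#' @export
print.leslie_matrix <- function(x, ...) {
  cat(sprintf("<leslie_matrix> %d x %d (%s census, M_0 = %.3f)\n",
              nrow(x), ncol(x), attr(x, "convention"), attr(x, "M_0")))
  invisible(x)
}
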