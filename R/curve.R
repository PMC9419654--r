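# Deterministic multisigmoidal logistic curve and its building blocks.

#' Evaluate the exponent polynomial Q and its derivative P
#'
#' `poly_Q()` evaluates `Q(t) = sum_{i=1}^p beta_i t^i` (no constant term)
#' by Horner's scheme; `poly_P()` evaluates its derivative
#' `P(t) = sum_i i beta_i t^{i-1}`.
#'
#' @param beta Numeric coefficient vector `(beta_1, ..., beta_p)`.
#' @param t Numeric vector of times.
#' @return Numeric vector of polynomial values.
#' @examples
#' poly_Q(c(0.1, -0.009, 0.0002), 10) # 0.3
#' poly_P(c(0.1, -0.009, 0.0002), 0)  # 0.1
#' @export
poly_Q <- function(beta, t) {
  r <- numeric(length(t))
  for (b in rev(beta)) r <- (r + b) * t
  r
}

#' @rdname poly_Q
#' @export
poly_P <- function(beta, t) {
  db <- beta * seq_along(beta)
  if (length(db) == 1L) return(rep(db, length.out = length(t)))
  r <- numeric(length(t))
  for (b in rev(db[-1L])) r <- (r + b) * t
  r + db[1L]
}

# log(eta + exp(-q)), overflow-safe for very negative q (transient
# decreasing stretches of Q make exp(-q) huge).
log_eta_plus_expq <- function(leta, q) {
  m <- pmax(leta, -q)
  m + log(exp(leta - m) + exp(-q - m))
}

#' Relative growth rate of the multisigmoidal logistic curve
#'
#' Computes `h(t) = P(t) exp(-Q(t)) / (eta + exp(-Q(t)))`, the relative
#' growth rate solving `l'(t) = h(t) l(t)`.
#'
#' @param params An [msl_params] object (`sigma2` is not used).
#' @param t Numeric vector of times.
#' @return Numeric vector.
#' @export
growth_rate <- function(params, t) {
  stopifnot(inherits(params, "msl_params"))
  q <- poly_Q(params$beta, t)
  # P e^{-Q}/(eta+e^{-Q}) = P exp(-q - log(eta+e^{-q}))
  poly_P(params$beta, t) * exp(-q - log_eta_plus_expq(log(params$eta), q))
}

#' Multisigmoidal logistic curve
#'
#' The solution of `l'(t) = h(t) l(t)` with `l(t0) = l0`:
#' `l(t) = l0 (eta + exp(-Q(t0))) / (eta + exp(-Q(t)))`. It may have
#' several inflection points; its limit as `t -> Inf` is the carrying
#' capacity returned by [carrying_capacity()].
#'
#' @inheritParams growth_rate
#' @param l0 Positive initial level.
#' @param t0 Initial time.
#' @return Numeric vector of curve values at `t`.
#' @examples
#' p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
#' msl_curve(p, l0 = 5, t0 = 0, t = c(0, 25, 50))
#' @export
msl_curve <- function(params, l0, t0, t) {
  stopifnot(inherits(params, "msl_params"), l0 > 0)
  leta <- log(params$eta)
  lq0 <- log_eta_plus_expq(leta, poly_Q(params$beta, t0))
  lq <- log_eta_plus_expq(leta, poly_Q(params$beta, t))
  l0 * exp(lq0 - lq)
}

#' Carrying capacity of the multisigmoidal logistic curve
#'
#' The limit `l0 (eta + exp(-Q(t0))) / eta` of [msl_curve()] as
#' `t -> Inf`. Unlike the classical logistic model it depends on the
#' initial condition `l0`.
#'
#' @inheritParams msl_curve
#' @return Positive scalar.
#' @export
carrying_capacity <- function(params, l0, t0) {
  stopifnot(inherits(params, "msl_params"), l0 > 0)
  leta <- log(params$eta)
  l0 * exp(log_eta_plus_expq(leta, poly_Q(params$beta, t0)) - leta)
}

#' Inflection-point equation of the curve
#'
#' Inflection times of the multisigmoidal logistic curve solve
#' `dP/dt = P(t)^2 (eta - exp(-Q(t))) / (eta + exp(-Q(t)))`.
#' `inflection_residual()` returns the difference of the two sides (zero
#' at candidate inflection points); [find_inflections()] locates its
#' sign-change roots on an interval by a dense scan refined with
#' bisection.
#'
#' @inheritParams growth_rate
#' @return Numeric vector of residual values.
#' @export
inflection_residual <- function(params, t) {
  stopifnot(inherits(params, "msl_params"))
  beta <- params$beta
  dP <- if (length(beta) >= 2L) {
    d2 <- beta[-1L] * seq_along(beta[-1L]) * (seq_along(beta[-1L]) + 1L)
    # second derivative of Q: sum_{i>=2} i(i-1) beta_i t^{i-2}
    r <- numeric(length(t))
    if (length(d2) > 1L) for (b in rev(d2[-1L])) r <- (r + b) * t
    r + d2[1L]
  } else {
    numeric(length(t))
  }
  q <- poly_Q(beta, t)
  # (eta - e^{-Q})/(eta + e^{-Q}) computed on the log scale for stability
  leta <- log(params$eta)
  lden <- log_eta_plus_expq(leta, q)
  ratio <- exp(leta - lden) - exp(-q - lden)
  dP - poly_P(beta, t)^2 * ratio
}

#' @rdname inflection_residual
#' @param t_lo,t_hi Search interval, `t_lo < t_hi`.
#' @param grid_n Number of points of the sign-scan grid.
#' @param tol Bisection tolerance on `t`.
#' @return For `find_inflections()`: a sorted numeric vector of roots
#'   (empty when no sign change occurs in the interval).
#' @examples
#' p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
#' find_inflections(p, 0, 50) # three inflection times
#' @export
find_inflections <- function(params, t_lo, t_hi, grid_n = 2000L, tol = 1e-10) {
  stopifnot(inherits(params, "msl_params"), t_lo < t_hi)
  tt <- seq(t_lo, t_hi, length.out = grid_n)
  rr <- inflection_residual(params, tt)
  sgn <- sign(rr)
  idx <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  roots <- vapply(idx, function(i) {
    a <- tt[i]; b <- tt[i + 1L]
    fa <- rr[i]
    while (b - a > tol) {
      mid <- (a + b) / 2
      fm <- inflection_residual(params, mid)
      if (sign(fm) == sign(fa)) { a <- mid; fa <- fm } else b <- mid
    }
    (a + b) / 2
  }, numeric(1))
  exact <- tt[which(rr == 0)]
  sort(unique(c(roots, exact)))
}
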