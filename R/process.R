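# Exact distributional laws and moments of the diffusion process.

#' Integrated drift correction H
#'
#' Closed form of `H(s, t) = int_s^t h(u) du - sigma^2 (t - s) / 2`,
#' i.e. `log[(eta + e^{-Q(s)}) / (eta + e^{-Q(t)})] - sigma^2 (t - s) / 2`.
#' This is the log-scale conditional displacement of the process between
#' two observation times; no quadrature is involved.
#'
#' @param params An [msl_params] object.
#' @param s,t Times with `s <= t` (vectorised; recycled).
#' @return Numeric vector.
#' @export
H_xi <- function(params, s, t) {
  stopifnot(inherits(params, "msl_params"))
  if (any(t < s)) rlang::abort("`H_xi()` needs s <= t.", class = "msl_bad_times")
  leta <- log(params$eta)
  log_eta_plus_expq(leta, poly_Q(params$beta, s)) -
    log_eta_plus_expq(leta, poly_Q(params$beta, t)) -
    params$sigma2 / 2 * (t - s)
}

#' Transition law of the process
#'
#' Conditional on `X(s) = z`, the state `X(t)` is lognormal with
#' log-scale mean `log z + H(s, t)` and variance `sigma^2 (t - s)`.
#'
#' @inheritParams H_xi
#' @param z Positive conditioning state.
#' @return A [lognormal_law].
#' @export
transition_law <- function(params, z, s, t) {
  stopifnot(inherits(params, "msl_params"), length(s) == 1L, length(t) == 1L)
  if (t <= s) rlang::abort("Transition needs `s < t`.", class = "msl_bad_times")
  if (z <= 0) rlang::abort("`z` must be positive.", class = "msl_bad_state")
  lognormal_law(log(z) + H_xi(params, s, t), params$sigma2 * (t - s))
}

init_mean <- function(init) {
  if (init$kind == "degenerate") init$x0 else exp(init$mu0 + init$sigma0sq / 2)
}

#' Mean and percentiles of the process
#'
#' `process_mean()` returns `E[X(t)] = E[X0] (eta + e^{-Q(t0)}) /
#' (eta + e^{-Q(t)})`, itself a multisigmoidal logistic curve of `t`.
#' `process_percentile()` returns the exact lognormal `alpha`-percentile
#' of `X(t)`.
#'
#' @inheritParams H_xi
#' @param init An [msl_init_degenerate] / [msl_init_lognormal] object.
#' @param t0 Initial time; `t >= t0`.
#' @param t Times (vectorised).
#' @return Numeric vector.
#' @examples
#' p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
#' process_mean(p, msl_init_degenerate(5), t0 = 0, t = 50)
#' @export
process_mean <- function(params, init, t0, t) {
  stopifnot(inherits(params, "msl_params"), inherits(init, "msl_init"))
  if (any(t < t0)) rlang::abort("Need t >= t0.", class = "msl_bad_times")
  msl_curve(params, init_mean(init), t0, t)
}

#' @rdname process_mean
#' @param alpha Percentile level in (0, 1).
#' @export
process_percentile <- function(params, init, alpha, t0, t) {
  stopifnot(inherits(params, "msl_params"), inherits(init, "msl_init"))
  if (any(alpha <= 0 | alpha >= 1)) {
    rlang::abort("`alpha` must lie strictly in (0, 1).", class = "msl_bad_level")
  }
  if (any(t < t0)) rlang::abort("Need t >= t0.", class = "msl_bad_times")
  leta <- log(params$eta)
  lq0 <- log_eta_plus_expq(leta, poly_Q(params$beta, t0))
  lq <- log_eta_plus_expq(leta, poly_Q(params$beta, t))
  exp(lq0 - lq) * exp(init$mu0 - params$sigma2 / 2 * (t - t0) +
                        stats::qnorm(alpha) *
                          sqrt(init$sigma0sq + params$sigma2 * (t - t0)))
}
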