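#' Parameters of the multisigmoidal logistic diffusion
#'
#' Bundles the drift parameters `theta = (eta, beta)` and the squared
#' infinitesimal-variance coefficient `sigma2` of the lognormal diffusion
#' whose mean follows a multisigmoidal logistic curve. The polynomial
#' `Q(t) = sum_i beta_i t^i` has no constant term and its leading
#' coefficient must be positive so that `Q(t) -> +Inf` and the curve
#' saturates at a finite carrying capacity.
#'
#' @param eta Positive real. Controls the carrying capacity `C / eta`.
#' @param beta Numeric vector `(beta_1, ..., beta_p)`, `p >= 1`, with
#'   `beta_p > 0`.
#' @param sigma2 Positive real, the squared diffusion coefficient.
#'
#' @return An object of class `"msl_params"`.
#' @examples
#' msl_params(eta = exp(-1), beta = c(0.1, -0.009, 0.0002), sigma2 = 1e-4)
#' @export
msl_params <- function(eta, beta, sigma2) {
  stopifnot(is.numeric(eta), length(eta) == 1L, is.numeric(sigma2),
            length(sigma2) == 1L, is.numeric(beta), length(beta) >= 1L)
  if (!is.finite(eta) || eta <= 0) {
    rlang::abort("`eta` must be a positive finite number.", class = "msl_bad_params")
  }
  if (!is.finite(sigma2) || sigma2 <= 0) {
    rlang::abort("`sigma2` must be a positive finite number.", class = "msl_bad_params")
  }
  if (any(!is.finite(beta))) {
    rlang::abort("`beta` must be finite.", class = "msl_bad_params")
  }
  if (beta[length(beta)] <= 0) {
    rlang::abort(
      "The leading coefficient `beta_p` must be positive (finite carrying capacity).",
      class = "msl_bad_params")
  }
  structure(
    list(eta = as.numeric(eta), beta = as.numeric(beta),
         sigma2 = as.numeric(sigma2), p = length(beta)),
    class = "msl_params")
}

#' @export
print.msl_params <- function(x, ...) {
  cat("<msl_params> multisigmoidal logistic diffusion parameters\n")
  cat("  eta    =", format(x$eta), "\n")
  cat("  beta   =", paste(format(x$beta), collapse = ", "),
      sprintf(" (degree p = %d)\n", x$p))
  cat("  sigma2 =", format(x$sigma2), " (sigma =", format(sqrt(x$sigma2)), ")\n")
  invisible(x)
}

#' Initial state of the process
#'
#' The process starts either degenerate at a fixed value `x0` (then
#' `mu0 = log x0`, `sigma0sq = 0`) or from a lognormal law with log-scale
#' location `mu0` and variance `sigma0sq > 0`.
#'
#' @param x0 Positive initial value (degenerate case).
#' @param mu0,sigma0sq Log-scale location and variance (lognormal case).
#' @return An object of class `"msl_init"` with fields `kind`, `x0`,
#'   `mu0`, `sigma0sq`.
#' @examples
#' msl_init_degenerate(5)
#' msl_init_lognormal(log(5), 0.01)
#' @export
msl_init_degenerate <- function(x0) {
  stopifnot(is.numeric(x0), length(x0) == 1L, is.finite(x0))
  if (x0 <= 0) rlang::abort("`x0` must be positive.", class = "msl_bad_init")
  structure(list(kind = "degenerate", x0 = as.numeric(x0),
                 mu0 = log(x0), sigma0sq = 0),
            class = "msl_init")
}

#' @rdname msl_init_degenerate
#' @export
msl_init_lognormal <- function(mu0, sigma0sq) {
  stopifnot(is.numeric(mu0), length(mu0) == 1L, is.finite(mu0),
            is.numeric(sigma0sq), length(sigma0sq) == 1L, is.finite(sigma0sq))
  if (sigma0sq <= 0) {
    rlang::abort("`sigma0sq` must be positive; use msl_init_degenerate() otherwise.",
                 class = "msl_bad_init")
  }
  structure(list(kind = "lognormal", x0 = exp(mu0), mu0 = as.numeric(mu0),
                 sigma0sq = as.numeric(sigma0sq)),
            class = "msl_init")
}

#' @export
print.msl_init <- function(x, ...) {
  if (x$kind == "degenerate") {
    cat("<msl_init> degenerate at x0 =", format(x$x0), "\n")
  } else {
    cat("<msl_init> lognormal, mu0 =", format(x$mu0),
        " sigma0sq =", format(x$sigma0sq), "\n")
  }
  invisible(x)
}

#' One-dimensional lognormal law
#'
#' Container for a lognormal distribution on the original scale:
#' `log X ~ N(mu, s2)`.
#'
#' @param mu Log-scale mean.
#' @param s2 Log-scale variance, positive.
#' @return An object of class `"lognormal_law"`.
#' @export
lognormal_law <- function(mu, s2) {
  stopifnot(is.numeric(mu), is.numeric(s2), length(mu) == 1L, length(s2) == 1L)
  if (!is.finite(s2) || s2 <= 0) {
    rlang::abort("`s2` must be a positive finite variance.", class = "msl_bad_law")
  }
  structure(list(mu = as.numeric(mu), s2 = as.numeric(s2)),
            class = "lognormal_law")
}

#' @export
print.lognormal_law <- function(x, ...) {
  cat("<lognormal_law> log X ~ N(", format(x$mu), ",", format(x$s2), ")\n")
  invisible(x)
}

#' Constant boundary for the first-passage-time problem
#'
#' @param S Constant boundary level, strictly above the initial value.
#' @param x0 Initial value of the process.
#' @param t0 Initial time (default 0).
#' @return An object of class `"msl_boundary"`.
#' @export
boundary_spec <- function(S, x0, t0 = 0) {
  stopifnot(is.numeric(S), is.numeric(x0), is.numeric(t0),
            length(S) == 1L, length(x0) == 1L, length(t0) == 1L)
  if (x0 <= 0) rlang::abort("`x0` must be positive.", class = "msl_bad_boundary")
  if (S <= x0) {
    rlang::abort("Only upward crossings are supported: need `S > x0`.",
                 class = "msl_bad_boundary")
  }
  structure(list(S = as.numeric(S), x0 = as.numeric(x0), t0 = as.numeric(t0)),
            class = "msl_boundary")
}
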