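# Likelihood machinery for discretely observed sample paths.
#
# The log-likelihood factorises over transitions; after the change of
# variables v_ij = dt^{-1/2} log(x_{i,j+1}/x_ij) every step enters only
# through its time pair (t_j, t_{j+1}) and the per-step sums of v. All
# quantities are therefore accumulated on a table of *unique* steps,
# which makes likelihood evaluations O(#unique steps) rather than
# O(#observations) -- the difference between milliseconds and seconds
# inside simulated annealing.

#' V-transform of a sample panel
#'
#' Computes the initial observations `V0_i = x_{i1}` and the scaled log
#' increments `v_ij = (t_{i,j+1} - t_{ij})^{-1/2} log(x_{i,j+1}/x_{ij})`,
#' together with the summary statistics `Z1 = sum v^2`,
#' `Z2 = sum v sqrt(dt)` and `Z3 = sum_i (t_{i,n_i} - t_{i,1})` (total
#' elapsed time per path) and the total step count
#' `n = sum_i (n_i - 1)`.
#'
#' @param panel A panel data frame (see [as_msl_panel()]), or an
#'   `msl_vstats` object (returned unchanged).
#' @return An object of class `"msl_vstats"`: list with `v0`, `d`, `n`,
#'   `t0`, `Z1`, `Z2`, `Z3` and a collapsed `steps` table
#'   (`t_from`, `t_to`, `delta`, `count`, `sum_v`).
#' @export
v_transform <- function(panel) {
  if (inherits(panel, "msl_vstats")) return(panel)
  panel <- as_msl_panel(panel)
  inc <- dplyr::mutate(dplyr::group_by(panel, .data$path_id),
                       t_from = .data$time,
                       t_to = dplyr::lead(.data$time),
                       v = log(dplyr::lead(.data$value) / .data$value) /
                         sqrt(dplyr::lead(.data$time) - .data$time)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$t_to))
  steps <- dplyr::summarise(dplyr::group_by(inc, .data$t_from, .data$t_to),
                            count = dplyr::n(),
                            sum_v = sum(.data$v),
                            sum_v2 = sum(.data$v^2), .groups = "drop") |>
    dplyr::mutate(delta = .data$t_to - .data$t_from)
  per_path <- dplyr::summarise(dplyr::group_by(panel, .data$path_id),
                               v0 = .data$value[1L],
                               span = max(.data$time) - min(.data$time),
                               .groups = "drop")
  structure(list(
    v0 = per_path$v0,
    d = nrow(per_path),
    n = sum(steps$count),
    t0 = min(panel$time),
    Z1 = sum(steps$sum_v2),
    Z2 = sum(steps$sum_v * sqrt(steps$delta)),
    Z3 = sum(per_path$span),
    steps = steps), class = "msl_vstats")
}

#' @export
print.msl_vstats <- function(x, ...) {
  cat("<msl_vstats>", x$d, "paths,", x$n, "steps (",
      nrow(x$steps), "unique ), t0 =", x$t0, "\n")
  cat("  Z1 =", format(x$Z1), " Z2 =", format(x$Z2), " Z3 =", format(x$Z3), "\n")
  invisible(x)
}

#' MLE of the initial lognormal law
#'
#' Closed-form estimates from the first observations of the `d` paths:
#' `mu1_hat = mean(log v0)` and `sigma1sq_hat` the mean squared
#' deviation (divisor `d`, not `d - 1`).
#'
#' @param x A panel or `msl_vstats` object.
#' @return Named numeric vector `c(mu1, sigma1sq)`.
#' @export
alpha_mle <- function(x) {
  vs <- v_transform(x)
  lv0 <- log(vs$v0)
  c(mu1 = mean(lv0), sigma1sq = mean((lv0 - mean(lv0))^2))
}

theta_parts <- function(theta) {
  if (inherits(theta, "msl_params")) list(eta = theta$eta, beta = theta$beta)
  else list(eta = theta[[1L]], beta = as.numeric(theta[[2L]]))
}

# lambda_j = log[(eta+e^{-Q(t_from)})/(eta+e^{-Q(t_to)})] per unique step
step_lambda <- function(eta, beta, steps) {
  leta <- log(eta)
  log_eta_plus_expq(leta, poly_Q(beta, steps$t_from)) -
    log_eta_plus_expq(leta, poly_Q(beta, steps$t_to))
}

# (p+1) x nsteps matrix of lD^{i,j+1,j} differences: row l+1 holds
# a_l(t_to) - a_l(t_from), a_0(t) = -1/(eta+e^{-Q}), a_l(t) =
# -t^l e^{-Q}/(eta+e^{-Q}) for l >= 1.
step_lD <- function(eta, beta, steps, p) {
  leta <- log(eta)
  tt <- c(steps$t_from, steps$t_to)
  q <- poly_Q(beta, tt)
  lq <- log_eta_plus_expq(leta, q)
  inv <- -exp(-lq)         # a_0
  eq <- exp(-q - lq)       # e^{-Q}/(eta+e^{-Q})
  ns <- nrow(steps)
  out <- matrix(0, p + 1L, ns)
  out[1L, ] <- inv[(ns + 1L):(2L * ns)] - inv[1L:ns]
  for (l in seq_len(p)) {
    al <- -tt^l * eq
    out[l + 1L, ] <- al[(ns + 1L):(2L * ns)] - al[1L:ns]
  }
  out
}

#' Likelihood building blocks
#'
#' Accumulates the step-level quantities of the log-likelihood and of
#' the score system for a drift parameter value `theta = (eta, beta)`:
#' `A`, `B`, `C` (from the log-ratios `lambda`), the score sums `W_l`,
#' `Y_l`, `X_l` built from the gradient differences `lD`, and -- when
#' `sigma2` is supplied -- the per-step conditional means
#' `m = lambda - sigma2 dt / 2` with their aggregates `Phi`, `Gamma`,
#' `Y_xi`. The identities `Phi = A + sigma2^2 Z3 / 4 - sigma2 C`,
#' `Gamma = B - sigma2 Z2 / 2` and `Y_xi = C - sigma2 Z3 / 2` hold for
#' every `sigma2`.
#'
#' @param x A panel or `msl_vstats` object.
#' @param theta An [msl_params] object or list `list(eta, beta)`.
#' @param sigma2 Optional positive scalar; when given (or when `theta`
#'   is an `msl_params`) the `sigma2`-dependent blocks are included.
#' @return A list of class `"msl_blocks"`.
#' @export
likelihood_blocks <- function(x, theta, sigma2 = NULL) {
  vs <- v_transform(x)
  th <- theta_parts(theta)
  if (is.null(sigma2) && inherits(theta, "msl_params")) sigma2 <- theta$sigma2
  st <- vs$steps
  lam <- step_lambda(th$eta, th$beta, st)
  p <- length(th$beta)
  lD <- step_lD(th$eta, th$beta, st, p)
  w_cnt <- st$count
  A <- sum(w_cnt * lam^2 / st$delta)
  B <- sum(st$sum_v * lam / sqrt(st$delta))
  C <- sum(w_cnt * lam)
  W <- as.numeric(lD %*% w_cnt)
  Y <- as.numeric(lD %*% (-w_cnt * lam / st$delta))
  X <- as.numeric(lD %*% (st$sum_v / sqrt(st$delta)))
  out <- list(eta = th$eta, beta = th$beta, p = p, lambda = lam, lD = lD,
              A = A, B = B, C = C, W = W, Y = Y, X = X,
              n = vs$n, Z1 = vs$Z1, Z2 = vs$Z2, Z3 = vs$Z3)
  if (!is.null(sigma2)) {
    m <- lam - sigma2 / 2 * st$delta
    out$sigma2 <- sigma2
    out$m_xi <- m
    out$Phi <- sum(w_cnt * m^2 / st$delta)
    out$Gamma <- sum(st$sum_v * m / sqrt(st$delta))
    out$Yxi <- sum(w_cnt * m)
  }
  structure(out, class = "msl_blocks")
}

#' Reduced log-likelihood of the diffusion parameters
#'
#' The part of the log-likelihood that depends only on
#' `xi = (eta, beta, sigma2)`:
#' `L_tilde = -(n/2) log sigma2 - (Z1 + Phi - 2 Gamma) / (2 sigma2)`.
#' This is the objective maximised by both fitting routes.
#'
#' @param x A panel or `msl_vstats` object.
#' @param params An [msl_params] object.
#' @return Scalar.
#' @export
reduced_log_likelihood <- function(x, params) {
  stopifnot(inherits(params, "msl_params"))
  vs <- v_transform(x)
  rll_raw(vs, params$eta, params$beta, params$sigma2)
}

# unclassed fast path used by the optimisers
rll_raw <- function(vs, eta, beta, sigma2) {
  if (!is.finite(eta) || eta <= 0 || !is.finite(sigma2) || sigma2 <= 0) {
    return(-Inf)
  }
  st <- vs$steps
  lam <- step_lambda(eta, beta, st)
  m <- lam - sigma2 / 2 * st$delta
  Phi <- sum(st$count * m^2 / st$delta)
  Gamma <- sum(st$sum_v * m / sqrt(st$delta))
  -vs$n / 2 * log(sigma2) - (vs$Z1 + Phi - 2 * Gamma) / (2 * sigma2)
}

#' Full log-likelihood
#'
#' The log-likelihood of the V-transformed sample when the initial state
#' follows a lognormal law with parameters `alpha = (mu1, sigma1sq)`:
#' the reduced part plus the initial-state terms
#' `-(n + d)/2 log 2 pi - d/2 log sigma1sq - sum log v0 -
#' sum (log v0 - mu1)^2 / (2 sigma1sq)`.
#'
#' @param x A panel or `msl_vstats` object.
#' @param alpha Numeric `c(mu1, sigma1sq)` with `sigma1sq > 0`.
#' @param params An [msl_params] object.
#' @return Scalar.
#' @export
log_likelihood <- function(x, alpha, params) {
  stopifnot(inherits(params, "msl_params"), length(alpha) == 2L)
  if (alpha[2L] <= 0) {
    rlang::abort("`sigma1sq` must be positive; degenerate initial laws have no density.",
                 class = "msl_bad_alpha")
  }
  alpha <- unname(alpha)
  vs <- v_transform(x)
  lv0 <- log(vs$v0)
  rll_raw(vs, params$eta, params$beta, params$sigma2) -
    (vs$n + vs$d) / 2 * log(2 * pi) - vs$d / 2 * log(alpha[2L]) -
    sum(lv0) - sum((lv0 - alpha[1L])^2) / (2 * alpha[2L])
}

#' Closed-form sigma2 given the drift parameters
#'
#' Remark-1 root of the first likelihood equation: for fixed
#' `theta = (eta, beta)` the only admissible solution is
#' `sigma2 = 2 (-n + sqrt(n^2 + Z3 (Z1 + A - 2B))) / Z3`, always
#' non-negative because `Z1 + A - 2B = sum (v - lambda/sqrt(dt))^2`.
#'
#' @inheritParams likelihood_blocks
#' @return Non-negative scalar.
#' @export
sigma2_given_theta <- function(x, theta) {
  vs <- v_transform(x)
  th <- theta_parts(theta)
  st <- vs$steps
  lam <- step_lambda(th$eta, th$beta, st)
  A <- sum(st$count * lam^2 / st$delta)
  B <- sum(st$sum_v * lam / sqrt(st$delta))
  S <- max(vs$Z1 + A - 2 * B, 0)
  2 * (-vs$n + sqrt(vs$n^2 + vs$Z3 * S)) / vs$Z3
}

#' Residuals of the maximum-likelihood system
#'
#' The `p + 2` nonlinear equations whose zeros are the MLEs of
#' `xi = (eta, beta, sigma2)`:
#' `sigma2 (n + sigma2 Z3 / 4) - Z1 - A + 2B = 0` and
#' `Y_l + (sigma2 / 2) W_l + X_l = 0` for `l = 0, ..., p`. Up to
#' per-equation scaling these are the partial derivatives of the reduced
#' log-likelihood.
#'
#' @param x A panel or `msl_vstats` object.
#' @param params An [msl_params] object.
#' @return Numeric vector of length `p + 2`.
#' @export
system_residuals <- function(x, params) {
  stopifnot(inherits(params, "msl_params"))
  vs <- v_transform(x)
  resid_raw(vs, params$eta, params$beta, params$sigma2)
}

resid_raw <- function(vs, eta, beta, sigma2) {
  st <- vs$steps
  p <- length(beta)
  lam <- step_lambda(eta, beta, st)
  lD <- step_lD(eta, beta, st, p)
  A <- sum(st$count * lam^2 / st$delta)
  B <- sum(st$sum_v * lam / sqrt(st$delta))
  r1 <- sigma2 * (vs$n + sigma2 / 4 * vs$Z3) - vs$Z1 - A + 2 * B
  W <- as.numeric(lD %*% st$count)
  Y <- as.numeric(lD %*% (-st$count * lam / st$delta))
  X <- as.numeric(lD %*% (st$sum_v / sqrt(st$delta)))
  c(r1, Y + sigma2 / 2 * W + X)
}
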