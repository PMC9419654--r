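# Fisher information, delta-method intervals and the exact laws of the
# initial-distribution estimates.

# per-unique-step gradient of the conditional mean m w.r.t. theta:
# dm/deta = 1/(eta+e^{-Q(s)}) - 1/(eta+e^{-Q(t)}),
# dm/dbeta_l = -s^l e^{-Q(s)}/(eta+e^{-Q(s)}) + t^l e^{-Q(t)}/(eta+e^{-Q(t)}).
step_dm <- function(eta, beta, steps, p) {
  leta <- log(eta)
  tt <- c(steps$t_from, steps$t_to)
  q <- poly_Q(beta, tt)
  lq <- log_eta_plus_expq(leta, q)
  inv <- exp(-lq)
  eq <- exp(-q - lq)
  ns <- nrow(steps)
  G <- matrix(0, ns, p + 1L)
  G[, 1L] <- inv[1L:ns] - inv[(ns + 1L):(2L * ns)]
  for (l in seq_len(p)) {
    al <- tt^l * eq
    G[, l + 1L] <- -al[1L:ns] + al[(ns + 1L):(2L * ns)]
  }
  G
}

#' Fisher information matrix of the diffusion parameters
#'
#' Assembles the `(p + 2) x (p + 2)` information matrix
#' `I(xi) = (1 / sigma2) [ Xi, -dgamma/2 ; -dgamma'/2, n/(2 sigma2) - Z3/4 ]`
#' with `Xi = sum_steps dt^{-1} (dm/dtheta)(dm/dtheta)'` and
#' `dgamma = sum_steps dm/dtheta`, evaluated at the supplied parameter
#' value (plug in the MLE for observed-at-estimate intervals).
#'
#' @param panel A panel data frame (or `msl_vstats`).
#' @param params An [msl_params] object (or an `"msl_fit"`).
#' @return A list of class `"msl_fisher"`: `matrix`, plus the blocks
#'   `Xi`, `dgamma`, `corner` (the latter before the `1/sigma2` factor).
#' @export
fisher_information <- function(panel, params) {
  vs <- v_transform(panel)
  if (inherits(params, "msl_fit")) params <- fit_params(params)
  stopifnot(inherits(params, "msl_params"))
  st <- vs$steps
  p <- params$p
  G <- step_dm(params$eta, params$beta, st, p)
  wc <- st$count
  Xi <- crossprod(G * sqrt(wc / st$delta))
  dgamma <- as.numeric(crossprod(G, wc))
  corner <- vs$n / (2 * params$sigma2) - vs$Z3 / 4
  I <- rbind(cbind(Xi, -dgamma / 2), c(-dgamma / 2, corner)) / params$sigma2
  nm <- c("eta", paste0("beta_", seq_len(p)), "sigma2")
  dimnames(I) <- list(nm, nm)
  structure(list(matrix = I, Xi = Xi, dgamma = dgamma, corner = corner,
                 n = vs$n, Z3 = vs$Z3, sigma2 = params$sigma2),
            class = "msl_fisher")
}

#' @export
print.msl_fisher <- function(x, ...) {
  cat("<msl_fisher> Fisher information,", nrow(x$matrix), "parameters\n")
  print(signif(x$matrix, 4))
  invisible(x)
}

# inverse with pseudo-inverse fallback for near-singular information
solve_info <- function(I) {
  kappa <- tryCatch(kappa(I, exact = FALSE), error = function(e) Inf)
  if (is.finite(kappa) && kappa < 1e12) {
    ok <- tryCatch(list(V = solve(I), reliable = TRUE), error = function(e) NULL)
    if (!is.null(ok)) return(ok)
  }
  rlang::warn("Information matrix is near-singular; using a pseudo-inverse. Intervals may be unreliable.")
  sv <- svd(I)
  pos <- sv$d > max(sv$d) * 1e-12
  V <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  list(V = V, reliable = FALSE)
}

#' Asymptotic confidence intervals for the diffusion parameters
#'
#' Normal intervals `xi_hat_k +/- z_{(1+level)/2} sqrt([I(xi_hat)^-1]_kk)`
#' from the inverse Fisher information evaluated at the estimate.
#'
#' @param fit An `"msl_fit"`.
#' @param panel The panel the fit was computed from.
#' @param level Confidence levels (default 0.95, 0.90, 0.75).
#' @return A tibble with columns `parameter`, `estimate`, `se`, `level`,
#'   `lower`, `upper`, `reliable`.
#' @export
asymptotic_ci <- function(fit, panel, level = c(0.95, 0.90, 0.75)) {
  stopifnot(inherits(fit, "msl_fit"), all(level > 0 & level < 1))
  fi <- fisher_information(panel, fit_params(fit))
  inv <- solve_info(fi$matrix)
  se <- unname(sqrt(pmax(diag(inv$V), 0)))
  est <- c(fit$eta, fit$beta, fit$sigma2)
  nm <- colnames(fi$matrix)
  purrr::map_dfr(level, function(lv) {
    z <- stats::qnorm((1 + lv) / 2)
    tibble::tibble(parameter = nm, estimate = est, se = se, level = lv,
                   lower = est - z * se, upper = est + z * se,
                   reliable = inv$reliable)
  })
}

#' Delta-method interval for a parametric function
#'
#' Normal interval for `g(xi_hat)` with variance
#' `grad g' I(xi_hat)^-1 grad g`; the gradient is supplied or computed
#' by central finite differences.
#'
#' @inheritParams asymptotic_ci
#' @param g Function of the parameter vector `(eta, beta_1..beta_p,
#'   sigma2)` returning a scalar.
#' @param gradient Optional function returning the gradient vector.
#' @param level Single confidence level.
#' @return A one-row tibble `estimate`, `se`, `lower`, `upper`,
#'   `reliable`.
#' @export
delta_method_ci <- function(fit, panel, g, gradient = NULL, level = 0.95) {
  stopifnot(inherits(fit, "msl_fit"), level > 0, level < 1)
  xi <- c(fit$eta, fit$beta, fit$sigma2)
  fi <- fisher_information(panel, fit_params(fit))
  inv <- solve_info(fi$matrix)
  gr <- if (is.null(gradient)) {
    vapply(seq_along(xi), function(k) {
      h <- 1e-6 * max(abs(xi[k]), 1e-8)
      xp <- xi; xm <- xi
      xp[k] <- xi[k] + h; xm[k] <- xi[k] - h
      (g(xp) - g(xm)) / (2 * h)
    }, numeric(1))
  } else {
    gradient(xi)
  }
  va <- max(as.numeric(t(gr) %*% inv$V %*% gr), 0)
  z <- stats::qnorm((1 + level) / 2)
  est <- g(xi)
  tibble::tibble(estimate = est, se = sqrt(va),
                 lower = est - z * sqrt(va), upper = est + z * sqrt(va),
                 reliable = inv$reliable)
}

#' Exact intervals for the initial-law parameters
#'
#' `mu1_hat` is exactly normal with variance `sigma1^2 / d` (plug-in),
#' and `d sigma1sq_hat / sigma1^2` is chi-square with `d - 1` degrees of
#' freedom, giving the pivot interval
#' `( d sigma1sq_hat / chisq_{d-1,(1+level)/2},
#'    d sigma1sq_hat / chisq_{d-1,(1-level)/2} )`.
#'
#' @param mu1_hat,sigma1sq_hat Estimates from [alpha_mle()].
#' @param d Number of sample paths, at least 2.
#' @param level Confidence level.
#' @return A tibble with one row per parameter.
#' @export
initial_law_ci <- function(mu1_hat, sigma1sq_hat, d, level = 0.95) {
  if (d < 2) rlang::abort("Need at least d = 2 paths.", class = "msl_bad_d")
  if (sigma1sq_hat <= 0) {
    rlang::warn("sigma1sq_hat is zero (degenerate initial sample); intervals collapse to points.")
    return(tibble::tibble(parameter = c("mu1", "sigma1sq"),
                          estimate = c(mu1_hat, 0), level = level,
                          lower = c(mu1_hat, 0), upper = c(mu1_hat, 0)))
  }
  z <- stats::qnorm((1 + level) / 2)
  se_mu <- sqrt(sigma1sq_hat / d)
  qs <- stats::qchisq(c((1 + level) / 2, (1 - level) / 2), df = d - 1)
  tibble::tibble(
    parameter = c("mu1", "sigma1sq"),
    estimate = c(mu1_hat, sigma1sq_hat),
    level = level,
    lower = c(mu1_hat - z * se_mu, d * sigma1sq_hat / qs[1L]),
    upper = c(mu1_hat + z * se_mu, d * sigma1sq_hat / qs[2L]))
}
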