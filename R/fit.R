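# Initial solutions and the Newton-Raphson fitter.

#' Regression-based initial solution for (eta, beta)
#'
#' Approximates the carrying capacity by the last sample mean `m_N` and
#' fits the linearisation `-log(m_N / m_j - 1) = Q(t_j) + log eta` by
#' ordinary least squares over the interior time points. Pairs with
#' `m_j >= m_N` (noise pushed the mean above its final value) are
#' dropped, as are plateau pairs with `m_N / m_j - 1 <= plateau_tol`,
#' where the log response degenerates.
#'
#' @param panel A panel data frame.
#' @param p Polynomial degree.
#' @param capacity Optional carrying-capacity value to use instead of
#'   the last sample mean.
#' @param plateau_tol Relative plateau guard (default 0.02).
#' @return List with `eta` and `beta` (length `p`).
#' @export
initial_theta_guess <- function(panel, p, capacity = NULL, plateau_tol = 0.02) {
  sm <- sample_moments(panel)
  mN <- if (is.null(capacity)) sm$m[nrow(sm)] else capacity
  keep <- sm$m < mN & (mN / sm$m - 1) > plateau_tol
  keep[nrow(sm)] <- FALSE
  if (sum(keep) < p + 2L) {
    rlang::abort(sprintf(
      "Only %d usable time points after dropping the plateau; need >= %d for degree %d.",
      sum(keep), p + 2L, p), class = "msl_insufficient_data")
  }
  tj <- sm$time[keep]
  y <- -log(mN / sm$m[keep] - 1)
  Xm <- outer(tj, seq_len(p), "^")
  fit <- stats::lm.fit(cbind(1, Xm), y)
  co <- unname(fit$coefficients)
  list(eta = exp(co[1L]), beta = co[-1L])
}

#' Regression-based initial solution for sigma2
#'
#' For a lognormal cross-section, `2 log(m_j / m_j^g)` estimates the
#' log-scale variance `sigma0^2 + sigma^2 (t_j - t0)`; a simple linear
#' regression through the origin of `sigma_j^2 - sigma0^2` on
#' `t_j - t0` therefore estimates `sigma^2`. A negative slope is
#' clipped to `floor`.
#'
#' @param panel A panel data frame.
#' @param sigma0sq Initial-law log-variance; defaults to the
#'   [alpha_mle()] estimate `sigma1sq_hat` (0 for a common start value).
#' @param floor Lower clip for the returned value.
#' @return Positive scalar.
#' @export
initial_sigma2_guess <- function(panel, sigma0sq = NULL, floor = 1e-8) {
  sm <- sample_moments(panel)
  if (is.null(sigma0sq)) sigma0sq <- unname(alpha_mle(panel)["sigma1sq"])
  tt <- sm$time - sm$time[1L]
  slope <- sum((sm$s2 - sigma0sq) * tt) / sum(tt^2)
  max(slope, floor)
}

new_msl_fit <- function(method, p, eta, beta, sigma2, vs,
                        converged, iterations, residual_norm,
                        initial = NULL, extra = NULL) {
  a <- alpha_mle(vs)
  rll <- rll_raw(vs, eta, beta, sigma2)
  ll <- if (a["sigma1sq"] > 0) {
    lv0 <- log(vs$v0)
    rll - (vs$n + vs$d) / 2 * log(2 * pi) - vs$d / 2 * log(a["sigma1sq"]) -
      sum(lv0) - sum((lv0 - a["mu1"])^2) / (2 * a["sigma1sq"])
  } else {
    # degenerate initial law: only the transition factors have a density
    rll - vs$n / 2 * log(2 * pi)
  }
  structure(list(
    method = method, p = p,
    eta = eta, beta = beta, sigma2 = sigma2,
    mu1 = unname(a["mu1"]), sigma1sq = unname(a["sigma1sq"]),
    loglik = unname(ll), reduced_loglik = unname(rll),
    converged = converged, iterations = iterations,
    residual_norm = residual_norm,
    n = vs$n, d = vs$d, t0 = vs$t0,
    initial = initial, extra = extra), class = "msl_fit")
}

#' @export
print.msl_fit <- function(x, ...) {
  cat(sprintf("<msl_fit> %s fit, degree p = %d (%s, %d iterations)\n",
              x$method, x$p, if (x$converged) "converged" else "NOT converged",
              x$iterations))
  cat("  eta    =", format(x$eta), "\n")
  cat("  beta   =", paste(format(x$beta), collapse = ", "), "\n")
  cat("  sigma2 =", format(x$sigma2), " (sigma =", format(sqrt(x$sigma2)), ")\n")
  cat("  mu1    =", format(x$mu1), " sigma1sq =", format(x$sigma1sq), "\n")
  cat("  logLik =", format(x$loglik),
      " residual =", format(x$residual_norm), "\n")
  invisible(x)
}

# coerce a fit (or params) to msl_params; fitted beta_p can be <= 0 for
# misspecified degrees, in which case downstream curve functions still
# work but no finite carrying capacity exists -- bypass validation.
fit_params <- function(fit) {
  if (inherits(fit, "msl_params")) return(fit)
  structure(list(eta = fit$eta, beta = fit$beta, sigma2 = fit$sigma2,
                 p = length(fit$beta)), class = "msl_params")
}

#' Maximum likelihood fit by Newton-Raphson
#'
#' Solves the `p + 2` likelihood equations (see [system_residuals()])
#' with a damped Newton iteration started at the regression-based
#' initial solutions. The Jacobian is computed by central finite
#' differences; steps are halved (up to 50 times) until the residual
#' norm decreases and the parameters stay admissible. Convergence is
#' declared when the sup-norm of the residual falls below `tol` or the
#' step below `1e-12`. Non-convergence is reported, never silent: the
#' returned fit carries `converged = FALSE` and the last iterate.
#'
#' @param panel A panel data frame (or `msl_vstats`).
#' @param p Polynomial degree.
#' @param init Optional named list/vector with starting values `eta`,
#'   `beta`, `sigma2`; defaults to [initial_theta_guess()] and
#'   [initial_sigma2_guess()].
#' @param profile_sigma2 When `TRUE`, `sigma2` is refreshed each
#'   iteration from its Remark-1 closed form [sigma2_given_theta()] and
#'   Newton runs on the remaining `p + 1` equations.
#' @param tol Residual sup-norm tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `"msl_fit"`; see also [tidy.msl_fit()]
#'   and [glance.msl_fit()].
#' @examples
#' panel <- make_case_panel(1, n_paths = 20, n_times = 101, seed = 1)
#' fit_newton_raphson(panel, p = 3)
#' @export
fit_newton_raphson <- function(panel, p, init = NULL, profile_sigma2 = FALSE,
                               tol = 1e-10, max_iter = 200L) {
  vs <- v_transform(panel)
  if (is.null(init)) {
    th0 <- initial_theta_guess(panel, p)
    s20 <- initial_sigma2_guess(panel)
    xi <- c(th0$eta, th0$beta, s20)
  } else {
    xi <- c(init$eta, init$beta, init$sigma2)
    stopifnot(length(xi) == p + 2L)
  }
  initial <- xi
  fvec <- function(z) {
    if (profile_sigma2) {
      s2 <- max(sigma2_given_theta(vs, list(z[1L], z[2:(p + 1L)])), 1e-12)
      resid_raw(vs, z[1L], z[2:(p + 1L)], s2)[-1L]
    } else {
      resid_raw(vs, z[1L], z[2:(p + 1L)], z[p + 2L])
    }
  }
  npar <- if (profile_sigma2) p + 1L else p + 2L
  z <- xi[seq_len(npar)]
  Fz <- fvec(z)
  nf <- max(abs(Fz))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    if (!all(is.finite(Fz))) break
    if (nf < tol) { converged <- TRUE; break }
    J <- matrix(0, length(Fz), npar)
    for (k in seq_len(npar)) {
      h <- 1e-6 * max(abs(z[k]), 1e-8)
      zp <- z; zm <- z
      zp[k] <- z[k] + h; zm[k] <- z[k] - h
      J[, k] <- (fvec(zp) - fvec(zm)) / (2 * h)
    }
    step <- tryCatch(solve(J, -Fz), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    lam <- 1
    accepted <- FALSE
    for (half in 1:50) {
      zn <- z + lam * step
      ok <- zn[1L] > 0 && (profile_sigma2 || zn[npar] > 0)
      if (ok) {
        Fn <- fvec(zn)
        if (all(is.finite(Fn)) && max(abs(Fn)) < nf) {
          accepted <- TRUE
          break
        }
      }
      lam <- lam / 2
    }
    if (!accepted) break
    moved <- max(abs(zn - z))
    z <- zn; Fz <- Fn; nf <- max(abs(Fn))
    if (moved < 1e-12) { converged <- nf < sqrt(tol); break }
  }
  if (profile_sigma2) {
    eta <- z[1L]; beta <- z[2:(p + 1L)]
    s2 <- max(sigma2_given_theta(vs, list(eta, beta)), 1e-12)
  } else {
    eta <- z[1L]; beta <- z[2:(p + 1L)]; s2 <- z[p + 2L]
  }
  new_msl_fit("newton", p, eta, beta, s2, vs,
              converged = converged, iterations = it, residual_norm = nf,
              initial = initial)
}
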