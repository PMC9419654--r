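# First-passage-time density through a constant boundary.
#
# For a degenerate start, log X(t) = log x0 + H(t0, t) + sigma W(t), so
# the first passage of X through the constant level S coincides with the
# first passage of a standard Wiener process through the moving boundary
# b(u) = [log(S/x0) - H(t0, t0 + u)] / sigma on the clock u = t - t0.
# The FPT density then solves a second-kind Volterra equation with the
# classical Wiener kernel
#   Psi(b(t), t | y, tau) = 0.5 [b'(t) - (b(t) - y)/(t - tau)]
#                            phi((b(t) - y)/sqrt(t - tau)) / sqrt(t - tau),
# which is solved by the composite trapezoid recursion. The FPTL
# function localises where the FPT mass lives so that the quadratic-cost
# recursion runs on a short window.

wiener_boundary <- function(params, boundary) {
  list(
    b = function(u) (log(boundary$S / boundary$x0) -
                       H_xi(params, boundary$t0, boundary$t0 + u)) /
      sqrt(params$sigma2),
    bprime = function(u) -growth_rate(params, boundary$t0 + u) /
      sqrt(params$sigma2) + sqrt(params$sigma2) / 2)
}

#' First-passage-time location (FPTL) function
#'
#' `FPTL(t) = P[X(t) > S | X(t0) = x0] = 1 - Phi(C(t))` with
#' `C(t) = [log(S / x0) - H(t0, t) - sigma2 (t - t0)] / (sigma
#' sqrt(t - t0))` rearranged from the lognormal transition law. Its
#' growth interval localises the first-passage-time mass.
#'
#' @param params An [msl_params] object.
#' @param boundary A [boundary_spec()].
#' @param t Times strictly greater than `t0` (vectorised).
#' @return Probabilities in `[0, 1]`.
#' @export
fptl <- function(params, boundary, t) {
  stopifnot(inherits(params, "msl_params"), inherits(boundary, "msl_boundary"))
  if (any(t <= boundary$t0)) {
    rlang::abort("FPTL is defined for t > t0.", class = "msl_bad_times")
  }
  u <- t - boundary$t0
  Ct <- (log(boundary$S / boundary$x0) - H_xi(params, boundary$t0, t)) /
    sqrt(params$sigma2 * u)
  1 - stats::pnorm(Ct)
}

#' Locate the first-passage-time window
#'
#' Scans the FPTL function on a dense grid over `(t0, horizon]` and
#' returns the window carrying essentially all the FPT mass: from the
#' first time FPTL exceeds `eps` up to the first time after the FPTL
#' global maximum at which FPTL falls below `eps` times the maximum.
#' When FPTL never decays below that threshold inside the horizon
#' (typical when the boundary sits below the carrying capacity, so that
#' passage is essentially certain by the time FPTL peaks), the window is
#' closed one growth-interval width beyond the maximum,
#' `min(2 t_max - t_lower, horizon)`.
#'
#' @inheritParams fptl
#' @param horizon Upper end of the search interval.
#' @param eps Localisation threshold (default 1e-4).
#' @param grid_n Scan-grid size.
#' @return List with `t_lower`, `t_upper`, `t_max` (FPTL argmax),
#'   `fptl_max`.
#' @export
locate_fpt_window <- function(params, boundary, horizon, eps = 1e-4,
                              grid_n = 20000L) {
  stopifnot(inherits(params, "msl_params"), inherits(boundary, "msl_boundary"),
            horizon > boundary$t0)
  tt <- seq(boundary$t0, horizon, length.out = grid_n + 1L)[-1L]
  fv <- fptl(params, boundary, tt)
  if (!any(fv > eps)) {
    rlang::abort(
      paste0("FPTL never exceeds ", format(eps), " before the horizon: the ",
             "boundary is effectively unreachable (no passage)."),
      class = "msl_no_passage")
  }
  imax <- which.max(fv)
  t_lower <- tt[min(which(fv > eps))]
  t_max <- tt[imax]
  after <- which(tt > t_max & fv < eps * fv[imax])
  t_upper <- if (length(after)) tt[min(after)] else
    min(2 * t_max - t_lower, horizon)
  if (t_upper <= t_lower) t_upper <- min(t_lower + (t_max - boundary$t0), horizon)
  list(t_lower = t_lower, t_upper = t_upper, t_max = t_max,
       fptl_max = fv[imax])
}

#' Approximate the first-passage-time density
#'
#' Solves the second-kind Volterra integral equation for the FPT density
#' of the process through the constant boundary `S > x0` on a uniform
#' grid over the window located by [locate_fpt_window()], using the
#' composite trapezoid recursion (the integral below the window start is
#' neglected; the FPTL threshold makes it smaller than `eps`).
#'
#' @inheritParams locate_fpt_window
#' @param step Grid step; default window length / `n_grid`.
#' @param n_grid Default number of grid intervals (4000).
#' @param window Optional precomputed window (list with `t_lower`,
#'   `t_upper`), bypassing localisation.
#' @return An object of class `"msl_fpt"`: tibble `grid` with columns
#'   `time`, `density`, `cumulative`, plus `step`, `total_mass`,
#'   `window`, `params`, `boundary`.
#' @examples
#' p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
#' dens <- fpt_density(p, boundary_spec(15, 5), horizon = 100, n_grid = 500)
#' fpt_summaries(dens)
#' @export
fpt_density <- function(params, boundary, horizon, step = NULL,
                        n_grid = 4000L, eps = 1e-4, window = NULL) {
  stopifnot(inherits(params, "msl_params"), inherits(boundary, "msl_boundary"))
  if (is.null(window)) {
    window <- locate_fpt_window(params, boundary, horizon, eps = eps)
  }
  if (is.null(step)) step <- (window$t_upper - window$t_lower) / n_grid
  N <- max(2L, as.integer(ceiling((window$t_upper - window$t_lower) / step -
                                    1e-9)))
  wb <- wiener_boundary(params, boundary)
  u <- seq(window$t_lower, window$t_lower + N * step, by = step) - boundary$t0
  h <- step
  b <- wb$b(u)
  bp <- wb$bprime(u)
  # free-space term: Psi(u_k | y = 0, tau = 0), W(0) = 0
  psi0 <- 0.5 * (bp - b / u) * stats::dnorm(b / sqrt(u)) / sqrt(u)
  g <- numeric(N + 1L)
  g[1L] <- max(-2 * psi0[1L], 0)
  for (k in 2:(N + 1L)) {
    j <- 1:(k - 1L)
    dt <- u[k] - u[j]
    z <- (b[k] - b[j]) / sqrt(dt)
    psi <- 0.5 * (bp[k] - (b[k] - b[j]) / dt) * stats::dnorm(z) / sqrt(dt)
    w <- rep(1, k - 1L); w[1L] <- 0.5   # trapezoid; diagonal kernel term is 0
    g[k] <- -2 * psi0[k] + 2 * h * sum(w * g[j] * psi)
  }
  if (min(g) < -1e-9) {
    rlang::warn(paste0("Trapezoid recursion produced density values down to ",
                       format(min(g)), "; clipped to zero."))
  }
  g <- pmax(g, 0)
  cum <- c(0, cumsum((g[-1L] + g[-length(g)]) / 2) * h)
  mass <- cum[length(cum)]
  if (mass < 0.99) {
    rlang::warn(paste0("FPT density mass over the window is ", format(mass),
                       " < 0.99; refine the step or widen the horizon."))
  }
  structure(list(
    grid = tibble::tibble(time = u + boundary$t0, density = g, cumulative = cum),
    step = h, total_mass = mass, window = window,
    params = params, boundary = boundary), class = "msl_fpt")
}

#' @export
print.msl_fpt <- function(x, ...) {
  cat("<msl_fpt> first-passage-time density, S =", x$boundary$S, "\n")
  cat(sprintf("  window [%.4f, %.4f], step %.5g, total mass %.6f\n",
              x$window$t_lower, x$window$t_upper, x$step, x$total_mass))
  invisible(x)
}

#' Summaries of a first-passage-time density
#'
#' Mean and standard deviation by trapezoid moments of the normalised
#' density, mode by three-point parabolic interpolation around the grid
#' argmax, and deciles by linear interpolation of the normalised
#' cumulative. Requires total mass of at least `min_mass`.
#'
#' @param dens An `"msl_fpt"` object.
#' @param probs Quantile levels (default the 1st, 5th and 9th deciles).
#' @param min_mass Minimum admissible total mass (default 0.99).
#' @return A one-row tibble: `mean`, `sd`, `mode`, one column per
#'   quantile (`d10`, `d50`, `d90` by default), and `total_mass`.
#' @export
fpt_summaries <- function(dens, probs = c(0.1, 0.5, 0.9), min_mass = 0.99) {
  stopifnot(inherits(dens, "msl_fpt"))
  if (dens$total_mass < min_mass) {
    rlang::abort(paste0("Total mass ", format(dens$total_mass), " < ",
                        format(min_mass), "; summaries would be unreliable."),
                 class = "msl_low_mass")
  }
  tt <- dens$grid$time
  g <- dens$grid$density / dens$total_mass
  h <- dens$step
  trap <- function(y) sum((y[-1L] + y[-length(y)]) / 2) * h
  m1 <- trap(tt * g)
  m2 <- trap(tt^2 * g)
  i <- which.max(g)
  mode <- if (i > 1L && i < length(g)) {
    den <- g[i - 1L] - 2 * g[i] + g[i + 1L]
    if (den < 0) tt[i] + h * 0.5 * (g[i - 1L] - g[i + 1L]) / den else tt[i]
  } else tt[i]
  cum <- dens$grid$cumulative / dens$total_mass
  qs <- stats::approx(cum, tt, xout = probs, ties = "ordered")$y
  out <- tibble::tibble(mean = m1, sd = sqrt(max(m2 - m1^2, 0)), mode = mode)
  for (k in seq_along(probs)) out[[paste0("d", round(100 * probs[k]))]] <- qs[k]
  out$total_mass <- dens$total_mass
  out
}
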