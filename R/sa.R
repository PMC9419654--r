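# Simulated-annealing maximisation of the reduced log-likelihood over a
# data-driven bounded parameter box.

#' Simulated-annealing configuration
#'
#' Defaults follow common annealing practice for diffusion-process
#' likelihoods: initial acceptance probability 0.9, geometric cooling
#' with factor 0.95, chains of 50 moves per temperature, final
#' temperature 1e-7, at most 1000 temperature stages, and 10 independent
#' runs whose parameter estimates are averaged.
#'
#' @param p0 Initial acceptance probability in (0, 1).
#' @param gamma Cooling factor in (0, 1).
#' @param chain_length Moves per temperature stage.
#' @param t_final Stopping temperature.
#' @param max_iter Maximum number of temperature stages.
#' @param repeats Independent runs to average.
#' @param neighborhood_frac Proposal box half-width as a fraction of
#'   each parameter interval.
#' @param seed Integer master seed.
#' @return A list of class `"sa_config"`.
#' @export
sa_config <- function(p0 = 0.9, gamma = 0.95, chain_length = 50L,
                      t_final = 1e-7, max_iter = 1000L, repeats = 10L,
                      neighborhood_frac = 0.1, seed = 1L) {
  stopifnot(p0 > 0, p0 < 1, gamma > 0, gamma < 1, chain_length >= 1,
            repeats >= 1, neighborhood_frac > 0)
  structure(list(p0 = p0, gamma = gamma, chain_length = as.integer(chain_length),
                 t_final = t_final, max_iter = as.integer(max_iter),
                 repeats = as.integer(repeats),
                 neighborhood_frac = neighborhood_frac, seed = seed),
            class = "sa_config")
}

#' Data-driven bounds for the parameter space
#'
#' Simulated annealing needs a bounded solution space. The `eta`
#' interval comes from the per-path endpoint ratios
#' `(x_{i,n_i} / x_{i,1} - 1)^{-1}` (min and max over paths, widened by
#' a minimal pad when degenerate); the `beta` intervals are the
#' `level`-confidence intervals of the coefficients of the no-intercept
#' polynomial regression of `-log[(m_N / m_j - 1) eta_hat]` on
#' `(t_j, ..., t_j^p)` with `eta_hat = (m_N / m_1 - 1)^{-1}`; the
#' `sigma2` interval is `(0, sigma2_upper)`. Paths whose last value does
#' not exceed their first are excluded from the `eta` interval with a
#' warning. Plateau pairs (sample mean within `plateau_tol` of its final
#' value) are dropped from the regression, where the log response
#' degenerates.
#'
#' @param panel A panel data frame.
#' @param p Polynomial degree.
#' @param level Confidence level of the regression intervals.
#' @param sigma2_upper Upper endpoint of the `sigma2` interval.
#' @param plateau_tol Relative plateau guard (default 0.02).
#' @return A list of class `"msl_bounds"` with numeric vectors `lower`
#'   and `upper` of length `p + 2`, ordered `(eta, beta_1..beta_p,
#'   sigma2)`.
#' @export
parameter_bounds <- function(panel, p, level = 0.999, sigma2_upper = 0.01,
                             plateau_tol = 0.02) {
  panel <- as_msl_panel(panel)
  per_path <- dplyr::summarise(dplyr::group_by(panel, .data$path_id),
                               first = .data$value[1L],
                               last = .data$value[dplyr::n()],
                               .groups = "drop")
  grew <- per_path$last > per_path$first
  if (!any(grew)) {
    rlang::abort("No path grows from its first to its last value; the eta bound is undefined.",
                 class = "msl_bad_bounds")
  }
  if (!all(grew)) {
    rlang::warn(sprintf("%d path(s) with x_last <= x_first excluded from the eta bound.",
                        sum(!grew)))
  }
  inv_ratio <- 1 / (per_path$last[grew] / per_path$first[grew] - 1)
  a <- min(inv_ratio); b <- max(inv_ratio)
  if (b - a < 1e-8) { a <- a * (1 - 1e-3); b <- b * (1 + 1e-3) }

  sm <- sample_moments(panel)
  mN <- sm$m[nrow(sm)]
  eta_hat <- 1 / (mN / sm$m[1L] - 1)
  keep <- sm$m < mN & (mN / sm$m - 1) > plateau_tol
  keep[nrow(sm)] <- FALSE
  if (sum(keep) < p + 2L) {
    rlang::abort("Too few usable time points for the beta bounds regression.",
                 class = "msl_bad_bounds")
  }
  tj <- sm$time[keep]
  y <- -log((mN / sm$m[keep] - 1) * eta_hat)
  Xm <- outer(tj, seq_len(p), "^")
  colnames(Xm) <- paste0("T", seq_len(p))
  df <- data.frame(y = y, Xm)
  reg <- stats::lm(y ~ . - 1, data = df)
  ci <- stats::confint(reg, level = level)
  structure(list(lower = unname(c(a, ci[, 1L], 1e-10)),
                 upper = unname(c(b, ci[, 2L], sigma2_upper)),
                 names = c("eta", paste0("beta_", seq_len(p)), "sigma2")),
            class = "msl_bounds")
}

#' @export
print.msl_bounds <- function(x, ...) {
  cat("<msl_bounds>\n")
  print(tibble::tibble(parameter = x$names, lower = x$lower, upper = x$upper))
  invisible(x)
}

#' Initial temperature from a pilot walk
#'
#' Runs a short accept-everything random walk inside the bounds and sets
#' `T0 = -mean(positive increments of the objective) / log(p0)` so that
#' uphill moves of typical size are initially accepted with probability
#' about `p0`. When no pilot move increases the objective, a fallback
#' scale based on the objective magnitude is used (with a warning).
#'
#' @param objective Function of the parameter vector, to be minimised.
#' @param bounds An `"msl_bounds"` object.
#' @param config An [sa_config()].
#' @param n_pilot Number of pilot proposals.
#' @return Positive scalar temperature.
#' @export
initial_temperature <- function(objective, bounds, config = sa_config(),
                                n_pilot = 100L) {
  lo <- bounds$lower; up <- bounds$upper
  w <- config$neighborhood_frac * (up - lo)
  x <- stats::runif(length(lo), lo, up)
  fx <- objective(x)
  inc <- numeric(0)
  for (i in seq_len(n_pilot)) {
    xn <- pmin(pmax(x + stats::runif(length(lo), -w, w), lo), up)
    fn <- objective(xn)
    if (is.finite(fn) && is.finite(fx) && fn > fx) inc <- c(inc, fn - fx)
    x <- xn; fx <- fn
  }
  if (length(inc)) {
    -mean(inc) / log(config$p0)
  } else {
    rlang::warn("No increasing pilot move; falling back to |objective|-based T0.")
    max(abs(fx), 1) * 0.1
  }
}

sa_single_run <- function(vs, p, bounds, config, seed) {
  set.seed(seed)
  lo <- bounds$lower; up <- bounds$upper
  w <- config$neighborhood_frac * (up - lo)
  obj <- function(z) -rll_raw(vs, z[1L], z[2:(p + 1L)], z[p + 2L])
  T0 <- initial_temperature(obj, bounds, config)
  x <- stats::runif(p + 2L, lo, up)
  fx <- obj(x)
  best <- x; fbest <- fx
  temp <- T0
  stage <- 0L
  acc_rates <- numeric(0)
  stopped <- "t_final"
  while (temp > config$t_final) {
    stage <- stage + 1L
    if (stage > config$max_iter) { stopped <- "max_iter"; break }
    accepted <- numeric(0)
    for (i in seq_len(config$chain_length)) {
      xn <- pmin(pmax(x + stats::runif(p + 2L, -w, w), lo), up)
      fn <- obj(xn)
      if (fn <= fx || stats::runif(1) < exp(-(fn - fx) / temp)) {
        x <- xn; fx <- fn
        accepted <- c(accepted, fx)
        if (fx < fbest) { best <- x; fbest <- fx }
      }
    }
    acc_rates <- c(acc_rates, length(accepted) / config$chain_length)
    if (length(accepted) >= config$chain_length &&
        max(accepted) - min(accepted) < 1e-12) {
      stopped <- "stalled"
      break
    }
    temp <- config$gamma * temp
  }
  list(xi = best, objective = fbest, stages = stage, T0 = T0,
       stopped = stopped, acceptance = acc_rates)
}

#' Maximum likelihood fit by simulated annealing
#'
#' Minimises the negative reduced log-likelihood over the bounded
#' parameter space of [parameter_bounds()] with geometric cooling and
#' the Metropolis acceptance rule `min(exp(-df / T), 1)`. Proposals are
#' uniform in a box around the current point, clipped to the bounds.
#' The procedure runs `config$repeats` independent chains and returns
#' the average of the per-run parameter estimates (`best_of = TRUE`
#' returns the run with the best objective instead). An optional single
#' Newton polish of the averaged estimate is available.
#'
#' @param panel A panel data frame (or `msl_vstats`).
#' @param p Polynomial degree.
#' @param config An [sa_config()].
#' @param bounds Optional `"msl_bounds"`; computed from the panel by
#'   default.
#' @param best_of Return the best run instead of the average.
#' @param polish Apply one damped-Newton refinement to the result.
#' @return An `"msl_fit"` (method `"sa"`); `$extra` carries the
#'   per-run estimates, objectives and acceptance-rate traces.
#' @export
fit_simulated_annealing <- function(panel, p, config = sa_config(),
                                    bounds = NULL, best_of = FALSE,
                                    polish = FALSE) {
  vs <- v_transform(panel)
  if (is.null(bounds)) bounds <- parameter_bounds(panel, p)
  runs <- purrr::map(seq_len(config$repeats), function(r) {
    sa_single_run(vs, p, bounds, config,
                  seed = path_seed(config$seed, 7919L + r))
  })
  ximat <- do.call(rbind, purrr::map(runs, "xi"))
  objs <- purrr::map_dbl(runs, "objective")
  xi <- if (best_of) ximat[which.min(objs), ] else colMeans(ximat)
  if (polish) {
    pol <- fit_newton_raphson(vs, p,
                              init = list(eta = xi[1L], beta = xi[2:(p + 1L)],
                                          sigma2 = xi[p + 2L]),
                              max_iter = 1L)
    xi <- c(pol$eta, pol$beta, pol$sigma2)
    xi <- pmin(pmax(xi, bounds$lower), bounds$upper)
  }
  new_msl_fit("sa", p, xi[1L], xi[2:(p + 1L)], xi[p + 2L], vs,
              converged = TRUE, iterations = sum(purrr::map_int(runs, "stages")),
              residual_norm = max(abs(resid_raw(vs, xi[1L], xi[2:(p + 1L)],
                                                xi[p + 2L]))),
              extra = list(bounds = bounds, runs = ximat, objectives = objs,
                           acceptance = purrr::map(runs, "acceptance"),
                           stopped = purrr::map_chr(runs, "stopped")))
}
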