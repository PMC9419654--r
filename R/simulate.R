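# Exact path simulation and the simulation-study parameter grid.

# Deterministic per-path seed stream from one master seed so that the
# panel is reproducible independently of path ordering or chunking.
path_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 48271 + i * 16807) %% 2147483647)
}

#' Simulate sample paths of the diffusion
#'
#' Draws `n_paths` independent trajectories on the grid `times` by exact
#' lognormal transition sampling: `X(t_{j+1}) = X(t_j) exp(H(t_j, t_{j+1})
#' + sigma sqrt(dt) Z)`. No Euler discretisation bias is introduced. The
#' same `(params, init, times, n_paths, seed)` reproduce the identical
#' panel.
#'
#' @param params An [msl_params] object.
#' @param init An initial law from [msl_init_degenerate()] or
#'   [msl_init_lognormal()].
#' @param times Strictly increasing numeric grid; `times[1]` is `t0`.
#' @param n_paths Number of independent trajectories.
#' @param seed Integer master seed; each path uses its own substream.
#' @return A tibble with columns `path_id`, `time`, `value` (a "panel",
#'   the long format used by every fitting function in the package).
#' @examples
#' p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
#' simulate_paths(p, msl_init_degenerate(5), seq(0, 50, 0.5), 3, seed = 1)
#' @export
simulate_paths <- function(params, init, times, n_paths, seed) {
  stopifnot(inherits(params, "msl_params"), inherits(init, "msl_init"),
            n_paths >= 1)
  if (length(times) < 2L || any(diff(times) <= 0)) {
    rlang::abort("`times` must be strictly increasing with at least 2 points.",
                 class = "msl_bad_grid")
  }
  dt <- diff(times)
  dH <- H_xi(params, times[-length(times)], times[-1L])
  sd_step <- sqrt(params$sigma2 * dt)
  paths <- purrr::map(seq_len(n_paths), function(i) {
    set.seed(path_seed(seed, i))
    lx0 <- if (init$kind == "degenerate") init$mu0 else
      stats::rnorm(1L, init$mu0, sqrt(init$sigma0sq))
    z <- stats::rnorm(length(dt), 0, sd_step)
    exp(c(lx0, lx0 + cumsum(dH + z)))
  })
  tibble::tibble(
    path_id = rep(seq_len(n_paths), each = length(times)),
    time = rep(as.numeric(times), times = n_paths),
    value = unlist(paths, use.names = FALSE))
}

#' Parameter grid of the simulation study
#'
#' The 32 parameter combinations crossing `beta_1 in {0.1, 0.5}`,
#' `beta_2 in {-0.009, -0.007}`, `beta_3 in {0.0002, 0.0003}`,
#' `eta in {exp(-1), exp(-3)}` and `sigma in {0.01, 0.05}`, with
#' `x0 = 5`; `case_params()` returns one row as parameters,
#' `make_case_panel()` simulates the corresponding panel on an
#' equidistant grid over \[0, 50\] (defaults: 200 paths, 501 points).
#'
#' @param case Integer case number, 1 to 32.
#' @return `case_params()`: list with `params` ([msl_params]) and `x0`.
#' @export
case_params <- function(case) {
  if (!(is.numeric(case) && length(case) == 1L && case %in% 1:32)) {
    rlang::abort("`case` must be an integer in 1..32.", class = "msl_bad_case")
  }
  case <- as.integer(case)
  k <- case - 1L
  beta1 <- c(0.1, 0.5)[k %/% 16L + 1L]
  beta2 <- c(-0.009, -0.007)[(k %% 16L) %/% 8L + 1L]
  beta3 <- c(2e-4, 3e-4)[(k %% 8L) %/% 4L + 1L]
  eta <- c(exp(-1), exp(-3))[(k %% 4L) %/% 2L + 1L]
  sigma <- c(0.01, 0.05)[k %% 2L + 1L]
  list(params = msl_params(eta, c(beta1, beta2, beta3), sigma^2), x0 = 5)
}

#' @rdname case_params
#' @param n_paths,n_times Panel dimensions (defaults are the study design).
#' @param seed Master seed passed to [simulate_paths()].
#' @return `make_case_panel()`: a panel tibble.
#' @export
make_case_panel <- function(case, n_paths = 200L, n_times = 501L, seed = 1L) {
  cp <- case_params(case)
  simulate_paths(cp$params, msl_init_degenerate(cp$x0),
                 seq(0, 50, length.out = n_times), n_paths, seed)
}
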