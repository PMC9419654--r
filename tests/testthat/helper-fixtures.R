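# Shared fixtures, generated once per test run.

.fx <- new.env()

example1_params <- function() msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
example1_boundary <- function() boundary_spec(15, 5, 0)

# scaled-down case-1 study panel: 50 paths x 201 equidistant points
case1_panel_small <- function() {
  if (is.null(.fx$p50)) .fx$p50 <- make_case_panel(1, 50, 201, seed = 101)
  .fx$p50
}

# tiny generic panel for exact-identity checks
tiny_panel <- function() {
  if (is.null(.fx$tiny)) {
    .fx$tiny <- simulate_paths(example1_params(),
                               msl_init_lognormal(log(5), 0.02),
                               times = c(0, 2, 5, 10, 17, 26, 40),
                               n_paths = 4, seed = 5)
  }
  .fx$tiny
}

# Example-1 FPT density at the default resolution (used by several tests)
example1_density <- function() {
  if (is.null(.fx$dens)) {
    .fx$dens <- fpt_density(example1_params(), example1_boundary(), horizon = 100)
  }
  .fx$dens
}

# Monte-Carlo first-passage oracle: simulates log X on a fine grid by
# chaining exact Gaussian increments and records the first up-crossing
# of S per path. Independent of the Volterra solver.
mc_fpt_times <- function(params, boundary, step, horizon, n_paths, seed,
                         chunk = 1000L) {
  tt <- seq(boundary$t0, horizon, by = step)
  n <- length(tt)
  dH <- H_xi(params, tt[-n], tt[-1L])
  sd_step <- sqrt(params$sigma2 * step)
  logS <- log(boundary$S / boundary$x0)
  set.seed(seed)
  out <- numeric(0)
  n_surv <- 0L
  remaining <- n_paths
  while (remaining > 0L) {
    np <- min(chunk, remaining)
    Z <- matrix(stats::rnorm(np * (n - 1L), sd = sd_step), np, n - 1L)
    L <- t(apply(sweep(Z, 2L, dH, "+"), 1L, cumsum))
    idx <- apply(L >= logS, 1L, function(r) {
      w <- which(r); if (length(w)) w[1L] else NA_integer_
    })
    n_surv <- n_surv + sum(is.na(idx))
    out <- c(out, tt[idx[!is.na(idx)] + 1L])
    remaining <- remaining - np
  }
  list(times = out, n_no_cross = n_surv)
}
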