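# Likelihood machinery: V-transform, blocks, identities, score system.

test_that("V-transform computes the scaled log increments and Z statistics", {
  # constant path: all increments vanish
  flat <- tibble::tibble(path_id = 1, time = 0:5, value = 7)
  vs <- v_transform(flat)
  expect_equal(vs$Z1, 0)
  expect_equal(vs$Z2, 0)
  expect_equal(vs$Z3, 5)
  # two-point path (x, x e) over dt = 4: v = 1/2
  two <- tibble::tibble(path_id = 1, time = c(0, 4), value = c(3, 3 * exp(1)))
  vs2 <- v_transform(two)
  expect_equal(vs2$steps$sum_v, 0.5)
  expect_equal(vs2$Z1, 0.25)
  # one path observed over [0, 50]: Z3 is the elapsed time
  p50 <- simulate_paths(example1_params(), msl_init_degenerate(5),
                        seq(0, 50, length.out = 11), 1, seed = 1)
  expect_equal(v_transform(p50)$Z3, 50)
  expect_equal(v_transform(p50)$n, 10)
})

test_that("initial-law MLE has the closed form with divisor d", {
  const <- tibble::tibble(path_id = rep(1:3, each = 2),
                          time = rep(c(0, 1), 3), value = rep(c(4, 5), 3))
  a <- alpha_mle(const)
  expect_equal(unname(a), c(log(4), 0))
  two <- tibble::tibble(path_id = rep(1:2, each = 2), time = rep(c(0, 1), 2),
                        value = c(1, 2, exp(2), 2))
  a2 <- alpha_mle(two)
  expect_equal(unname(a2), c(1, 1))  # v0 = (1, e^2)
  one <- tibble::tibble(path_id = 1, time = c(0, 1), value = c(3, 4))
  expect_equal(unname(alpha_mle(one)["sigma1sq"]), 0)
})

test_that("block identities hold for every sigma2", {
  panel <- tiny_panel()
  set.seed(31)
  for (k in 1:5) {
    th <- list(eta = exp(stats::runif(1, -3, 0)),
               beta = c(stats::runif(1, 0.05, 0.5), stats::runif(1, -0.01, 0),
                        stats::runif(1, 1e-4, 5e-4)))
    s2 <- stats::runif(1, 1e-5, 1e-2)
    bl <- likelihood_blocks(panel, th, sigma2 = s2)
    expect_equal(bl$Phi, bl$A + s2^2 / 4 * bl$Z3 - s2 * bl$C, tolerance = 1e-10)
    expect_equal(bl$Gamma, bl$B - s2 / 2 * bl$Z2, tolerance = 1e-10)
    expect_equal(bl$Yxi, bl$C - s2 / 2 * bl$Z3, tolerance = 1e-10)
  }
})

test_that("the quadratic-form identity of the variance equation holds", {
  panel <- tiny_panel()
  vs <- v_transform(panel)
  th <- list(eta = 0.4, beta = c(0.09, -0.008, 0.00022))
  bl <- likelihood_blocks(panel, th)
  # Z1 + A - 2B = sum over steps of (v - lambda/sqrt(dt))^2, term by term
  st <- vs$steps
  direct <- sum(st$sum_v2 - 2 * st$sum_v * bl$lambda / sqrt(st$delta) +
                  st$count * bl$lambda^2 / st$delta)
  expect_equal(vs$Z1 + bl$A - 2 * bl$B, direct, tolerance = 1e-12)
  expect_gte(direct, 0)
})

test_that("log-likelihood equals the sum of log transition densities", {
  panel <- tiny_panel()
  p <- msl_params(0.35, c(0.11, -0.0085, 0.00019), 2e-4)
  a <- alpha_mle(panel)
  ll <- log_likelihood(panel, a, p)
  # oracle: initial lognormal factors + exact lognormal transition pdfs,
  # mapped to the V scale through the change-of-variables Jacobian
  wide <- tidyr::pivot_wider(panel, names_from = "path_id", values_from = "value")
  tt <- wide$time
  oracle <- 0
  jac <- 0
  for (i in 2:ncol(wide)) {
    x <- wide[[i]]
    oracle <- oracle + stats::dlnorm(x[1], a[1], sqrt(a[2]), log = TRUE)
    for (j in seq_len(length(tt) - 1L)) {
      law <- transition_law(p, x[j], tt[j], tt[j + 1])
      oracle <- oracle + stats::dlnorm(x[j + 1], law$mu, sqrt(law$s2), log = TRUE)
      jac <- jac + log(x[j + 1]) + 0.5 * log(tt[j + 1] - tt[j])
    }
  }
  expect_equal(ll, oracle + jac, tolerance = 1e-10)
  # invariant under path relabelling
  shuffled <- dplyr::mutate(panel, path_id = 5 - path_id)
  expect_equal(log_likelihood(shuffled, a, p), ll, tolerance = 1e-12)
  expect_error(log_likelihood(panel, c(0, 0), p), class = "msl_bad_alpha")
})

test_that("the likelihood is maximised over alpha at the closed-form MLE", {
  panel <- tiny_panel()
  p <- msl_params(0.35, c(0.11, -0.0085, 0.00019), 2e-4)
  a <- alpha_mle(panel)
  base <- log_likelihood(panel, a, p)
  for (dmu in c(-0.05, 0.05)) {
    expect_lt(log_likelihood(panel, a + c(dmu, 0), p), base)
  }
  for (ds in c(-0.3, 0.5)) {
    expect_lt(log_likelihood(panel, a * c(1, 1 + ds), p), base)
  }
})

test_that("sigma2_given_theta solves the first likelihood equation", {
  panel <- tiny_panel()
  th <- list(eta = 0.4, beta = c(0.09, -0.008, 0.00022))
  s2 <- sigma2_given_theta(panel, th)
  expect_gte(s2, 0)
  r <- system_residuals(panel, msl_params(th$eta, th$beta, s2))
  expect_lt(abs(r[1]), 1e-12 * max(1, abs(v_transform(panel)$Z1)))
  # perfect fit: a noiseless panel built from the curve itself
  tt <- seq(0, 40, length.out = 9)
  p <- msl_params(0.4, c(0.09, -0.008, 0.00022), 1e-30)
  det_panel <- tibble::tibble(path_id = 1, time = tt,
                              value = msl_curve(p, 5, 0, tt))
  expect_equal(sigma2_given_theta(det_panel, th), 0, tolerance = 1e-8)
})

test_that("score residuals match the gradient of the reduced likelihood", {
  panel <- tiny_panel()
  vs <- v_transform(panel)
  p <- msl_params(0.35, c(0.11, -0.0085, 0.00019), 2e-4)
  r <- system_residuals(panel, p)
  xi <- c(p$eta, p$beta, p$sigma2)
  fd <- vapply(seq_along(xi), function(k) {
    h <- 1e-5 * abs(xi[k])
    xp <- xi; xm <- xi
    xp[k] <- xi[k] + h; xm[k] <- xi[k] - h
    (reduced_log_likelihood(panel, msl_params(xp[1], xp[2:4], xp[5])) -
       reduced_log_likelihood(panel, msl_params(xm[1], xm[2:4], xm[5]))) / (2 * h)
  }, numeric(1))
  # dL/deta = r_0 / s2, dL/dbeta_l = -r_l / s2, dL/dsigma2 = -r_1 / (2 s2^2)
  expect_equal(fd[1], r[2] / p$sigma2, tolerance = 1e-5)
  expect_equal(fd[2:4], -r[3:5] / p$sigma2, tolerance = 1e-5)
  expect_equal(fd[5], -r[1] / (2 * p$sigma2^2), tolerance = 1e-5)
})

test_that("residuals stay finite over the bounded parameter box", {
  panel <- case1_panel_small()
  bd <- parameter_bounds(panel, 3)
  set.seed(17)
  for (k in 1:20) {
    xi <- stats::runif(5, bd$lower, bd$upper)
    r <- system_residuals(panel, msl_params(xi[1], xi[2:4], xi[5]))
    expect_true(all(is.finite(r)))
  }
})
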