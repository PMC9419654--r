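# Goodness-of-fit measures and degree selection.

fake_fit <- function(eta = exp(-1), beta = c(0.1, -0.009, 0.0002),
                     sigma2 = 1e-4, mu1 = log(5), sigma1sq = 0,
                     loglik = 0, n = 100) {
  structure(list(method = "newton", p = length(beta), eta = eta, beta = beta,
                 sigma2 = sigma2, mu1 = mu1, sigma1sq = sigma1sq,
                 loglik = loglik, reduced_loglik = loglik, converged = TRUE,
                 iterations = 0L, residual_norm = 0, n = n, d = 1, t0 = 0,
                 initial = NULL, extra = NULL), class = "msl_fit")
}

test_that("RAE is the mean absolute relative error of the mean curve", {
  # single time point: m = 10 vs fitted initial mean 11 -> 0.1
  panel <- tibble::tibble(path_id = 1, time = 0, value = 10)
  fit <- fake_fit(mu1 = log(11))
  expect_equal(rae(panel, fit), 0.1)
  # a fit whose mean reproduces the sample mean exactly gives zero
  p <- example1_params()
  tt <- seq(0, 50, length.out = 21)
  exact <- tibble::tibble(path_id = 1, time = tt, value = msl_curve(p, 5, 0, tt))
  expect_equal(rae(exact, fake_fit()), 0, tolerance = 1e-12)
})

test_that("RAE grows with the diffusion noise across matched panels", {
  raes <- purrr::map_dbl(c(1, 2), function(case) {
    panel <- make_case_panel(case, n_paths = 50, n_times = 101, seed = 13)
    rae(panel, fit_newton_raphson(panel, 3))
  })
  expect_lt(raes[1], raes[2])  # sigma 0.01 vs 0.05
})

test_that("information criteria follow their formulas", {
  f <- fake_fit(loglik = 0, n = 100)
  expect_equal(aic(f), 10)
  expect_equal(bic(f), 5 * log(100))
  expect_equal(bic(f), 23.02585, tolerance = 1e-6)
  expect_equal(aic(f) - bic(f), 5 * (2 - log(100)))
})

test_that("KL divergence between lognormal laws matches quadrature", {
  a <- lognormal_law(1, 1)
  expect_equal(kl_lognormal(a, a), 0)
  b <- lognormal_law(1, exp(1))
  expect_equal(kl_lognormal(a, b), 1 / (2 * exp(1)), tolerance = 1e-12)
  set.seed(5)
  for (k in 1:4) {
    la <- lognormal_law(stats::rnorm(1), stats::runif(1, 0.2, 2))
    lb <- lognormal_law(stats::rnorm(1), stats::runif(1, 0.2, 2))
    quad <- stats::integrate(function(x) {
      fa <- stats::dlnorm(x, la$mu, sqrt(la$s2))
      fa * (stats::dlnorm(x, la$mu, sqrt(la$s2), log = TRUE) -
              stats::dlnorm(x, lb$mu, sqrt(lb$s2), log = TRUE))
    }, 0, Inf, rel.tol = 1e-10)$value
    kl <- kl_lognormal(la, lb)
    expect_equal(kl, quad, tolerance = 1e-6)
    expect_gte(kl, 0)
  }
})

test_that("resistor-average distance is the harmonic mean of divergences", {
  a <- lognormal_law(0, 1)
  expect_equal(resistor_average(a, a), 0)  # 0/0 convention
  # symmetric pair: both divergences equal (mu difference with same s2)
  b <- lognormal_law(sqrt(2), 1)           # D_KL = 1 both ways
  expect_equal(kl_lognormal(a, b), 1)
  expect_equal(resistor_average(a, b), 0.5)
  c2 <- lognormal_law(0.4, 2.5)
  expect_lte(resistor_average(a, c2),
             min(kl_lognormal(a, c2), kl_lognormal(c2, a)))
})

test_that("the distance curve vanishes for the generating parameters", {
  panel <- make_case_panel(1, n_paths = 200, n_times = 101, seed = 19)
  fit <- fake_fit()  # the truth, with the degenerate initial law
  dra <- ra_distance_curve(panel, fit)
  expect_true(all(dra$curve$d_ra >= 0))
  expect_lt(dra$median, 0.02)
  dra_th <- ra_distance_curve(panel, fit_newton_raphson(panel, 3),
                              reference = "theoretical",
                              params = example1_params(),
                              init = msl_init_degenerate(5))
  expect_lt(dra_th$median, 0.05)
})

test_that("degree selection tabulates all degrees and picks the cubic", {
  panel <- make_case_panel(1, n_paths = 100, n_times = 251, seed = 3)
  rep <- select_degree(panel, 2, 6)
  expect_equal(rep$measures$degree, 2:6)
  expect_equal(nrow(rep$measures), 5)
  expect_equal(rep$chosen, 3)
  expect_true(rep$measures$chosen[rep$measures$degree == 3])
  # single-degree range returns that degree
  rep1 <- select_degree(panel, 4, 4)
  expect_equal(rep1$chosen, 4)
  # tidyverse surface
  expect_s3_class(autoplot(rep), "ggplot")
})
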