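# Deterministic curve machinery: polynomial, growth rate, logistic
# curve, carrying capacity, inflection points.

beta1 <- c(0.1, -0.009, 0.0002)

test_that("poly_Q and poly_P match direct arithmetic and each other", {
  expect_identical(poly_Q(beta1, 0), 0)
  expect_equal(poly_Q(beta1, 10), 0.3)
  expect_equal(poly_Q(beta1, 50), 7.5)
  expect_equal(poly_P(beta1, 0), 0.1)
  expect_equal(poly_P(beta1, 10), -0.02)
  # central-difference oracle for the derivative
  for (t in c(-3, 0.7, 12, 41)) {
    h <- 1e-5
    fd <- (poly_Q(beta1, t + h) - poly_Q(beta1, t - h)) / (2 * h)
    expect_equal(poly_P(beta1, t), fd, tolerance = 1e-6)
  }
})

test_that("parameter containers enforce their invariants", {
  expect_error(msl_params(-1, beta1, 1e-4), class = "msl_bad_params")
  expect_error(msl_params(1, beta1, 0), class = "msl_bad_params")
  expect_error(msl_params(1, c(0.1, -0.2), 1e-4), class = "msl_bad_params")
  expect_error(msl_init_degenerate(-2), class = "msl_bad_init")
  expect_error(msl_init_lognormal(0, 0), class = "msl_bad_init")
  expect_error(lognormal_law(0, -1), class = "msl_bad_law")
  expect_error(boundary_spec(3, 5), class = "msl_bad_boundary")
})

test_that("growth rate handles the boundary cases of its formula", {
  p <- msl_params(exp(-1), beta1, 1e-4)
  expect_equal(growth_rate(p, 0), 0.1 / (exp(-1) + 1))
  expect_equal(growth_rate(p, 0), 0.0731058579, tolerance = 1e-9)
  # zero numerator: P has a root where Q' vanishes
  troot <- polyroot(c(0.1, -0.018, 0.0006))
  t1 <- Re(troot[1])
  expect_equal(growth_rate(p, t1), 0, tolerance = 1e-12)
  # Q -> Inf kills the rate
  expect_equal(growth_rate(p, 1e4), 0)
  # overflow-safe for very negative Q
  pneg <- msl_params(1, c(-50, 1e-3), 1e-4)  # Q(1) ~ -50
  expect_true(is.finite(growth_rate(pneg, 1)))
})

test_that("the curve solves its defining ODE and has the stated limit", {
  p <- msl_params(exp(-1), beta1, 1e-4)
  expect_identical(msl_curve(p, 5, 0, 0), 5)
  expect_equal(carrying_capacity(p, 5, 0), 5 * (1 + exp(1)), tolerance = 1e-9)
  expect_equal(carrying_capacity(p, 5, 0), 18.5914091, tolerance = 1e-7)
  expect_equal(msl_curve(p, 5, 0, 1e6), carrying_capacity(p, 5, 0),
               tolerance = 1e-9)
  # l'(t) = h(t) l(t) on a dense grid (finite differences)
  tt <- seq(0.5, 49.5, length.out = 200)
  h <- 1e-4
  lp <- (msl_curve(p, 5, 0, tt + h) - msl_curve(p, 5, 0, tt - h)) / (2 * h)
  expect_equal(lp, growth_rate(p, tt) * msl_curve(p, 5, 0, tt),
               tolerance = 1e-6)
})

test_that("carrying capacity bounds the curve in both growth regimes", {
  # monotone case (Fig-1b style parameters): sup over t equals the limit
  pmono <- msl_params(exp(-1), c(0.1, -0.007, 0.0003), 1e-4)
  tt <- seq(0, 200, length.out = 2000)
  lm <- msl_curve(pmono, 5, 0, tt)
  expect_true(all(diff(lm) > -1e-12))
  expect_equal(max(lm), carrying_capacity(pmono, 5, 0), tolerance = 1e-3)
  # non-monotone case: the limit still matches t -> Inf
  pnm <- msl_params(exp(-1), beta1, 1e-4)
  expect_lt(max(msl_curve(pnm, 5, 0, tt)),
            carrying_capacity(pnm, 5, 0) * (1 + 1e-12))
})

test_that("inflection roots agree with the second-derivative oracle", {
  p <- msl_params(exp(-1), beta1, 1e-4)
  roots <- find_inflections(p, 0, 50)
  # oracle: sign changes of the numerical second derivative of the curve
  tt <- seq(0, 50, length.out = 40001)
  d2 <- diff(diff(msl_curve(p, 5, 0, tt)))
  sg <- sign(d2)
  ora <- tt[which(sg[-1] * sg[-length(sg)] < 0) + 1L]
  expect_length(roots, length(ora))
  expect_equal(roots, ora, tolerance = 1e-3)
  # residual refined below tolerance at each root
  expect_true(all(abs(inflection_residual(p, roots)) < 1e-10))
  # second derivative changes sign across each root
  for (r in roots) {
    s_lo <- sign(msl_curve(p, 5, 0, r - 0.2) - 2 * msl_curve(p, 5, 0, r - 0.1) +
                   msl_curve(p, 5, 0, r))
    s_hi <- sign(msl_curve(p, 5, 0, r) - 2 * msl_curve(p, 5, 0, r + 0.1) +
                   msl_curve(p, 5, 0, r + 0.2))
    expect_true(s_lo * s_hi < 0)
  }
})

test_that("classical logistic case has the closed-form inflection", {
  p <- msl_params(0.5, 0.2, 1e-4)  # p = 1
  tstar <- -log(0.5) / 0.2
  expect_equal(inflection_residual(p, tstar), 0, tolerance = 1e-14)
  expect_equal(find_inflections(p, 0, 30), tstar, tolerance = 1e-8)
  expect_length(find_inflections(p, 20, 30), 0)  # excludes the root
})
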