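# Fisher information, delta-method intervals, initial-law pivots.

test_that("Fisher information matches its definition and brute force", {
  panel <- tiny_panel()
  p <- msl_params(0.35, c(0.11, -0.0085, 0.00019), 2e-4)
  fi <- fisher_information(panel, p)
  expect_equal(fi$matrix, t(fi$matrix))
  expect_true(all(eigen(fi$Xi, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-8))
  # brute-force double loop with finite-difference step gradients
  wide <- tidyr::pivot_wider(panel, names_from = "path_id",
                             values_from = "value")
  tt <- wide$time
  Xi_bf <- matrix(0, 4, 4)
  dg_bf <- numeric(4)
  grad_m <- function(s, t, xi) {
    vapply(1:4, function(k) {
      h <- 1e-6 * abs(xi[k])
      xp <- xi; xm <- xi
      xp[k] <- xi[k] + h; xm[k] <- xi[k] - h
      (H_xi(msl_params(xp[1], xp[2:4], p$sigma2), s, t) -
         H_xi(msl_params(xm[1], xm[2:4], p$sigma2), s, t)) / (2 * h)
    }, numeric(1))
  }
  xi0 <- c(p$eta, p$beta)
  for (i in 2:ncol(wide)) {
    for (j in seq_len(length(tt) - 1L)) {
      g <- grad_m(tt[j], tt[j + 1], xi0)
      Xi_bf <- Xi_bf + g %*% t(g) / (tt[j + 1] - tt[j])
      dg_bf <- dg_bf + g
    }
  }
  expect_equal(unname(fi$Xi), Xi_bf, tolerance = 1e-6)
  expect_equal(unname(fi$dgamma), dg_bf, tolerance = 1e-6)
  # exact-summation check against a naive loop with the analytic gradient
  vs <- v_transform(panel)
  st <- vs$steps
  G <- msldiff:::step_dm(p$eta, p$beta, st, 3)
  Xi_naive <- matrix(0, 4, 4)
  for (r in seq_len(nrow(st))) {
    Xi_naive <- Xi_naive + st$count[r] * G[r, ] %*% t(G[r, ]) / st$delta[r]
  }
  expect_equal(unname(fi$Xi), Xi_naive, tolerance = 1e-12)
})

test_that("the corner entry has its closed form", {
  p <- msl_params(exp(-1), c(0.1, -0.009, 0.0002), 1e-4)
  panel <- simulate_paths(p, msl_init_degenerate(5),
                          seq(0, 50, length.out = 501), 1, seed = 1)
  fi <- fisher_information(panel, p)
  expect_equal(fi$corner, 500 / (2e-4) - 50 / 4)
  expect_equal(fi$corner, 2.4999875e6)
  # the theta block of I scales as 1/sigma2
  p2 <- msl_params(p$eta, p$beta, 2 * p$sigma2)
  fi2 <- fisher_information(panel, p2)
  expect_equal(fi2$matrix[1:4, 1:4], fi$matrix[1:4, 1:4] / 2, tolerance = 1e-12)
})

test_that("asymptotic intervals nest across levels and match the delta method", {
  panel <- case1_panel_small()
  fit <- fit_newton_raphson(panel, 3)
  ci <- asymptotic_ci(fit, panel)
  expect_equal(sort(unique(ci$level), decreasing = TRUE), c(0.95, 0.90, 0.75))
  for (par in unique(ci$parameter)) {
    w <- ci[ci$parameter == par, ]
    w <- w[order(w$level), ]
    expect_true(all(diff(w$lower) <= 1e-15))  # wider level, lower bound smaller
    expect_true(all(diff(w$upper) >= -1e-15))
  }
  # identity coordinate reproduces the marginal interval
  d1 <- delta_method_ci(fit, panel, function(xi) xi[2], level = 0.95)
  w <- ci[ci$parameter == "beta_1" & ci$level == 0.95, ]
  expect_equal(d1$lower, w$lower, tolerance = 1e-6)
  expect_equal(d1$upper, w$upper, tolerance = 1e-6)
  # constant function: zero-width interval
  d0 <- delta_method_ci(fit, panel, function(xi) 42)
  expect_equal(d0$se, 0)
  expect_equal(d0$lower, d0$upper)
  # carrying capacity: positive interval
  dcc <- delta_method_ci(fit, panel, function(xi)
    5 * (xi[1] + 1) / xi[1])
  expect_gt(dcc$lower, 0)
})

test_that("95% intervals for beta_1 cover the truth at the nominal rate", {
  hits <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    panel <- make_case_panel(1, n_paths = 50, n_times = 101, seed = 4000 + s)
    fit <- fit_newton_raphson(panel, 3)
    if (!fit$converged) next
    ci <- asymptotic_ci(fit, panel, level = 0.95)
    w <- ci[ci$parameter == "beta_1", ]
    hits <- hits + (w$lower <= 0.1 && 0.1 <= w$upper)
  }
  # binomial 3-sigma band around 0.95 at n = 200
  expect_gt(hits / n_rep, 0.95 - 3 * sqrt(0.95 * 0.05 / n_rep))
  expect_lte(hits, n_rep)
})

test_that("initial-law intervals use the exact normal and chi-square pivots", {
  ci <- initial_law_ci(1.6, 0.04, d = 30, level = 0.95)
  qs <- stats::qchisq(c(0.975, 0.025), df = 29)
  expect_equal(ci$lower[2], 30 * 0.04 / qs[1])
  expect_equal(ci$upper[2], 30 * 0.04 / qs[2])
  expect_equal(ci$estimate[1], 1.6)
  # intervals shrink to points as d grows
  ci_big <- initial_law_ci(1.6, 0.04, d = 1e7)
  expect_lt(ci_big$upper[1] - ci_big$lower[1], 1e-3)
  expect_lt(ci_big$upper[2] - ci_big$lower[2], 1e-3)
  expect_error(initial_law_ci(1.6, 0.04, d = 1), class = "msl_bad_d")
  expect_warning(ci0 <- initial_law_ci(1.6, 0, d = 10), "degenerate")
  expect_equal(ci0$lower[2], 0)
  expect_equal(ci0$upper[2], 0)
})
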