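# Goodness-of-fit measures and polynomial-degree selection.

#' Mean absolute relative error of the fitted mean
#'
#' `RAE = (1/N) sum_j |m_j - Ehat[X(t_j)]| / m_j`, comparing the sample
#' mean curve with the mean of the estimated process (initial mean taken
#' from the fitted initial law `exp(mu1 + sigma1sq / 2)`).
#'
#' @param panel A panel data frame.
#' @param fit An `"msl_fit"`.
#' @return Non-negative scalar.
#' @export
rae <- function(panel, fit) {
  stopifnot(inherits(fit, "msl_fit"))
  sm <- sample_moments(panel)
  l0 <- exp(fit$mu1 + fit$sigma1sq / 2)
  est <- msl_curve(fit_params(fit), l0, sm$time[1L], sm$time)
  if (any(est <= 0)) rlang::abort("Estimated mean non-positive.", class = "msl_bad_fit")
  mean(abs(sm$m - est) / sm$m)
}

#' Information criteria of a fit
#'
#' `AIC_p = 2 (p + 2) - 2 L` and `BIC_p = (p + 2) log(n) - 2 L`, where
#' `L` is the full log-likelihood of the fit, `p + 2` the number of
#' diffusion parameters and `n` the number of observed transitions.
#'
#' @param fit An `"msl_fit"`.
#' @param p Parameter-count degree; defaults to the fit's.
#' @param n Observation count for the BIC; defaults to the fit's.
#' @return Scalar.
#' @export
aic <- function(fit, p = fit$p) 2 * (p + 2) - 2 * fit$loglik

#' @rdname aic
#' @export
bic <- function(fit, p = fit$p, n = fit$n) (p + 2) * log(n) - 2 * fit$loglik

#' Kullback-Leibler divergence between lognormal laws
#'
#' `D_KL(A || B) = 0.5 [ log(s2_B / s2_A) + (s2_A + (mu_A - mu_B)^2) /
#' s2_B - 1 ]`, the divergence from law `A` to law `B` (equal to the
#' divergence of the underlying normals).
#'
#' @param lawA,lawB [lognormal_law] objects.
#' @return Non-negative scalar.
#' @export
kl_lognormal <- function(lawA, lawB) {
  stopifnot(inherits(lawA, "lognormal_law"), inherits(lawB, "lognormal_law"))
  0.5 * (log(lawB$s2 / lawA$s2) + (lawA$s2 + (lawA$mu - lawB$mu)^2) / lawB$s2 - 1)
}

#' Resistor-average distance
#'
#' Harmonic mean of the two directed Kullback-Leibler divergences,
#' `D_RA = D_KL(A||B) D_KL(B||A) / (D_KL(A||B) + D_KL(B||A))`; zero when
#' both divergences vanish. Always bounded by the smaller divergence.
#'
#' @inheritParams kl_lognormal
#' @return Non-negative scalar.
#' @export
resistor_average <- function(lawA, lawB) {
  dab <- kl_lognormal(lawA, lawB)
  dba <- kl_lognormal(lawB, lawA)
  if (dab + dba == 0) return(0)
  dab * dba / (dab + dba)
}

#' Resistor-average distance curve between sample and fitted laws
#'
#' At each observation time `t > t0` the sample cross-section is
#' summarised as a lognormal law with `mu = log m_g(t)` and
#' `s2 = 2 log(m(t) / m_g(t))`, and compared with the fitted law
#' (`mu1 + H(t0, t)`, `sigma1sq + sigma2 (t - t0)`) through
#' [resistor_average()]. With `reference = "theoretical"` the fitted law
#' is compared with the law of a supplied generating process instead of
#' the sample law.
#'
#' @param panel A panel data frame (`d >= 2` paths).
#' @param fit An `"msl_fit"`.
#' @param reference `"sample"` (default) or `"theoretical"`.
#' @param params Generating [msl_params] (theoretical reference).
#' @param init Generating [msl_init_degenerate()]/[msl_init_lognormal()]
#'   (theoretical reference).
#' @return A list with the per-time tibble `curve` (`time`, `d_ra`) and
#'   scalars `median` and `mean`.
#' @export
ra_distance_curve <- function(panel, fit, reference = c("sample", "theoretical"),
                              params = NULL, init = NULL) {
  reference <- match.arg(reference)
  stopifnot(inherits(fit, "msl_fit"))
  sm <- sample_moments(panel)
  t0 <- sm$time[1L]
  tt <- sm$time[sm$time > t0]
  fitp <- fit_params(fit)
  mu_fit <- fit$mu1 + H_xi(fitp, t0, tt)
  s2_fit <- fit$sigma1sq + fit$sigma2 * (tt - t0)
  if (reference == "sample") {
    if (max(sm$d) < 2) {
      rlang::abort("Sample reference needs d >= 2 paths.", class = "msl_bad_panel")
    }
    sm2 <- sm[sm$time > t0, ]
    mu_ref <- log(sm2$m_g)
    s2_ref <- sm2$s2
  } else {
    stopifnot(inherits(params, "msl_params"), inherits(init, "msl_init"))
    mu_ref <- init$mu0 + H_xi(params, t0, tt)
    s2_ref <- init$sigma0sq + params$sigma2 * (tt - t0)
  }
  usable <- s2_ref > 0 & s2_fit > 0
  if (!all(usable)) {
    rlang::warn(sprintf("%d time point(s) with zero variance skipped.", sum(!usable)))
  }
  dra <- purrr::map_dbl(which(usable), function(i) {
    resistor_average(lognormal_law(mu_ref[i], s2_ref[i]),
                     lognormal_law(mu_fit[i], s2_fit[i]))
  })
  list(curve = tibble::tibble(time = tt[usable], d_ra = dra),
       median = stats::median(dra), mean = mean(dra))
}

#' Polynomial-degree selection
#'
#' Fits every degree in `p_min..p_max` and tabulates the four goodness
#' measures (RAE, AIC, BIC, median and mean resistor-average distance).
#' The selected degree minimises BIC, with AIC, then median distance,
#' then the smallest degree as tie-breakers; RAE is reported but never
#' decisive (it keeps improving with degree). Degrees whose fit fails to
#' converge are reported as such, carrying the regression-based initial
#' solution as their estimate.
#'
#' @param panel A panel data frame.
#' @param p_min,p_max Degree range (default 2..6).
#' @param method `"newton"` or `"sa"`.
#' @param reference Reference law for the distance curve, see
#'   [ra_distance_curve()].
#' @param params,init Generating process (theoretical reference only).
#' @param ... Passed to the fitting routine.
#' @return An object of class `"msl_degree_report"`: list with the
#'   `measures` tibble (one row per degree), `fits` (named list of
#'   `"msl_fit"`), and `chosen` (the selected degree).
#' @export
select_degree <- function(panel, p_min = 2L, p_max = 6L,
                          method = c("newton", "sa"),
                          reference = c("sample", "theoretical"),
                          params = NULL, init = NULL, ...) {
  method <- match.arg(method)
  reference <- match.arg(reference)
  stopifnot(p_min >= 1L, p_max >= p_min)
  panel <- as_msl_panel(panel)
  degrees <- seq.int(p_min, p_max)
  fits <- purrr::map(degrees, function(p) {
    tryCatch(
      if (method == "newton") fit_newton_raphson(panel, p, ...) else
        fit_simulated_annealing(panel, p, ...),
      error = function(e) e)
  })
  names(fits) <- paste0("p", degrees)
  rows <- purrr::map2_dfr(fits, degrees, function(f, p) {
    if (inherits(f, "error")) {
      return(tibble::tibble(degree = p, converged = FALSE, rae = NA_real_,
                            aic = NA_real_, bic = NA_real_,
                            median_dra = NA_real_, mean_dra = NA_real_,
                            failure = conditionMessage(f)))
    }
    dra <- tryCatch(
      ra_distance_curve(panel, f, reference = reference,
                        params = params, init = init),
      error = function(e) list(median = NA_real_, mean = NA_real_))
    tibble::tibble(degree = p, converged = f$converged,
                   rae = tryCatch(rae(panel, f), error = function(e) NA_real_),
                   aic = aic(f), bic = bic(f),
                   median_dra = dra$median, mean_dra = dra$mean,
                   failure = NA_character_)
  })
  ok <- which(is.finite(rows$bic))
  if (!length(ok)) rlang::abort("No degree produced a finite fit.", class = "msl_bad_fit")
  ord <- ok[order(rows$bic[ok], rows$aic[ok], rows$median_dra[ok], rows$degree[ok])]
  chosen <- rows$degree[ord[1L]]
  rows$chosen <- rows$degree == chosen
  structure(list(measures = rows, fits = fits, chosen = chosen,
                 method = method),
            class = "msl_degree_report")
}

#' @export
print.msl_degree_report <- function(x, ...) {
  cat("<msl_degree_report> method:", x$method, "- chosen degree p =", x$chosen, "\n")
  print(x$measures)
  invisible(x)
}
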