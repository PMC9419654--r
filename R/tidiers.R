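# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a diffusion fit
#'
#' One row per estimated parameter (`eta`, `beta_1..beta_p`, `sigma2`,
#' `mu1`, `sigma1sq`). With `conf.int = TRUE` the asymptotic intervals
#' from [asymptotic_ci()] are attached for the diffusion parameters
#' (this requires the fitting `panel`).
#'
#' @param x An `"msl_fit"`.
#' @param conf.int Attach confidence intervals.
#' @param conf.level Level for the intervals.
#' @param panel Panel used for the fit (needed for intervals).
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (and `std.error`,
#'   `conf.low`, `conf.high` when requested).
#' @method tidy msl_fit
#' @export
tidy.msl_fit <- function(x, conf.int = FALSE, conf.level = 0.95,
                         panel = NULL, ...) {
  out <- tibble::tibble(
    term = c("eta", paste0("beta_", seq_len(x$p)), "sigma2", "mu1", "sigma1sq"),
    estimate = c(x$eta, x$beta, x$sigma2, x$mu1, x$sigma1sq))
  if (conf.int) {
    if (is.null(panel)) {
      rlang::abort("`panel` is required for confidence intervals.",
                   class = "msl_need_panel")
    }
    ci <- asymptotic_ci(x, panel, level = conf.level)
    out <- dplyr::left_join(
      out,
      dplyr::select(ci, term = "parameter", std.error = "se",
                    conf.low = "lower", conf.high = "upper"),
      by = "term")
  }
  out
}

#' Glance at a diffusion fit
#'
#' @param x An `"msl_fit"`.
#' @param ... Unused.
#' @return A one-row tibble with the log-likelihood, information
#'   criteria and convergence diagnostics.
#' @method glance msl_fit
#' @export
glance.msl_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = aic(x), BIC = bic(x),
    p = x$p, n = x$n, d = x$d, method = x$method,
    converged = x$converged, iterations = x$iterations,
    residual_norm = x$residual_norm)
}

#' Plot a sample panel
#'
#' Spaghetti plot of the trajectories with the sample mean overlaid.
#'
#' @param panel A panel data frame.
#' @param max_paths At most this many paths are drawn.
#' @param alpha Line transparency for the paths.
#' @return A ggplot object.
#' @export
plot_panel <- function(panel, max_paths = 100L, alpha = 0.3) {
  panel <- as_msl_panel(panel)
  ids <- unique(panel$path_id)
  shown <- dplyr::filter(panel, .data$path_id %in% ids[seq_len(min(length(ids), max_paths))])
  sm <- sample_moments(panel)
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$time, y = .data$value,
                                      group = .data$path_id)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey40") +
    ggplot2::geom_line(data = sm, ggplot2::aes(y = .data$m, group = NULL),
                       colour = "black", linewidth = 0.9) +
    ggplot2::labs(x = "time", y = "value",
                  title = "Sample paths (black: sample mean)") +
    ggplot2::theme_minimal()
}

#' Plot a fit against the sample mean
#'
#' @param object An `"msl_fit"`.
#' @param panel Panel used for the fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msl_fit
#' @export
autoplot.msl_fit <- function(object, panel, ...) {
  sm <- sample_moments(panel)
  l0 <- exp(object$mu1 + object$sigma1sq / 2)
  est <- msl_curve(fit_params(object), l0, sm$time[1L], sm$time)
  df <- tidyr::pivot_longer(
    tibble::tibble(time = sm$time, sample = sm$m, fitted = est),
    -"time", names_to = "curve", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time", y = "mean",
                  title = sprintf("Fitted mean curve (p = %d, %s)",
                                  object$p, object$method)) +
    ggplot2::theme_minimal()
}

#' Plot a first-passage-time density
#'
#' @param object An `"msl_fpt"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msl_fpt
#' @export
autoplot.msl_fpt <- function(object, ...) {
  ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$time, y = .data$density)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time", y = "density",
                  title = sprintf("FPT density through S = %g (mass %.4f)",
                                  object$boundary$S, object$total_mass)) +
    ggplot2::theme_minimal()
}

#' Plot a degree-selection report
#'
#' Shows BIC and median resistor-average distance per candidate degree.
#'
#' @param object An `"msl_degree_report"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot msl_degree_report
#' @export
autoplot.msl_degree_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object$measures, "degree", "bic", "median_dra"),
    -"degree", names_to = "measure", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$value)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::geom_vline(xintercept = object$chosen, linetype = 2,
                        colour = "steelblue") +
    ggplot2::labs(x = "polynomial degree", y = NULL,
                  title = sprintf("Degree selection (chosen p = %d)", object$chosen)) +
    ggplot2::theme_minimal()
}
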