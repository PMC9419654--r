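# Long-format sample panels: validation and CSV round trip.

#' Validate a sample panel
#'
#' A panel is a long-format data frame with columns `path_id`, `time`,
#' `value`: `d >= 1` trajectories on (possibly ragged) strictly
#' increasing time grids sharing the same first observation time, all
#' values positive. Returns the panel as a tibble ordered by path and
#' time, or aborts with a row-level diagnostic.
#'
#' @param panel A data frame with columns `path_id`, `time`, `value`.
#' @return A validated tibble.
#' @export
as_msl_panel <- function(panel) {
  if (!is.data.frame(panel) ||
      !all(c("path_id", "time", "value") %in% names(panel))) {
    rlang::abort("A panel needs columns `path_id`, `time`, `value`.",
                 class = "msl_bad_panel")
  }
  bad <- which(!is.finite(panel$time) | !is.finite(panel$value))
  if (length(bad)) {
    rlang::abort(paste0("Non-finite time/value in panel row(s) ",
                        paste(utils::head(bad, 5L), collapse = ", "), "."),
                 class = "msl_bad_panel")
  }
  bad <- which(panel$value <= 0)
  if (length(bad)) {
    rlang::abort(paste0("Non-positive value in panel row(s) ",
                        paste(utils::head(bad, 5L), collapse = ", "),
                        "; the process is strictly positive."),
                 class = "msl_bad_panel")
  }
  out <- dplyr::arrange(tibble::as_tibble(panel[c("path_id", "time", "value")]),
                        .data$path_id, .data$time)
  chk <- dplyr::summarise(dplyr::group_by(out, .data$path_id),
                          t0 = .data$time[1L],
                          ok = all(diff(.data$time) > 0), .groups = "drop")
  if (!all(chk$ok)) {
    rlang::abort(paste0("Times must be strictly increasing within each path (path ",
                        paste(chk$path_id[!chk$ok], collapse = ", "), ")."),
                 class = "msl_bad_panel")
  }
  if (length(unique(chk$t0)) != 1L) {
    rlang::abort("All paths must share the same first observation time.",
                 class = "msl_bad_panel")
  }
  out
}

#' Read / write a panel as long-format CSV
#'
#' The on-disk format is a plain CSV with header `path_id,time,value`.
#'
#' @param path File path.
#' @return `read_panel()`: a validated panel tibble.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path), class = "msl_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in c("time", "value")) {
    if (!is.numeric(df[[cl]])) {
      suppressWarnings(v <- as.numeric(df[[cl]]))
      if (any(is.na(v) & !is.na(df[[cl]]))) {
        rlang::abort(paste0("Non-numeric `", cl, "` in ", path, " (first bad row ",
                            which(is.na(v) & !is.na(df[[cl]]))[1L], ")."),
                     class = "msl_io_error")
      }
      df[[cl]] <- v
    }
  }
  as_msl_panel(df)
}

#' @rdname read_panel
#' @param panel A panel data frame.
#' @export
write_panel <- function(panel, path) {
  panel <- as_msl_panel(panel)
  utils::write.csv(panel, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-time sample moments of a panel
#'
#' For panels observed on a common grid, returns per time point the
#' arithmetic mean `m_j`, the geometric mean `m_j^g`, and the lognormal
#' log-variance proxy `sigma_j^2 = 2 log(m_j / m_j^g)` (non-negative by
#' the AM-GM inequality).
#'
#' @param panel A panel data frame.
#' @return A tibble with columns `time`, `m`, `m_g`, `s2`, `d`.
#' @export
sample_moments <- function(panel) {
  panel <- as_msl_panel(panel)
  dplyr::summarise(dplyr::group_by(panel, .data$time),
                   m = mean(.data$value),
                   m_g = exp(mean(log(.data$value))),
                   d = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(s2 = 2 * log(.data$m / .data$m_g)) |>
    dplyr::select("time", "m", "m_g", "s2", "d")
}
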