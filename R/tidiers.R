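#' Tidy a recovery result
#'
#' @param x A `recovery_result`.
#' @param ... Unused.
#' @return A one-row tibble with the pooled counts, recovery and CI.
#' @export
tidy.recovery_result <- function(x, ...) {
  tibble::tibble(
    recovery = x$recovery,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    n_bound = x$n_bound,
    n_lost = x$n_lost,
    batches = x$batches_run,
    converged = x$converged
  )
}

#' One-line summary of a recovery result
#'
#' @param x A `recovery_result`.
#' @param ... Unused.
#' @return A one-row tibble including total particles and derived
#'   transport quantities when available.
#' @export
glance.recovery_result <- function(x, ...) {
  out <- tidy.recovery_result(x)
  out$n_total <- x$n_bound + x$n_lost
  if (!is.null(x$derived)) {
    out$u_mean <- x$derived$u_mean
    out$dt <- x$derived$dt
    out$residence_time_s <- x$derived$residence_time
  }
  out
}

#' Tidy a flow-rate sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A tibble with one row per flow rate: `flow_ul_min, recovery,
#'   ci_low, ci_high, n_bound, n_lost, batches, converged`.
#' @export
tidy.sweep_result <- function(x, ...) {
  rows <- purrr::map2(x$flow_rates, x$recoveries, function(q, r) {
    dplyr::bind_cols(tibble::tibble(flow_ul_min = q), tidy.recovery_result(r))
  })
  dplyr::bind_rows(rows)
}

#' One-line summary of a flow-rate sweep
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A one-row tibble: device label, flow range, recovery range.
#' @export
glance.sweep_result <- function(x, ...) {
  tbl <- tidy.sweep_result(x)
  tibble::tibble(
    device = x$device,
    n_flow_rates = nrow(tbl),
    flow_min = min(tbl$flow_ul_min),
    flow_max = max(tbl$flow_ul_min),
    recovery_min = min(tbl$recovery),
    recovery_max = max(tbl$recovery),
    all_converged = all(tbl$converged)
  )
}

#' Recovery-versus-flow-rate plot
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot: recovery (with CI ribbon) against flow rate.
#' @export
autoplot.sweep_result <- function(object, ...) {
  tbl <- tidy.sweep_result(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$flow_ul_min,
                                    y = .data$recovery)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v),
                                limits = c(0, 1)) +
    ggplot2::labs(
      x = expression("Volumetric flow rate (" * mu * "L/min)"),
      y = "Predicted EV recovery",
      title = object$device
    ) +
    ggplot2::theme_minimal()
}

#' Quick recovery-curve plot
#'
#' Convenience wrapper around [autoplot.sweep_result()].
#'
#' @param sweep A `sweep_result`.
#' @return A ggplot object.
#' @export
plot_recovery_curve <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  autoplot.sweep_result(sweep)
}
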