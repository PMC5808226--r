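#' Plot oocyte swelling traces
#'
#' Relative volume against time, one line per oocyte, colored by group.
#'
#' @param traces A `swelling_trace` tibble (one or many oocytes).
#' @return A ggplot object.
#' @examples
#' plot_traces(gen_swelling_experiment(n_expressing = 2, n_control = 2,
#'                                     seed = 1)$traces)
#' @export
plot_traces <- function(traces) {
  .validate_trace(traces)
  ggplot2::ggplot(traces,
                  ggplot2::aes(x = .data$time_s, y = .data$rel_volume,
                               group = .data$oocyte_id,
                               color = .data$group)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "Time (s)", y = expression(V / V[0]),
                  color = "Group") +
    ggplot2::theme_minimal()
}

#' Plot per-group permeability estimates
#'
#' Group mean with SEM error bars over the individual oocyte estimates.
#'
#' @param estimates A `permeability_estimates` tibble.
#' @return A ggplot object.
#' @export
plot_estimates <- function(estimates) {
  lab <- if (any(estimates$kind == "pf")) expression(P[f] ~ "(cm/s)")
         else expression(P[sol] ~ "(cm/s)")
  summ <- glance(estimates)
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::geom_jitter(data = tibble::as_tibble(unclass(estimates)),
                         ggplot2::aes(y = .data$value), width = 0.08,
                         alpha = 0.6) +
    ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a hydropathy profile with called segments
#'
#' @param profile Output of [hydropathy_profile()].
#' @param threshold Threshold line to draw (default 1.6).
#' @return A ggplot object.
#' @export
plot_hydropathy <- function(profile, threshold = 1.6) {
  p <- ggplot2::ggplot(profile$profile,
                       ggplot2::aes(x = .data$center, y = .data$hydropathy)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        color = "red") +
    ggplot2::labs(x = "Residue (window center)",
                  y = "Mean Kyte-Doolittle hydropathy") +
    ggplot2::theme_minimal()
  if (nrow(profile$segments) > 0) {
    p <- p + ggplot2::geom_rect(
      data = profile$segments,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' Plot relative expression by condition
#'
#' Mean relative quantity with SEM error bars and, when supplied, compact
#' letter groupings from [group_stats()].
#'
#' @param rq_table Output of [relative_quantity()].
#' @param stats Optional `expression_stats` object for letter annotations.
#' @return A ggplot object.
#' @export
plot_expression <- function(rq_table, stats = NULL) {
  summ <- rq_table |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(mean_rq = mean(.data$rq),
                     sem = stats::sd(.data$rq) / sqrt(dplyr::n()),
                     .groups = "drop")
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$condition,
                                          y = .data$mean_rq)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rq - .data$sem,
                                        ymax = .data$mean_rq + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = "Relative mRNA level (fold)") +
    ggplot2::theme_minimal()
  if (!is.null(stats) && !is.null(stats$letters)) {
    ann <- dplyr::left_join(summ, stats$letters, by = "condition")
    p <- p + ggplot2::geom_text(
      data = ann,
      ggplot2::aes(label = .data$letters,
                   y = .data$mean_rq + 2 * .data$sem),
      vjust = -0.5
    )
  }
  p
}
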