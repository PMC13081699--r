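#' Plot true vs predicted age for an ensemble
#'
#' Scatter of subject-level averaged rescaled predictions against true
#' age with the identity line; the vertical spread around y = x is the
#' brain-age gap.
#'
#' @param object An `fcage_ensemble`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fcage_ensemble
#' @export
autoplot.fcage_ensemble <- function(object, ...) {
  df <- dplyr::filter(object$subjects, !is.na(.data$pred_age))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$pred_age,
                                   colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      title = sprintf("%s: predicted vs true age", object$label),
      x = "True age (years)", y = "Predicted age (years)",
      colour = "Reading group"
    ) +
    ggplot2::theme_minimal()
}

#' Mean brain-age gap by model and reading group
#'
#' Group-mean BAG with standard-error bars per model; positive values
#' mean the ensemble underestimates age.
#'
#' @param bag_tbl A BAG table from [bag_table()].
#' @return A ggplot.
#' @export
plot_bag_by_group <- function(bag_tbl) {
  sm <- dplyr::summarise(
    dplyr::group_by(bag_tbl, .data$model, .data$group),
    mean_bag = mean(.data$bag, na.rm = TRUE),
    se = sd(.data$bag, na.rm = TRUE) / sqrt(sum(!is.na(.data$bag))),
    .groups = "drop"
  )
  ggplot2::ggplot(sm, ggplot2::aes(.data$model, .data$mean_bag,
                                   colour = .data$group,
                                   group = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_bag - .data$se,
                                          ymax = .data$mean_bag + .data$se)) +
    ggplot2::labs(x = "Model", y = "Mean BAG (years; + = underestimated)",
                  colour = "Reading group") +
    ggplot2::theme_minimal()
}

#' Network representation among significant edges
#'
#' Observed share of pooled significant-edge ROI slots per network
#' against the resampling-null mean (+/- SD), so over- and
#' under-represented networks stand out relative to their spatial
#' extent.
#'
#' @param net_tbl Output of [network_representation()].
#' @return A ggplot.
#' @export
plot_network_representation <- function(net_tbl) {
  long <- tidyr::pivot_longer(
    dplyr::select(net_tbl, "network", observed = "observed_share",
                  null = "null_mean_share"),
    cols = c("observed", "null"), names_to = "which", values_to = "share"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$network, .data$share,
                                     fill = .data$which)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(
      data = net_tbl,
      ggplot2::aes(x = .data$network,
                   ymin = .data$null_mean_share - .data$null_sd_share,
                   ymax = .data$null_mean_share + .data$null_sd_share),
      inherit.aes = FALSE, width = 0.3
    ) +
    ggplot2::labs(x = "Network", y = "Share of pooled ROI slots",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
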