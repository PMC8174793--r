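#' Phase boxplots of daily bias and RMSE
#'
#' Boxplots of the daily bias and RMSE values for each method, split
#' into the early (7–30), middle (31–60) and late (61–84) parts of the
#' collection period — one panel per metric, methods side by side within
#' each phase.
#'
#' @param object A `propensity_eval` from [evaluate_replay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot propensity_eval
#' @export
autoplot.propensity_eval <- function(object, ...) {
  long <- object |>
    dplyr::mutate(phase = phase_of(.data$day)) |>
    dplyr::filter(!is.na(.data$phase)) |>
    dplyr::mutate(phase = factor(.data$phase,
                                 levels = c("early", "middle", "late"))) |>
    tidyr::pivot_longer(c("bias", "rmse"), names_to = "metric",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$phase, y = .data$value,
                               fill = .data$method)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "data collection phase",
                  y = "daily value vs target", fill = "method") +
    ggplot2::theme_minimal()
}

#' Plot a pooled prior table
#'
#' Prior means with ±2 SE intervals per coefficient; diffuse-fallback
#' rows are distinguished by colour.
#'
#' @param object A `prior_table` from [build_prior_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prior_table
#' @export
autoplot.prior_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(term = factor(.data$term, levels = rev(.data$term)))
  ggplot2::ggplot(df,
                  ggplot2::aes(x = .data$mean, y = .data$term,
                               colour = .data$source)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$mean - 2 * .data$se,
                   xmax = .data$mean + 2 * .data$se),
      height = 0.25) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::labs(x = "prior mean (log-odds) ± 2 SE", y = NULL,
                  colour = "source") +
    ggplot2::theme_minimal()
}

#' Plot expert coefficient distributions by subgroup
#'
#' Boxplots of individual experts' converted coefficients per term,
#' grouped by organization or experience band.
#'
#' @param panel Expert-response tibble.
#' @param schema A [covariate_schema()].
#' @param by `"organization"` or `"experience_band"`.
#' @param baseline Baseline attempt-level rate for continuous items.
#' @return A ggplot object.
#' @export
plot_expert_betas <- function(panel, schema,
                              by = c("organization", "experience_band"),
                              baseline = 0.24) {
  by <- match.arg(by)
  eb <- expert_betas(panel, schema, baseline = baseline)
  ggplot2::ggplot(eb,
                  ggplot2::aes(x = .data$term, y = .data$beta,
                               fill = .data[[by]])) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge(width = 0.8),
                          outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-expert coefficient (log-odds)",
                  fill = by) +
    ggplot2::theme_minimal()
}
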