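#' Percentile curves of a fitted norming model
#'
#' The qualitative check test constructors use before accepting a model:
#' expected raw score as a function of age for a set of norm scores. Curves
#' that cross or fold back reveal monotonicity problems.
#'
#' @param model A `semiparam_model`.
#' @param norms Norm scores (T) to draw, default every half SD from 20 to 80.
#' @param ages Age grid, default the fitted age range.
#' @return A ggplot object.
#' @export
plot_percentile_curves <- function(model,
                                   norms = seq(20, 80, by = 5),
                                   ages = NULL) {
  stopifnot(inherits(model, "semiparam_model"))
  if (is.null(ages))
    ages <- seq(model$data_range$age[1], model$data_range$age[2],
                length.out = 100)
  df <- tidyr::expand_grid(T = norms, age = ages) |>
    dplyr::mutate(raw = predict_raw(model, .data$T, .data$age))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$raw,
                                   group = .data$T,
                                   colour = .data$T)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_viridis_c(name = "T-score") +
    ggplot2::labs(x = "age", y = "expected raw score",
                  title = "Percentile curves of the norming model") +
    ggplot2::theme_minimal()
}

#' Plot the band-wise RMSE profile
#'
#' RMSE per five-point band of the ideal norm score, per method and scale.
#' The semi-parametric method typically shows a U shape: larger errors at
#' extreme abilities, small errors around the population mean.
#'
#' @param cycles Per-cycle tibble or `study_results`.
#' @return A ggplot object.
#' @export
plot_band_profile <- function(cycles) {
  bp <- band_profile(cycles)
  ggplot2::ggplot(bp, ggplot2::aes(.data$band_mid, .data$rmse,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(x = "ideal norm score (band midpoint, T)",
                  y = "RMSE (T-score points)",
                  title = "Norming error as a function of ability") +
    ggplot2::theme_minimal()
}

#' Plot RMSE against sample size
#'
#' @param cycles Per-cycle tibble or `study_results`.
#' @return A ggplot object.
#' @export
plot_rmse_by_n <- function(cycles) {
  if (inherits(cycles, "study_results")) cycles <- cycles$cycles
  df <- clean_results(cycles) |>
    dplyr::group_by(.data$scale, .data$method, .data$n_per_group) |>
    dplyr::summarise(rmse = mean(.data$rmse), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$n_per_group, .data$rmse,
                                   colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~scale) +
    ggplot2::labs(x = "sample size per age group",
                  y = "mean RMSE (T-score points)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_band_profile
#' @param object A `study_results` object.
#' @param ... Unused.
#' @export
autoplot.study_results <- function(object, ...) {
  plot_rmse_by_n(object)
}
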