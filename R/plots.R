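# ggplot2 figures for the two result types: the per-breed omega_P bar
# chart with bootstrap SE bars, and the log-log age-vs-delta scatter with
# its least-squares line.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-breed omega_P bar chart with bootstrap SE bars
#'
#' @param object a `breed_load` tibble from [estimate_breed_load()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.breed_load <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::arrange(dplyr::desc(.data$omega_P)) |>
    dplyr::mutate(breed = factor(.data$breed, levels = .data$breed))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$breed, y = .data$omega_P)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$omega_P - .data$se_omega_P,
                   ymax = .data$omega_P + .data$se_omega_P),
      width = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = NULL,
                  y = expression(omega[P] == pi[N] / pi[S])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname autoplot.breed_load
#' @param x a `breed_load` tibble
#' @export
plot_breed_load <- function(x, ...) autoplot.breed_load(x, ...)

#' Log-log age-vs-delta scatter with regression line
#'
#' @param object an `age_load_cor` from [correlate_age_load()]
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.age_load_cor <- function(object, ...) {
  fit <- dplyr::filter(object$results, .data$method == "pearson",
                       .data$transform == "log10")
  df <- dplyr::filter(object$scatter, is.finite(.data$log10_age),
                      is.finite(.data$log10_delta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log10_age,
                                   y = .data$log10_delta)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(
      x = "log10 breed age (years)",
      y = expression(log[10] ~ delta),
      subtitle = sprintf("Pearson r = %.2f, P = %.2g (log10 scale, n = %d)",
                         fit$r, fit$p_value, fit$n)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.age_load_cor
#' @param x an `age_load_cor`
#' @export
plot_age_delta <- function(x, ...) autoplot.age_load_cor(x, ...)
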