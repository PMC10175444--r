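#' Cumulative flux curves per compartment
#'
#' Running cumulative sums (ug m-2) of one or more gap-filled 30-min
#' flux series; by micrometeorological convention the curves run
#' downward for net deposition.
#'
#' @param ... Named flux tibbles (`timestamp`, `flux`), e.g.
#'   `ecosystem = eco, floor = fl, canopy = can`.
#' @return A ggplot object.
#' @export
plot_cumulative_flux <- function(...) {
  series <- list(...)
  stopifnot(length(series) > 0, !is.null(names(series)))
  df <- purrr::imap(series, function(s, nm) {
    s <- arrange(as_tibble(s), .data$timestamp)
    tibble(timestamp = s$timestamp,
           cumulative = cumsum(tidyr::replace_na(s$flux, 0)) * 0.5 / 1000,
           compartment = nm)
  }) %>% bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$timestamp,
                                   y = .data$cumulative,
                                   colour = .data$compartment)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = expression(
      "Cumulative GEM flux (" * mu * "g" ~ m^-2 * ")"),
      colour = NULL) +
    ggplot2::theme_minimal()
}

#' Mean diel cycle of a flux series
#'
#' @param series Flux tibble (`timestamp`, `flux` in ng m-2 hr-1).
#' @param months Optional integer months to restrict to (e.g. a growing
#'   season).
#' @return A ggplot object of hour-of-day mean flux.
#' @export
plot_diel_cycle <- function(series, months = NULL) {
  series <- as_tibble(series)
  if (!is.null(months)) {
    series <- filter(series, lubridate::month(.data$timestamp) %in% months)
  }
  df <- series %>%
    mutate(hour = lubridate::hour(.data$timestamp) +
             lubridate::minute(.data$timestamp) / 60) %>%
    group_by(.data$hour) %>%
    summarise(flux = mean(.data$flux, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hour, y = .data$flux)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Hour of day", y = expression(
      "GEM flux (ng" ~ m^-2 ~ hr^-1 * ")")) +
    ggplot2::theme_minimal()
}

#' Histogram of daily-differencing random errors with the Laplace fit
#'
#' @param object A `gem_error_model`.
#' @param differences The daily differences the model was fitted to.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gem_error_model <- function(object, differences, ...) {
  if (is.data.frame(differences)) differences <- differences$diff
  df <- tibble(diff = differences)
  # difference of two iid Laplace(beta) errors
  dens <- function(z, b) (1 / (4 * b)) * (1 + abs(z) / b) * exp(-abs(z) / b)
  grid <- tibble(z = seq(min(df$diff), max(df$diff), length.out = 400))
  grid$d <- dens(grid$z - median(df$diff), object$scale_beta)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$diff)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey80", colour = "grey60") +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$z, y = .data$d),
                       colour = "firebrick") +
    ggplot2::labs(x = expression("24-h flux difference (ng" ~ m^-2 ~
                                   hr^-1 * ")"),
                  y = "Density") +
    ggplot2::theme_minimal()
}
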