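#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point facet_wrap
#'   labs theme_bw
#' @export
ggplot2::autoplot

kJ <- function(x) x / 1e3

#' Plot DSC scans
#'
#' @param object A [dsc_scans()] table.
#' @param ... Unused.
#' @return A ggplot: apparent heat capacity (kJ mol^-1 K^-1) versus
#'   temperature, coloured by scan role, faceted by experiment.
#' @export
autoplot.dsc_scans <- function(object, ...) {
  d <- as_tibble(object)
  d$scan <- ifelse(d$role == "reheat",
                   paste0("reheat (T' = ", round(d$t_prime - 273.15), " °C)"),
                   "first")
  ggplot(d, aes(.data$temperature - 273.15, kJ(.data$cp),
                colour = .data$scan)) +
    geom_line() +
    facet_wrap(~experiment) +
    labs(x = "Temperature (°C)",
         y = expression(C[p]^app ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
         colour = NULL) +
    theme_bw()
}

#' Plot a state-fraction trajectory
#'
#' @param object A `dsc_trajectory` from [simulate_fractions()].
#' @param ... Unused.
#' @return A ggplot of every state fraction versus temperature, with line
#'   type distinguishing heating from cooling segments.
#' @export
autoplot.dsc_trajectory <- function(object, ...) {
  d <- tidyr::pivot_longer(as_tibble(object),
                           dplyr::starts_with("x_"),
                           names_to = "state", values_to = "fraction")
  d$direction <- ifelse(d$rate < 0, "cooling", "heating")
  ggplot(d, aes(.data$temperature - 273.15, .data$fraction,
                colour = .data$state, linetype = .data$direction,
                group = interaction(.data$segment, .data$state))) +
    geom_line() +
    labs(x = "Temperature (°C)", y = "State fraction",
         colour = NULL, linetype = NULL) +
    theme_bw()
}

#' Plot a global fit
#'
#' @param object A `dsc_fit` from [global_fit()].
#' @param residuals If `TRUE`, plot residuals instead of curves.
#' @param ... Unused.
#' @return A ggplot overlaying the data (points) and the globally fitted
#'   model curves (lines) per scan, or the residuals split by scan role.
#' @export
autoplot.dsc_fit <- function(object, residuals = FALSE, ...) {
  d <- object$fitted
  d$scan <- ifelse(d$role == "reheat",
                   paste0("reheat (T' = ", round(d$t_prime - 273.15), " °C)"),
                   "first")
  if (residuals) {
    return(ggplot(d, aes(.data$temperature - 273.15, kJ(.data$.resid),
                         colour = .data$scan)) +
             geom_point(size = 0.4, alpha = 0.6) +
             facet_wrap(~experiment) +
             labs(x = "Temperature (°C)",
                  y = expression(Residual ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
                  colour = NULL) +
             theme_bw())
  }
  ggplot(d, aes(.data$temperature - 273.15, group = .data$scan)) +
    geom_point(aes(y = kJ(.data$cp), colour = .data$scan),
               size = 0.4, alpha = 0.4) +
    geom_line(aes(y = kJ(.data$.fitted)), linewidth = 0.4) +
    facet_wrap(~experiment) +
    labs(x = "Temperature (°C)",
         y = expression(C[p]^app ~ "(kJ" ~ mol^-1 ~ K^-1 * ")"),
         colour = NULL) +
    theme_bw()
}
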