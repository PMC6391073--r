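#' Plot a light-response curve
#'
#' Growth rate and proteome mass fractions of the allocation model as a
#' function of light intensity.
#'
#' @param object A [light_response()] result.
#' @param fractions Which mass-fraction columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot light_response
#' @export
autoplot.light_response <- function(object,
                                    fractions = c("fraction_R", "fraction_P",
                                                  "fraction_M"),
                                    ...) {
  d <- as_tibble(object) |>
    dplyr::select("I", "mu", dplyr::all_of(fractions)) |>
    tidyr::pivot_longer(-"I", names_to = "quantity", values_to = "value") |>
    dplyr::mutate(quantity = factor(.data$quantity,
                                    levels = c("mu", fractions)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$I, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(
      x = expression(paste("light intensity (", mu, "mol photons ",
                           m^-2, s^-1, ")")),
      y = NULL,
      title = "Modelled light response and proteome allocation"
    ) +
    ggplot2::theme_minimal()
}

#' Plot clustered abundance profiles
#'
#' Normalized per-group profiles (grey) with cluster centroids (blue),
#' one panel per cluster.
#'
#' @param object A [cluster_profiles()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  prof <- as_tibble(object$profiles, rownames = "protein_id") |>
    tidyr::pivot_longer(-"protein_id", names_to = "group",
                        values_to = "value") |>
    dplyr::left_join(object$assignments, by = "protein_id")
  lev <- colnames(object$profiles)
  prof$group <- factor(prof$group, levels = lev)
  cent <- object$centroids
  cent$group <- factor(cent$group, levels = lev)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$group, y = .data$value,
                                     group = .data$protein_id)) +
    ggplot2::geom_line(alpha = 0.15, colour = "grey40") +
    ggplot2::geom_line(data = cent,
                       ggplot2::aes(group = .data$cluster),
                       colour = "#2166ac", linewidth = 1) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = "condition group", y = "normalized abundance",
                  title = sprintf("%d profile clusters", object$k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a grid fit against its observations
#'
#' Measured growth rates with uncertainties, overlaid with the model curve
#' at the best-fit parameters.
#'
#' @param object A [grid_fit()] result.
#' @param n_curve Number of intensities at which the best-fit curve is
#'   evaluated.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot growth_fit
#' @export
autoplot.growth_fit <- function(object, n_curve = 12, ...) {
  obs <- object$observations
  grid_I <- sort(unique(c(obs$light,
                          seq(min(obs$light), max(obs$light),
                              length.out = n_curve))))
  curve <- as_tibble(light_response(object$params_best, grid_I,
                                    cix = object$cix))
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$light, y = .data$mu)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$I, y = .data$mu),
                       colour = "#2166ac") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mu - .data$sd,
                                          ymax = .data$mu + .data$sd)) +
    ggplot2::labs(
      x = expression(paste("light intensity (", mu, "mol photons ",
                           m^-2, s^-1, ")")),
      y = expression(paste("specific growth rate (", h^-1, ")")),
      title = sprintf("best fit: tau = %g, kd = %g, sigma = %g (l = %.2f)",
                      object$best$tau, object$best$kd, object$best$sigma,
                      object$best$l)
    ) +
    ggplot2::theme_minimal()
}
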