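#' Plot methods
#'
#' `autoplot()` methods for the package's result types: simulator output
#' (water table, fluxes, budget panels), reconstructions (WTD with
#' bootstrap error ribbon, reversed axis so wetter is up), SCP profiles
#' and age-depth models.  All return ggplot objects.
#'
#' @param object the result to plot.
#' @param vars for simulations: which annual variables to facet.
#' @param ... unused.
#' @return a ggplot.
#' @name peatsim-plots
NULL

#' @rdname peatsim-plots
#' @method autoplot peat_simulation
#' @export
autoplot.peat_simulation <- function(object,
                                     vars = c("mean_wtd", "co2_flux",
                                              "ch4_net", "soil_c_budget"), ...) {
  long <- tidyr::pivot_longer(object$annual[, c("year", vars)],
                              -"year", names_to = "variable")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$year, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "Year", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname peatsim-plots
#' @method autoplot wtd_reconstruction
#' @export
autoplot.wtd_reconstruction <- function(object, ...) {
  xvar <- if ("age_yr" %in% names(object)) "age_yr" else "depth_cm"
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[xvar]], y = .data$wtd_pred))
  if ("se_boot" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$wtd_pred - .data$se_boot,
                   ymax = .data$wtd_pred + .data$se_boot),
      fill = "grey80")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = if (xvar == "age_yr") "Year" else "Depth (cm)",
                  y = "Water-table depth (cm)") +
    ggplot2::theme_minimal()
}

#' @rdname peatsim-plots
#' @method autoplot age_depth_model
#' @export
autoplot.age_depth_model <- function(object, ...) {
  grid <- tibble::tibble(depth_cm = seq(0, max(object$anchors$depth_cm) * 1.25,
                                        length.out = 200))
  grid$year <- age_at_depth(object, grid$depth_cm)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$year, y = .data$depth_cm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = object$anchors, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Year", y = "Depth (cm)") +
    ggplot2::theme_minimal()
}

#' Plot an SCP profile with detected markers
#'
#' @param profile tibble with `depth_cm`, `conc_per_g`.
#' @param markers optional result of [detect_scp_markers()] drawn as
#'   horizontal lines.
#' @return a ggplot.
#' @export
plot_scp_profile <- function(profile, markers = NULL) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$conc_per_g, y = .data$depth_cm)) +
    ggplot2::geom_path() + ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "SCP concentration (per g dry peat)", y = "Depth (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(markers)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(markers), linetype = "dashed")
  }
  p
}

#' Plot paired proxy and model water tables with the offset fit
#'
#' @param pairs a [pair_years()] tibble.
#' @param reg optional [fit_offset()] result drawn as the fitted line.
#' @return a ggplot.
#' @export
plot_offset <- function(pairs, reg = NULL) {
  p <- ggplot2::ggplot(pairs, ggplot2::aes(x = .data$wtd_recon, y = .data$wtd_model)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Reconstructed WTD (cm)", y = "Simulated WTD (cm)") +
    ggplot2::theme_minimal()
  if (!is.null(reg)) {
    p <- p + ggplot2::geom_abline(slope = reg$slope, intercept = reg$intercept,
                                  linetype = "dashed")
  }
  p
}
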