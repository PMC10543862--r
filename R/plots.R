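# Figures: scatter, Bland-Altman and polar electrode-mean plots.
# All return the written file path so callers can collect a manifest.

param_unit <- function(parameter) if (parameter == "emd") "mm" else "deg"

#' Scatter plot of one method against the other
#'
#' One point per (array, electrode) pair, with the line of equality.
#'
#' @param report An [agreement_report()].
#' @param path Output image path (png).
#' @return `path`, invisibly.
#' @export
plot_scatter <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  d <- report$differences
  unit <- param_unit(report$parameter)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$b, y = .data$a)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = sprintf("reference method %s (%s)", toupper(report$parameter), unit),
      y = sprintf("evaluated method %s (%s)", toupper(report$parameter), unit),
      title = sprintf("%s: r = %.3f [%.3f, %.3f]", toupper(report$parameter),
                      report$pearson_r, report$r_ci_low, report$r_ci_high)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
  invisible(path)
}

#' Bland-Altman plot with bias and limits of agreement
#'
#' Differences (evaluated minus reference) against pair means, with
#' horizontal lines at the bias and at bias +/- 1.96 SD.
#'
#' @param report An [agreement_report()].
#' @param path Output image path (png).
#' @return `path`, invisibly.
#' @export
plot_bland_altman <- function(report, path) {
  stopifnot(inherits(report, "agreement_report"))
  d <- report$differences
  unit <- param_unit(report$parameter)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = report$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(report$loa_low, report$loa_high),
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(
      x = sprintf("mean of methods (%s)", unit),
      y = sprintf("difference (%s)", unit),
      title = sprintf("%s: bias %.3f, LoA [%.3f, %.3f] %s",
                      toupper(report$parameter), report$bias,
                      report$loa_low, report$loa_high, unit)) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 4, dpi = 150)
  invisible(path)
}

#' Polar plot of per-electrode mean position by method
#'
#' For each electrode and method, the mean EMD (radius) and mean aDOI
#' (angle) pooled over arrays, drawn in the plane of the cochlear spiral
#' with the mid-modiolar axis at the origin.
#'
#' @param moving_df,reference_df Measurement tables, one method each.
#' @param path Output image path (png).
#' @return `path`, invisibly.
#' @export
plot_polar_means <- function(moving_df, reference_df, path) {
  both <- rbind(moving_df, reference_df)
  agg <- stats::aggregate(cbind(emd_mm, adoi_deg) ~ electrode + method,
                          data = both, FUN = mean)
  agg$x <- agg$emd_mm * cos(deg2rad(agg$adoi_deg))
  agg$y <- agg$emd_mm * sin(deg2rad(agg$adoi_deg))
  p <- ggplot2::ggplot(agg, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$method)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_path(ggplot2::aes(group = .data$method), alpha = 0.5) +
    ggplot2::annotate("point", x = 0, y = 0, shape = 3, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = "Per-electrode mean position (origin = mid-modiolar axis)") +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 5, height = 5, dpi = 150)
  invisible(path)
}
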