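#' Scatter plot of drug-induced change versus pre-drug baseline
#'
#' One point per ROI, colored by its drug-effect class (red = significant
#' increase, blue = significant decrease, gray = no change), with the fitted
#' regression line.
#'
#' @param effects Per-ROI effects table from \code{\link{analyze_locomotion}}.
#' @param regression Matching \code{regression_result} (optional; refitted
#'   from \code{effects} if missing).
#' @return A ggplot object.
#' @export
plot_change_vs_baseline <- function(effects, regression = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  if (is.null(regression)) regression <- regress_change_vs_baseline(effects)
  cols <- c(increase = "red", decrease = "blue", none = "gray50")
  ggplot2::ggplot(effects,
                  ggplot2::aes(x = .data$baseline, y = .data$change,
                               color = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = regression$slope,
                         intercept = regression$intercept) +
    ggplot2::scale_color_manual(values = cols, name = "drug effect") +
    ggplot2::labs(
      x = "pre-drug locomotion fluorescence (dF/F_rest)",
      y = "change after drug (dF/F_rest)",
      subtitle = sprintf("r = %.3f, R^2 = %.2f, p = %.2g, n = %d",
                         regression$r, regression$r_squared, regression$p,
                         regression$n)) +
    ggplot2::theme_classic()
}

#' Bar plot of the perisynaptic annulus density profile
#'
#' @param profile An \code{annulus_profile}.
#' @return A ggplot object.
#' @export
plot_annulus_profile <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  b <- profile$bands
  b$band_label <- factor(sprintf("%d-%d", b$lower_nm, b$upper_nm),
                         levels = sprintf("%d-%d", b$lower_nm, b$upper_nm))
  ggplot2::ggplot(b, ggplot2::aes(x = .data$band_label,
                                  y = .data$density_per_um2)) +
    ggplot2::geom_col(fill = "gray30") +
    ggplot2::labs(x = "distance from PSD edge (nm)",
                  y = expression("particle density (per " * mu * m^2 * ")")) +
    ggplot2::theme_classic()
}
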