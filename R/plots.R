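#' Plot a single-drug dose-response fit
#'
#' Points are measured mean relative counts (with SE bars when present),
#' the line is the model curve evaluated on a fine dose lattice.
#'
#' @param fit a [fit_drug_params()] result.
#' @param base the calibrated [transition_params()] used in the fit.
#' @return A ggplot object.
#' @export
plot_dose_response <- function(fit, base) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- fit$data
  pos <- d$doses[d$doses > 0]
  lattice <- c(0, 10^seq(log10(min(pos)) - 0.5, log10(max(pos)) + 0.5,
                         length.out = 60))
  p <- fit$params
  curve <- predict_counts_for_fit(base, p$target_state, lattice, p$ec50,
                                  p$hill_n, p$emax_phi, p$ec50_phi)
  offset <- min(pos) / 10   # display position for the dose-0 control
  pts <- data.frame(dose = pmax(d$doses, offset), y = d$mean_counts,
                    se = if (is.null(d$se)) NA_real_ else d$se)
  ln <- data.frame(dose = pmax(lattice, offset), y = curve)
  ggplot2::ggplot(pts, ggplot2::aes(x = dose, y = y)) +
    ggplot2::geom_line(data = ln, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = y - se, ymax = y + se),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (uM, control at left edge)",
                  y = "relative cell count at 72 h",
                  title = sprintf("%s / %s", d$drug, d$cell_line)) +
    ggplot2::theme_minimal()
}

#' Heatmap of a combination dose grid
#'
#' @param grid a [dose_grid()].
#' @return A ggplot object.
#' @export
plot_grid_heatmap <- function(grid) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  df <- data.frame(
    dose_a = factor(rep(signif(grid$doses_a, 3), times = length(grid$doses_b))),
    dose_b = factor(rep(signif(grid$doses_b, 3), each = length(grid$doses_a))),
    value = as.vector(grid$values))
  ggplot2::ggplot(df, ggplot2::aes(x = dose_b, y = dose_a, fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, max(1, df$value))) +
    ggplot2::labs(x = paste(grid$drug_b, "(uM)"), y = paste(grid$drug_a, "(uM)"),
                  fill = "relative\ncount",
                  title = paste(grid$drug_a, "x", grid$drug_b,
                                grid$cell_line %||% "")) +
    ggplot2::theme_minimal()
}

#' Scatter of predicted vs measured EOB summary scores
#'
#' @param eob_table `data.frame` with columns `pair`, `predicted`,
#'   `measured`, and optional `predicted_se`, `measured_se` (e.g. built
#'   from a [run_pipeline()] report).
#' @return A ggplot object.
#' @export
plot_eob_summary <- function(eob_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  ggplot2::ggplot(eob_table,
                  ggplot2::aes(x = predicted, y = measured, label = pair)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "model EOB", y = "experiment EOB",
                  title = "Excess over Bliss (positive = synergy)") +
    ggplot2::theme_minimal()
}
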