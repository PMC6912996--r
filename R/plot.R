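#' Calibration plot with class-wise risk histograms
#'
#' Square calibration plot: predicted risk on the x-axis, observed proportion
#' on the y-axis, the ideal diagonal as reference, the flexible calibration
#' curve with its shaded pointwise band, and at the base back-to-back
#' histograms of the predicted risks for subjects with and without the event.
#'
#' @param report A [assess_calibration()] report whose `moderate` (curve) or
#'   `weak` (recalibration line) section is estimable.
#' @param ds The underlying [validation_dataset()] (for the histograms).
#' @param path Optional file to save to (PNG/PDF by extension); when `NULL`
#'   the ggplot object is returned unsaved.
#' @param hist_height Fraction of the y-axis occupied by the histograms.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_calibration <- function(report, ds, path = NULL, hist_height = 0.12) {
  stopifnot(inherits(report, "calibration_report"),
            inherits(ds, "validation_dataset"))
  curve_ok <- !inherits(report$moderate, "not_estimable") &&
    !is.null(report$moderate)
  line_ok <- !inherits(report$weak, "not_estimable") && !is.null(report$weak)
  if (!curve_ok && !line_ok) {
    stop("nothing to plot: neither a calibration curve nor a recalibration ",
         "line is estimable", call. = FALSE)
  }
  if (curve_ok) {
    cd <- as.data.frame(report$moderate)
  } else {
    fit <- report$weak
    r <- seq(min(ds$predicted_risk), max(ds$predicted_risk), length.out = 100)
    r <- clip_risk(r, warn = FALSE)
    obs <- expit(fit$intercept$estimate + fit$slope$estimate * logit(r))
    cd <- data.frame(risk = r, observed = obs, ci_low = obs, ci_high = obs)
  }
  # back-to-back histograms at the plot base, events above the baseline,
  # non-events below
  brk <- seq(0, 1, by = 0.02)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  h1 <- graphics::hist(ds$predicted_risk[ds$outcome == 1], breaks = brk,
                       plot = FALSE)$counts
  h0 <- graphics::hist(ds$predicted_risk[ds$outcome == 0], breaks = brk,
                       plot = FALSE)$counts
  scale <- hist_height / max(c(h0, h1, 1))
  hd <- data.frame(
    mid = rep(mids, 2),
    y = c(h1 * scale, -h0 * scale),
    class = rep(c("event (1)", "non-event (0)"), each = length(mids))
  )
  gp <- ggplot2::ggplot() +
    ggplot2::geom_abline(intercept = hist_height, slope = 1,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_ribbon(
      data = cd,
      ggplot2::aes(x = risk, ymin = ci_low + hist_height,
                   ymax = ci_high + hist_height),
      fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(
      data = cd,
      ggplot2::aes(x = risk, y = observed + hist_height),
      linewidth = 0.8) +
    ggplot2::geom_col(
      data = hd,
      ggplot2::aes(x = mid, y = y, fill = class),
      width = 0.018, show.legend = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c("event (1)" = "#d95f02",
                                          "non-event (0)" = "#7570b3")) +
    ggplot2::scale_y_continuous(
      breaks = seq(0, 1, 0.25) + hist_height,
      labels = sprintf("%.2f", seq(0, 1, 0.25))) +
    ggplot2::coord_fixed(xlim = c(0, 1),
                         ylim = c(-hist_height, 1 + hist_height)) +
    ggplot2::labs(x = "Predicted risk", y = "Observed proportion",
                  fill = NULL,
                  title = sprintf("Calibration (%s)",
                                  if (curve_ok) report$moderate$method
                                  else "recalibration line")) +
    ggplot2::theme_minimal()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gp, width = 6, height = 6.5, dpi = 150)
    return(invisible(gp))
  }
  gp
}
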