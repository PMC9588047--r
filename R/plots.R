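# Diagnostic plots: field snapshots, error histograms, and condition
# summaries.  All plots use base graphics and draw to the active device.

#' Snapshot of every field in a model state
#'
#' One panel per field showing activation (blue) and sigmoided output scaled
#' to the activation axis (red), in the style of the architecture figures.
#' The 2D sensory field is shown as an image.
#'
#' @param state a state list as returned by `simulate_trial(..., keep_state
#'   = TRUE)` (the `"state"` attribute) .
#' @param model the `df_model` the state belongs to.
#' @param main overall title.
#' @export
snapshot_plot <- function(state, model, main = "field state") {
  f1d <- intersect(c("fa", "fc", "inh", "fwm", "sa", "ior", "sla"),
                   names(state))
  n_panel <- length(f1d) + 1
  old <- graphics::par(mfrow = c(ceiling(n_panel / 2), 2),
                       mar = c(2.5, 2.5, 1.5, 0.5), mgp = c(1.5, 0.4, 0))
  on.exit(graphics::par(old))
  graphics::image(site_degrees(model$ns), site_degrees(model$nc),
                  t(state$cs), xlab = "polar angle (deg)",
                  ylab = "hue (deg)", main = "CS",
                  col = grDevices::hcl.colors(64, "YlGnBu", rev = TRUE))
  for (nm in f1d) {
    u <- state[[nm]]
    beta <- model$params$fields[[nm]]$beta
    x <- site_degrees(length(u))
    ylim <- range(u, 0, 5)
    plot(x, u, type = "l", col = "blue", ylim = ylim, xlab = "deg",
         ylab = "u", main = toupper(nm))
    graphics::lines(x, df_sigmoid(u, beta) * diff(ylim) + ylim[1],
                    col = "red")
    graphics::abline(h = 0, lty = 3)
  }
  invisible(main)
}

#' Histogram of recall errors with the fitted mixture density
#'
#' @param errors recall errors in degrees.
#' @param fit optional `mixture_fit` to overlay.
#' @param main title.
#' @export
error_histogram <- function(errors, fit = NULL, main = "recall errors") {
  graphics::hist(wrap180(errors), breaks = seq(-180, 180, by = 10),
                 freq = FALSE, xlab = "signed error (deg)", main = main)
  if (!is.null(fit)) {
    x <- seq(-180, 180, by = 1)
    kappa <- kappa_from_sd(fit$sd)
    d <- (1 - fit$p_uniform) * dvonmises_deg(x, fit$mu, kappa) +
      fit$p_uniform / 360
    graphics::lines(x, d, col = "red", lwd = 2)
  }
  invisible(NULL)
}

#' Bar summary of condition-wise mixture parameters
#'
#' Three panels (bias, s.d., probability in memory) across conditions, in
#' the style of condition-summary figures.
#'
#' @param summary the `summary` element of [run_simulated_participants()].
#' @export
condition_barplot <- function(summary) {
  old <- graphics::par(mfrow = c(1, 3), mar = c(4, 3.5, 2, 0.5),
                       mgp = c(2.2, 0.6, 0))
  on.exit(graphics::par(old))
  draw <- function(v, se, lab) {
    bp <- graphics::barplot(v, names.arg = summary$condition, ylab = lab,
                            las = 2)
    graphics::arrows(bp, v - se, bp, v + se, angle = 90, code = 3,
                     length = 0.04)
  }
  draw(summary$mu, summary$mu_se, "mean bias (deg)")
  draw(summary$sd, summary$sd_se, "s.d. (deg)")
  draw(summary$p_m, summary$p_m_se, "P(in memory)")
  invisible(NULL)
}
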