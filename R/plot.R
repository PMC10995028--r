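#' Predicted outcomes by arm across the range of M*
#'
#' Plots the fitted percent-change lines for the two arms over the
#' observed M* range with pointwise 95% confidence bands and a vertical
#' line at the cross-point. Requires ggplot2.
#'
#' @param fit an [fit_interaction_model()] result.
#' @param cross_point optional cross-point to mark; computed from the fit
#'   when missing and the interaction permits.
#' @return A ggplot object.
#' @export
plot_predicted_outcomes <- function(fit, cross_point = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  lmfit <- stats::lm(pct_change ~ m_star * treat, data = fit$data)
  grid <- expand.grid(
    m_star = seq(min(fit$data$m_star), max(fit$data$m_star),
                 length.out = 100),
    treat = c(0, 1))
  pred <- stats::predict(lmfit, grid, interval = "confidence")
  grid <- cbind(grid, as.data.frame(pred))
  grid$arm <- factor(ifelse(grid$treat == 1, "CBASP", "ESC/CM"))
  if (is.null(cross_point))
    cross_point <- tryCatch(find_cross_point(fit), error = function(e) NULL)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = m_star)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lwr, ymax = upr, fill = arm), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = fit, color = arm)) +
    ggplot2::labs(x = "Composite moderator M*",
                  y = "Predicted percent change in MADRS",
                  color = "Arm", fill = "Arm")
  if (!is.null(cross_point))
    p <- p + ggplot2::geom_vline(xintercept = cross_point,
                                 linetype = "dashed")
  p
}

utils::globalVariables(c("m_star", "lwr", "upr", "arm"))
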