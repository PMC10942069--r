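utils::globalVariables(c("d_qaly", "d_cost", "lambda", "p", "arm",
                         "parameter", "icer_lo", "icer_hi"))

#' Cost-effectiveness plane of PSA draws
#'
#' Incremental QALYs against incremental cost per draw, with willingness-to-pay
#' threshold lines.
#'
#' @param psa data.frame from [run_psa_model()].
#' @param wtp willingness-to-pay thresholds (VND/QALY) drawn as lines.
#' @return a ggplot object.
#' @export
plot_psa_plane <- function(psa, wtp = c(83e6, 249e6)) {
  ggplot2::ggplot(psa, ggplot2::aes(x = d_qaly, y = d_cost / 1e6)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6) +
    ggplot2::geom_abline(intercept = 0, slope = wtp / 1e6, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALYs per person",
                  y = "Incremental cost (million VND per person)",
                  title = "Cost-effectiveness plane")
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ce data.frame from [ceac()].
#' @return a ggplot object.
#' @export
plot_ceac <- function(ce) {
  long <- rbind(
    data.frame(lambda = ce$lambda, p = ce$p_trastuzumab, arm = "trastuzumab + chemo"),
    data.frame(lambda = ce$lambda, p = ce$p_chemo, arm = "chemo alone")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = lambda / 1e6, y = p, colour = arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay (million VND per QALY)",
                  y = "Probability cost-effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram
#'
#' @param tor data.frame from [tornado()].
#' @param base_icer deterministic base-case ICER (VND/QALY) for the reference
#'   line.
#' @param top show only the `top` widest parameters (default all).
#' @return a ggplot object.
#' @export
plot_tornado <- function(tor, base_icer, top = nrow(tor)) {
  df <- tor[tor$valid & seq_len(nrow(tor)) <= top, ]
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(y = parameter, yend = parameter,
                                       x = icer_lo / 1e6, xend = icer_hi / 1e6),
                          linewidth = 3, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer / 1e6, linetype = "dashed") +
    ggplot2::labs(x = "ICER (million VND per QALY)", y = NULL,
                  title = "One-way sensitivity analysis")
}
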