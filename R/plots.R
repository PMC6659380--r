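# ggplot2 views of MR instrument sets, grids and power curves.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter plot of an MR instrument set
#'
#' Plots SNP-outcome against SNP-exposure effects for one arm of a
#' harmonized instrument set, with the IVW (through the origin) and
#' MR-Egger fitted lines.
#'
#' @param object A harmonized-instrument tibble from
#'   [harmonize_instruments()] (or the `"instruments"` attribute of an
#'   [mr_pipeline()] result).
#' @param arm `"maternal"` or `"offspring"`: which partitioned outcome
#'   effect to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_instruments <- function(object, arm = c("maternal", "offspring"),
                             ...) {
  arm <- match.arg(arm)
  beta_out <- if (arm == "maternal") object$beta_out_m else
    object$beta_out_o
  se_out <- if (arm == "maternal") object$se_out_m else object$se_out_o
  flip <- sign(object$beta_exp)
  flip[flip == 0] <- 1
  df <- tibble::tibble(beta_exp = object$beta_exp * flip,
                       beta_out = beta_out * flip, se_out = se_out)
  ratios <- wald_ratio(df$beta_out, df$se_out, df$beta_exp)
  ivw <- mr_ivw(ratios)
  eg <- if (nrow(df) >= 3) mr_egger(df) else NULL
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_exp,
                                        y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - se_out,
                                        ymax = .data$beta_out + se_out),
                           linewidth = 0.2, colour = "grey70") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_abline(intercept = 0, slope = ivw$estimate,
                         colour = "steelblue") +
    ggplot2::labs(x = "SNP-exposure effect",
                  y = paste0("Conditional ", arm, " SNP-outcome effect"),
                  title = paste0(toupper(substr(arm, 1, 1)),
                                 substr(arm, 2, nchar(arm)),
                                 " arm: IVW (blue)",
                                 if (!is.null(eg)) " and Egger (dashed)"))
  if (!is.null(eg)) {
    p <- p + ggplot2::geom_abline(intercept = eg$egger_intercept,
                                  slope = eg$estimate,
                                  colour = "firebrick",
                                  linetype = "dashed")
  }
  p
}

#' @rdname plot_instruments
#' @method autoplot mr_grid
#' @export
autoplot.mr_grid <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$estimate))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$method,
                                   colour = .data$adjustment)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$se,
                   xmax = .data$estimate + 1.96 * .data$se),
      height = 0.2, position = ggplot2::position_dodge(0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~arm) +
    ggplot2::labs(x = "Causal estimate (outcome units per exposure unit)",
                  y = NULL)
}

#' Plot power curves
#'
#' @param data A tibble from [power_curve()].
#' @return A ggplot object.
#' @export
plot_power_curve <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$q_m, y = .data$power,
                                     colour = .data$design)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Variance explained by the maternal effect",
                  y = "Power", colour = "Design") +
    ggplot2::ylim(0, 1)
}
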