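#' Plot a tag-density or metagene profile
#'
#' Line plot of mean tag value per bin against the offset from the profile
#' center (annotation midpoint or TSS/TES).
#'
#' @param object A `cha_profile` tibble from [density_profile()] or
#'   [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cha_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$offset, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "offset from center (bp)", y = "mean tag density") +
    ggplot2::theme_classic()
}

#' Plot the loop-degree distribution of regulatory units
#'
#' Histogram of CHA loop counts per promoter, with the hub threshold drawn
#' as a dashed line.
#'
#' @param object A `cha_regulatory_units` table from [call_hubs()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cha_regulatory_units <- function(object, ...) {
  thr <- attr(object, "hub_threshold")
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(x = .data$loop_count)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey55",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = thr - 0.5, linetype = 2) +
    ggplot2::labs(x = "CHA loops converging on promoter",
                  y = "promoters") +
    ggplot2::theme_classic()
}

#' Plot per-instrument Wald ratios behind an IVW estimate
#'
#' Exposure effects against outcome effects, one point per instrument,
#' with the fitted causal slope through the origin.
#'
#' @param object A `cha_mr` object from [ivw_mr()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cha_mr <- function(object, ...) {
  r <- object$ratios
  ggplot2::ggplot(r, ggplot2::aes(x = .data$beta_exp, y = .data$beta_out)) +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::geom_abline(intercept = 0, slope = object$beta,
                         colour = "firebrick") +
    ggplot2::labs(x = "effect on expression (exposure)",
                  y = "effect on trait (outcome)",
                  title = sprintf("IVW beta = %.3f (SE %.3f)",
                                  object$beta, object$se)) +
    ggplot2::theme_classic()
}
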