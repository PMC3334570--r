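#' Plot an LD decay curve
#'
#' Line plot of a distance-binned LD summary ([average_r2_curve()] or
#' [mean_max_r2_curve()]); empty bins (`n = 0`) are omitted.
#'
#' @param object An `ld_curve`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ld_curve <- function(object, ...) {
  stat <- attr(object, "stat") %||% "r2"
  d <- filter(as_tibble(object), n > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = (bin_start + bin_width / 2) / 1000,
                                  y = value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8, colour = "steelblue") +
    ggplot2::labs(x = "distance (kb)",
                  y = if (stat == "mean_max_r2") expression(mean ~ max ~ r^2)
                      else expression(average ~ r^2)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot tagging percentages
#'
#' Grouped bar chart of the percentage of focal variants tagged at each LD
#' threshold, per stratum.
#'
#' @param object A `tagging_table` from [tagging_summary()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.tagging_table <- function(object, ...) {
  d <- mutate(as_tibble(object),
              threshold = factor(threshold))
  ggplot2::ggplot(d, ggplot2::aes(x = stratum, y = percent, fill = threshold)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of focal variants tagged",
                  fill = expression(r^2 ~ threshold)) +
    ggplot2::theme_minimal()
}

#' Plot the r-squared-binned imputation experiment
#'
#' Per-genotype-class concordance against the r-squared bin used for
#' imputation — the qualitative picture of imputation power rising with LD.
#'
#' @param object An `r2_binned_concordance` from [r2_binned_concordance()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.r2_binned_concordance <- function(object, ...) {
  d <- tidy(object)
  d <- tidyr::pivot_longer(select(d, r2_low, r2_high, refref, refalt, altalt),
                           c(refref, refalt, altalt),
                           names_to = "class", values_to = "concordance")
  d <- filter(d, !is.na(concordance))
  ggplot2::ggplot(d, ggplot2::aes(x = (r2_low + r2_high) / 2, y = concordance,
                                  colour = class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = expression(r^2 ~ bin), y = "concordance") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
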