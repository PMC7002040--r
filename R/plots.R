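# ggplot2 figure helpers; cosmetic only, never load-bearing

#' Scatter plot of TE scores in two conditions
#'
#' @param te A classified TE tibble (see [change_in_te()] /
#'   [classify_te_shift()]).
#' @param knockdown,control Condition names.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_te_scatter <- function(te, knockdown = "knockdown", control = "control", ...) {
  kd <- paste0("te_", knockdown)
  ct <- paste0("te_", control)
  p <- ggplot(as_tibble(te), aes(x = .data[[ct]], y = .data[[kd]]))
  if ("shift_class" %in% names(te)) {
    p <- p + geom_point(aes(colour = .data$shift_class), alpha = 0.5, size = 0.8) +
      scale_colour_manual(values = c(down = "#3366bb", none = "grey60",
                                     up = "#bb3333"), na.value = "grey85")
  } else {
    p <- p + geom_point(alpha = 0.5, size = 0.8)
  }
  p + scale_x_log10() + scale_y_log10() +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey40") +
    labs(x = paste("TE,", control), y = paste("TE,", knockdown),
         colour = "shift") +
    theme_minimal()
}

#' @method autoplot te_result
#' @export
autoplot.te_result <- function(object, ...) plot_te_scatter(object, ...)

#' Binned feature profile plot
#'
#' @param bins Output of [bin_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_bin_profile <- function(bins, ...) {
  ggplot(filter(bins, .data$n > 0),
         aes(x = .data$bin_mid, y = .data$feature_mean)) +
    geom_errorbar(aes(ymin = .data$feature_mean - .data$feature_se,
                      ymax = .data$feature_mean + .data$feature_se),
                  width = 0.1, colour = "grey50", na.rm = TRUE) +
    geom_point(aes(size = .data$n), colour = "#3366bb") +
    scale_size_area(max_size = 4) +
    labs(x = "log2 change in TE (bin midpoint)", y = "feature mean",
         size = "transcripts") +
    theme_minimal()
}

#' Volcano plot of a differential-proteomics result
#'
#' log2 fold change against -log10 q (q floored at one tenth of the smallest
#' nonzero q so that q = 0 stays plottable); significant proteins coloured.
#'
#' @param object An `s0_test_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot s0_test_result
#' @export
autoplot.s0_test_result <- function(object, ...) {
  q <- object$q
  floor_q <- min(q[q > 0], 1) / 10
  df <- mutate(as_tibble(object), neg_log_q = -log10(pmax(.data$q, floor_q)))
  ggplot(df, aes(x = .data$log2_fc, y = .data$neg_log_q,
                 colour = .data$significant)) +
    geom_point(alpha = 0.6, size = 0.9) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "#bb3333")) +
    labs(x = "log2 fold change", y = "-log10 q (permutation FDR)",
         colour = "significant") +
    theme_minimal()
}

#' @rdname autoplot.s0_test_result
#' @export
plot_volcano <- function(object, ...) autoplot.s0_test_result(object, ...)

#' Stacked organelle mass-fraction plot
#'
#' @param fractions Output of [organelle_mass_fractions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_organelle_fractions <- function(fractions, ...) {
  ggplot(fractions, aes(x = .data$sample, y = .data$percent,
                        fill = .data$compartment)) +
    geom_col() +
    labs(x = NULL, y = "% of total protein mass", fill = "compartment") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
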