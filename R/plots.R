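#' Plot microstate template topographies
#'
#' Schematic scalp maps: electrodes at their 2-D montage positions, coloured
#' by potential, one panel per class, with the head outline. Polarity is
#' arbitrary (microstate maps are defined up to sign).
#'
#' @param object An `ms_templates` matrix (needs a montage attribute, as
#'   produced by [prototype_maps()]; for fitted templates pass the montage
#'   via `montage`).
#' @param montage Montage to use when the object carries none.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ms_templates
#' @export
autoplot.ms_templates <- function(object, montage = montage_1020(), ...) {
  if (is.null(attr(object, "montage"))) attr(object, "montage") <- montage
  df <- tidy.ms_templates(object)
  circle <- tibble::tibble(theta = seq(0, 2 * pi, length.out = 181),
                           x = cos(.data$theta), y = sin(.data$theta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = circle, linewidth = 0.3, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(fill = .data$value), shape = 21, size = 5) +
    ggplot2::scale_fill_gradient2(low = "black", mid = "white", high = "red") +
    ggplot2::facet_wrap(~class, nrow = 1) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "map (a.u.)")
}

#' Plot group microstate profiles
#'
#' Group mean with standard-error bars per class, one panel per measure
#' (duration, occurrence, coverage), mirroring the conventional microstate
#' statistics figure.
#'
#' @param profiles Long profile tibble (e.g. `report$profiles`).
#' @return A ggplot object.
#' @export
plot_profiles <- function(profiles) {
  long <- profiles |>
    tidyr::pivot_longer(c("duration_ms", "occurrence", "coverage"),
                        names_to = "measure", values_to = "value") |>
    dplyr::group_by(.data$group, .data$class, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value, na.rm = TRUE),
                     se = sd(.data$value, na.rm = TRUE) /
                       sqrt(sum(is.finite(.data$value))),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$mean,
                                     colour = .data$group,
                                     group = .data$group)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2,
                           position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "microstate class", y = NULL, colour = NULL)
}

#' Plot per-transition t values
#'
#' Bar chart of the between-group t statistic for each doublet or triplet
#' sequence, with dashed lines at the two-tailed 5% critical values.
#' Positive t means a higher transition fraction in the first group level.
#'
#' @param syntax_tests Output of [syntax_ttests()].
#' @param type `"doublet"` or `"triplet"`.
#' @return A ggplot object.
#' @export
plot_syntax_t <- function(syntax_tests, type = c("doublet", "triplet")) {
  type <- match.arg(type)
  d <- syntax_tests[syntax_tests$type == type & is.finite(syntax_tests$t), ]
  crit <- qt(0.975, max(d$df))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$sequence, y = .data$t)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = c(-crit, crit), linetype = "dashed") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) +
    ggplot2::labs(x = NULL, y = "t value")
}

#' @method autoplot ms_report
#' @export
autoplot.ms_report <- function(object, ...) plot_profiles(object$profiles)
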