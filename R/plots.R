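#' Plot a fitted dose-response curve over its data
#'
#' @param object A `hill_fit` or `sigmoid_fit`.
#' @param n_grid Curve evaluation points.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_fit <- function(object, n_grid = 200, ...) {
  dat <- object$data
  lab <- if (inherits(object, "hill_fit")) {
    c("dose", "response", "Hill fit")
  } else {
    c("C-CDK level (AU)", "CDK activity (N/C)", "Sigmoid fit")
  }
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(colour = "grey30") +
    ggplot2::labs(x = lab[1], y = lab[2], title = lab[3]) +
    ggplot2::theme_minimal()
  if (object$converged) {
    pos <- dat$x[dat$x > 0]
    grid <- exp(seq(log(min(pos)), log(max(dat$x)), length.out = n_grid))
    curve <- tibble(x = grid, y = predict(object, tibble(x = grid)))
    p <- p + ggplot2::geom_line(data = curve, colour = "firebrick") +
      ggplot2::scale_x_log10()
  }
  p
}

#' Plot a P(Div) hazard curve
#'
#' @param object A `pdiv_curve` from [estimate_pdiv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pdiv_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$bin_mid, y = .data$rate_per_min)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_timepoints),
                        alpha = 0.8) +
    ggplot2::geom_line(linetype = 2, colour = "grey50") +
    ggplot2::labs(x = attr(object, "bin_var"), y = "P(Div) (per min)",
                  size = "timepoints") +
    ggplot2::theme_minimal()
}

#' Plot size-binned threshold curves, marking capped (undefined) bins
#'
#' @param object A `threshold_curve` (or `synergy_decomposition` via
#'   [plot_synergy()]).
#' @param cap Level drawn for undefined bins (default 1000 AU).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.threshold_curve <- function(object, cap = 1000, ...) {
  df <- mutate(object,
               shown = ifelse(.data$defined, .data$threshold_level_au, cap))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$shown)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$defined), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "cell length (um)",
                  y = "C-CDK threshold level (AU)",
                  shape = "defined") +
    ggplot2::theme_minimal()
}

#' Bar plot of the synergy decomposition across size bins
#'
#' @param decomposition A `synergy_decomposition` from
#'   [decompose_synergy()].
#' @return A ggplot with one bar group per size bin: the individual
#'   regulatory contributions and the synergy remainder.
#' @export
plot_synergy <- function(decomposition) {
  long <- decomposition %>%
    select("bin_mid", "contrib_yphos_pp2a", "contrib_yphos_alone",
           "contrib_pp2a_alone", "synergy") %>%
    tidyr::pivot_longer(-"bin_mid", names_to = "component",
                        values_to = "contribution")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(round(.data$bin_mid, 1)),
                                     y = .data$contribution,
                                     fill = .data$component)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "cell length bin (um)",
                  y = "C-CDK level restricted (AU)") +
    ggplot2::theme_minimal()
}

#' Plot a bistability profile: max gradient vs length and residuals
#'
#' @param object A `bistability_profile`.
#' @param ... Unused.
#' @return A ggplot of max gradient against size-bin centre with the
#'   fitted regression line.
#' @export
autoplot.bistability_profile <- function(object, ...) {
  df <- filter(object$by_bin, is.finite(.data$max_gradient))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid,
                                        y = .data$max_gradient)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "cell length bin (um)",
                  y = "max gradient (activity / AU)") +
    ggplot2::theme_minimal()
  if (!is.null(object$regression)) {
    p <- p + ggplot2::geom_abline(intercept = object$regression$intercept,
                                  slope = object$regression$slope,
                                  colour = "firebrick", linetype = 2)
  }
  p
}

#' Plot lineage traces with detected events
#'
#' @param traces A `lineage_traces` object.
#' @param cells Optional subset of cell ids (default first 6).
#' @return A ggplot of size and level traces with event markers.
#' @export
plot_lineages <- function(traces, cells = NULL) {
  stopifnot(inherits(traces, "lineage_traces"))
  ids <- cells %||% head(unique(traces$frames$cell_id), 6)
  fr <- filter(traces$frames, .data$cell_id %in% ids)
  ev <- filter(traces$events, .data$cell_id %in% ids)
  ev <- dplyr::left_join(ev, select(fr, "cell_id", "frame", "level_au"),
                         by = c("cell_id", "frame"))
  ggplot2::ggplot(fr, ggplot2::aes(x = .data$time_min)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$level_au), colour = "purple") +
    ggplot2::geom_line(ggplot2::aes(y = .data$size * 30), colour = "orange") +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$time_min,
                                     linetype = .data$kind),
                        alpha = 0.5) +
    ggplot2::facet_wrap(~cell_id) +
    ggplot2::scale_y_continuous(
      name = "C-CDK level (AU)",
      sec.axis = ggplot2::sec_axis(~. / 30, name = "length (um)")) +
    ggplot2::theme_minimal()
}
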