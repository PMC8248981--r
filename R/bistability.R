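#' Mean activity vs level curve within one size bin
#'
#' Plain within-bin mean of CDK activity per C-CDK level bin. Where the
#' single-cell response is bimodal (on/off mixture) this mean averages the
#' two subpopulations, so the steepness of this curve reflects how sharply
#' the population switches from off to on as level rises.
#'
#' @param records Cell records (already restricted to one size bin if
#'   desired).
#' @param level_bin_width Level bin width in AU (default 100).
#' @param min_bins Minimum occupied level bins (default 3).
#' @return Tibble `level_mid`, `n`, `mean_activity`.
#' @export
mean_activity_curve <- function(records, level_bin_width = 100,
                                min_bins = 3) {
  df <- filter(records, is.finite(.data$cdk_level_au),
               is.finite(.data$activity_nc))
  if (!nrow(df)) abort("no records", class = "cdkflow_empty_result")
  lo <- floor(min(df$cdk_level_au) / level_bin_width) * level_bin_width
  out <- df %>%
    mutate(.bin = floor((.data$cdk_level_au - lo) / level_bin_width)) %>%
    group_by(.data$.bin) %>%
    summarise(n = dplyr::n(), mean_activity = mean(.data$activity_nc),
              .groups = "drop") %>%
    mutate(level_mid = lo + (.data$.bin + 0.5) * level_bin_width) %>%
    select("level_mid", "n", "mean_activity") %>%
    arrange(.data$level_mid)
  if (nrow(out) < min_bins) {
    abort(sprintf("only %d occupied level bins (need >= %d)", nrow(out),
                  min_bins),
          class = "cdkflow_insufficient_data")
  }
  out
}

#' Maximum gradient of a mean activity curve
#'
#' Fits a smoothing spline (generalised cross-validation by default) to
#' mean activity vs level and returns the maximum first derivative over
#' the observed level range. Steep maximum gradients indicate switch-like
#' (bistable) activation; shallow gradients a graded response.
#'
#' @param curve Tibble with `level_mid` and `mean_activity` (from
#'   [mean_activity_curve()]), or any two-column numeric data frame
#'   (x, y).
#' @param spar Optional fixed smoothing parameter for reproducibility;
#'   `NULL` = GCV.
#' @param n_grid Evaluation grid size for the derivative.
#' @param trim Fraction of the level range dropped from each end before
#'   taking the derivative maximum (default 0.05): spline derivatives are
#'   unreliable at the boundary, and a response curve that ends
#'   mid-transition would otherwise report an edge artefact.
#' @return List with `max_gradient`, `at_level`, and `method`
#'   (`"spline"` or `"finite_diff"` when the spline fit fails).
#' @export
max_gradient <- function(curve, spar = NULL, n_grid = 200, trim = 0.05) {
  x <- curve$level_mid %||% curve[[1]]
  y <- curve$mean_activity %||% curve[[2]]
  if (length(x) < 4) {
    abort("need >= 4 curve points", class = "cdkflow_insufficient_data")
  }
  span <- diff(range(x))
  grid <- seq(min(x) + trim * span, max(x) - trim * span,
              length.out = n_grid)
  sp <- tryCatch({
    fit <- if (is.null(spar)) smooth.spline(x, y) else
      smooth.spline(x, y, spar = spar)
    d <- predict(fit, grid, deriv = 1)$y
    list(g = max(d), at = grid[which.max(d)], method = "spline")
  }, error = function(e) NULL)
  if (is.null(sp)) {
    d <- diff(y) / diff(x)
    sp <- list(g = max(d), at = x[which.max(d)], method = "finite_diff")
  }
  list(max_gradient = max(sp$g, 0), at_level = sp$at, method = sp$method)
}

#' Regression of maximum gradients on cell length, with residual structure
#'
#' Ordinary least squares of per-size-bin maximum gradient against bin
#' length; residuals are actual minus predicted. Structured (non-linear)
#' residuals indicate that the gradient's size dependence is not linear —
#' the signature of bistable activation sharpening with size. The
#' `nonlinearity_score` is the lag-1 autocorrelation of residuals ordered
#' by length: independent residuals score near 0, a smooth curved trend
#' scores high.
#'
#' @param max_gradients Numeric vector, one per size bin.
#' @param lengths Bin centres (same length, >= 4).
#' @return List with `slope`, `intercept`, `residuals` (tibble with
#'   `length`, `actual`, `predicted`, `residual`), `nonlinearity_score`.
#' @export
gradient_residuals <- function(max_gradients, lengths) {
  if (length(max_gradients) != length(lengths) || length(lengths) < 4) {
    abort("need >= 4 size bins", class = "cdkflow_insufficient_data")
  }
  ord <- order(lengths)
  x <- lengths[ord]; y <- max_gradients[ord]
  fit <- lm(y ~ x)
  res <- resid(fit)
  score <- if (sd(res) < .Machine$double.eps^0.25 * max(1, sd(y))) 0 else {
    r <- res - mean(res)
    sum(head(r, -1) * tail(r, -1)) / sum(r^2)
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       residuals = tibble(length = x, actual = y,
                          predicted = unname(predict(fit)),
                          residual = unname(res)),
       nonlinearity_score = score)
}

#' Bistability profile across size bins
#'
#' Full per-size-bin switch-likeness analysis: mean activity vs level
#' curve and its spline maximum gradient per size bin, then the
#' linear-regression residual analysis of gradient vs length.
#'
#' @param records Cell records.
#' @param size_var Size column (default `"length_um"`).
#' @param size_bin_width Size bin width (default 1 um).
#' @param level_bin_width Level bin width (default 100 AU).
#' @param min_n Minimum cells per size bin.
#' @param spar Optional fixed spline smoothing parameter.
#' @return A `bistability_profile`: list with `by_bin` (tibble: `bin_mid`,
#'   `n`, `max_gradient`, `method`), `regression`
#'   (from [gradient_residuals()], `NULL` if < 4 usable bins) and the
#'   parameters used.
#' @export
bistability_profile <- function(records, size_var = "length_um",
                                size_bin_width = 1, level_bin_width = 100,
                                min_n = 50, spar = NULL) {
  df <- filter(records, is.finite(.data[[size_var]]))
  if ("gated" %in% names(df)) df <- filter(df, .data$gated)
  lo <- floor(min(df[[size_var]]) / size_bin_width) * size_bin_width
  df$.bin <- floor((df[[size_var]] - lo) / size_bin_width)
  by_bin <- purrr::map_dfr(sort(unique(df$.bin)), function(b) {
    sub <- df[df$.bin == b, ]
    if (nrow(sub) < min_n) {
      return(tibble(bin_mid = lo + (b + 0.5) * size_bin_width, n = nrow(sub),
                    max_gradient = NA_real_, method = "low_n"))
    }
    mg <- tryCatch({
      curve <- mean_activity_curve(sub, level_bin_width)
      max_gradient(curve, spar = spar)
    }, error = function(e) NULL)
    tibble(bin_mid = lo + (b + 0.5) * size_bin_width, n = nrow(sub),
           max_gradient = mg$max_gradient %||% NA_real_,
           method = mg$method %||% "failed")
  })
  usable <- filter(by_bin, is.finite(.data$max_gradient))
  reg <- if (nrow(usable) >= 4) {
    gradient_residuals(usable$max_gradient, usable$bin_mid)
  }
  structure(list(by_bin = by_bin, regression = reg,
                 params = list(size_var = size_var,
                               size_bin_width = size_bin_width,
                               level_bin_width = level_bin_width)),
            class = "bistability_profile")
}

#' @export
print.bistability_profile <- function(x, ...) {
  cat("<bistability_profile>", nrow(x$by_bin), "size bins\n")
  if (!is.null(x$regression)) {
    cat(sprintf("  gradient ~ length slope %.4g, nonlinearity score %.3f\n",
                x$regression$slope, x$regression$nonlinearity_score))
  }
  invisible(x)
}
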