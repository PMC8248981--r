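#' Hill dose-response model
#'
#' Four-parameter Hill curve with a signed Hill coefficient:
#' \deqn{y = bottom + \frac{top - bottom}{1 + (dose/IC_{50})^{-h}}}
#' A negative `hill_coef` gives a decreasing response (inhibitor), so at
#' dose 0 the response is `top` and at saturating dose it is `bottom`; at
#' `dose = ic50` the response is the plateau midpoint for any coefficient.
#'
#' @param dose Non-negative dose vector.
#' @param ic50 Half-maximal dose (> 0).
#' @param hill_coef Signed Hill coefficient (non-zero).
#' @param top,bottom Response plateaus.
#' @return Response vector.
#' @examples
#' hill_model(115.4, ic50 = 115.4, hill_coef = -1.71, top = 1, bottom = 0)
#' @export
hill_model <- function(dose, ic50, hill_coef, top = 1, bottom = 0) {
  if (any(dose < 0)) abort("doses must be non-negative",
                           class = "cdkflow_domain_error")
  check_pos(ic50, "ic50")
  ratio <- (dose / ic50)^(-hill_coef)
  bottom + (top - bottom) / (1 + ratio)
}

#' Sigmoid activity-vs-level model
#'
#' Increasing logistic in the C-CDK level:
#' \deqn{y = bottom + \frac{top - bottom}{1 + (EC_{50}/level)^{slope}}}
#'
#' @param level Positive level vector (AU).
#' @param ec50 Half-activation level (> 0).
#' @param slope Steepness (> 0).
#' @param top,bottom Activity plateaus.
#' @return Activity vector.
#' @export
sigmoid_model <- function(level, ec50, slope, top = 1, bottom = 0) {
  check_pos(ec50, "ec50")
  check_pos(slope, "slope")
  bottom + (top - bottom) / (1 + (ec50 / level)^slope)
}

#' Fit a Hill curve to dose-response data
#'
#' Least-squares fit of [hill_model()] by Levenberg-Marquardt with
#' multi-start initialisation: the IC50 is started at the dose bracketing
#' the half-range crossing of the response, slopes from
#' `c(0.5, 1, 2, 4)` in the direction implied by the data trend, and the
#' best residual sum of squares wins. Internally the optimiser works on
#' `log(ic50)` and `|h|` with a direction flag; the returned coefficient is
#' signed. Flat data (response range below twice a robust noise estimate)
#' returns `converged = FALSE` rather than an arbitrary fit.
#'
#' @param doses,responses Numeric vectors (>= 4 distinct doses).
#' @param init Optional named list overriding starting values (`ic50`,
#'   `hill_coef`, `top`, `bottom`).
#' @param fix_top Optional value to pin the top plateau (e.g. 1 after
#'   normalisation to a reference maximum); `NULL` fits it freely.
#' @return A `hill_fit` object with coefficients `ic50`, `hill_coef`,
#'   `top`, `bottom`, plus `rss` and `converged`. Supports [tidy()],
#'   [glance()], [predict()] and [autoplot()].
#' @examples
#' d <- c(0, 31.25, 62.5, 125, 250, 500, 1000)
#' y <- hill_model(d, 115.4, -1.71, top = 1, bottom = 0)
#' fit_hill(d, y)
#' @export
fit_hill <- function(doses, responses, init = NULL, fix_top = NULL) {
  check_fit_input(doses, responses)
  fit_logistic_core(x = doses, y = responses, model = "hill", init = init,
                    fix_top = fix_top)
}

#' Fit a sigmoid to activity-vs-level data
#'
#' Same fitting machinery as [fit_hill()] for the increasing
#' [sigmoid_model()] used for CDK activity against C-CDK level; reports
#' `ec50` and a positive `slope`.
#'
#' @param levels,activities Numeric vectors (>= 4 distinct levels, > 0).
#' @inheritParams fit_hill
#' @return A `sigmoid_fit` object (same interface as `hill_fit`).
#' @examples
#' l <- exp(seq(log(10), log(2000), length.out = 30))
#' a <- sigmoid_model(l, ec50 = 372, slope = 2, top = 10, bottom = 1)
#' fit_sigmoid(l, a)
#' @export
fit_sigmoid <- function(levels, activities, init = NULL, fix_top = NULL) {
  check_fit_input(levels, activities)
  if (any(levels <= 0)) {
    abort("levels must be positive", class = "cdkflow_domain_error")
  }
  fit_logistic_core(x = levels, y = activities, model = "sigmoid",
                    init = init, fix_top = fix_top)
}

check_fit_input <- function(x, y) {
  if (length(x) != length(y) || any(!is.finite(y)) || any(!is.finite(x))) {
    abort("doses/responses must be finite and of equal length",
          class = "cdkflow_domain_error")
  }
  if (length(unique(x)) < 4) {
    abort("need at least 4 distinct dose/level values",
          class = "cdkflow_insufficient_data")
  }
}

# shared LM fit on log(ec50), log(|slope|) with a direction flag
fit_logistic_core <- function(x, y, model, init = NULL, fix_top = NULL) {
  cls <- if (model == "hill") "hill_fit" else "sigmoid_fit"
  # flat-data guard: range must exceed twice a robust noise estimate
  noise <- mad(diff(y[order(x)])) / sqrt(2)
  if (diff(range(y)) <
      max(2 * noise, .Machine$double.eps^0.5 * max(1, max(abs(y))))) {
    return(new_response_fit(cls, ic50 = NA_real_, hill = NA_real_,
                            top = max(y), bottom = min(y), rss = NA_real_,
                            converged = FALSE, x = x, y = y))
  }
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  increasing <- model == "sigmoid" ||
    coef(lm(ys ~ xs))[2] >= 0
  direction <- if (increasing) 1 else -1

  # ic50 start: dose bracketing the half-range crossing
  halfy <- (max(ys) + min(ys)) / 2
  cross <- which(diff(sign(ys - halfy)) != 0)
  x_pos <- xs[xs > 0]
  ic_starts <- unique(c(
    if (length(cross)) sqrt(pmax(xs[cross], min(x_pos)) *
                              xs[pmin(cross + 1, length(xs))]),
    stats::median(x_pos)))
  ic_starts <- ic_starts[is.finite(ic_starts) & ic_starts > 0]
  slope_starts <- c(0.5, 1, 2, 4)
  if (!is.null(init)) {
    if (!is.null(init$ic50)) ic_starts <- c(init$ic50, ic_starts)
    if (!is.null(init$ec50)) ic_starts <- c(init$ec50, ic_starts)
    sl <- init$hill_coef %||% init$slope
    if (!is.null(sl)) slope_starts <- c(abs(sl), slope_starts)
  }

  top0 <- fix_top %||% max(ys)
  bot0 <- min(ys)
  best <- NULL
  for (ic0 in ic_starts) for (s0 in slope_starts) {
    fit <- try_lm_fit(xs, ys, log(ic0), log(s0), top0, bot0, direction,
                      fix_top)
    if (!is.null(fit) && (is.null(best) || fit$rss < best$rss)) best <- fit
  }
  if (is.null(best)) {
    return(new_response_fit(cls, ic50 = NA_real_, hill = NA_real_,
                            top = top0, bottom = bot0, rss = NA_real_,
                            converged = FALSE, x = x, y = y))
  }
  new_response_fit(cls, ic50 = best$ic50, hill = direction * best$slope,
                   top = best$top, bottom = best$bottom, rss = best$rss,
                   converged = TRUE, x = x, y = y)
}

try_lm_fit <- function(xs, ys, lic0, lsl0, top0, bot0, direction, fix_top) {
  fn <- function(p) {
    ic <- exp(p[1]); sl <- exp(p[2])
    top <- if (is.null(fix_top)) p[3] else fix_top
    bot <- if (is.null(fix_top)) p[4] else p[3]
    pred <- bot + (top - bot) / (1 + (xs / ic)^(-direction * sl))
    pred[xs == 0] <- if (direction < 0) top else bot
    ys - pred
  }
  p0 <- if (is.null(fix_top)) c(lic0, lsl0, top0, bot0) else
    c(lic0, lsl0, bot0)
  out <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(out) || !all(is.finite(out$par))) return(NULL)
  p <- out$par
  list(ic50 = exp(p[1]), slope = exp(p[2]),
       top = if (is.null(fix_top)) p[3] else fix_top,
       bottom = if (is.null(fix_top)) p[4] else p[3],
       rss = sum(fn(p)^2))
}

new_response_fit <- function(cls, ic50, hill, top, bottom, rss, converged,
                             x, y) {
  structure(list(ic50 = ic50, hill_coef = hill, top = top, bottom = bottom,
                 rss = rss, converged = converged,
                 data = tibble(x = x, y = y)),
            class = c(cls, "response_fit"))
}

#' @export
print.response_fit <- function(x, ...) {
  lab <- if (inherits(x, "hill_fit")) c("IC50", "Hill coefficient") else
    c("EC50", "slope")
  cat(sprintf("<%s> %s = %.4g, %s = %.4g, top = %.4g, bottom = %.4g\n",
              class(x)[1], lab[1], x$ic50, lab[2], x$hill_coef,
              x$top, x$bottom))
  cat(sprintf("  rss = %.4g, converged = %s, n = %d\n", x$rss, x$converged,
              nrow(x$data)))
  invisible(x)
}

#' @export
predict.response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    (newdata$x %||% newdata[[1]])
  if (!object$converged) return(rep(NA_real_, length(x)))
  pred <- object$bottom + (object$top - object$bottom) /
    (1 + (x / object$ic50)^(-object$hill_coef))
  pred[x == 0] <- if (object$hill_coef < 0) object$top else object$bottom
  pred
}

#' @rdname fit_hill
#' @param x A `hill_fit` or `sigmoid_fit`.
#' @param ... Unused.
#' @export
tidy.response_fit <- function(x, ...) {
  nms <- if (inherits(x, "hill_fit")) c("ic50", "hill_coef") else
    c("ec50", "slope")
  tibble(term = c(nms, "top", "bottom"),
         estimate = c(x$ic50, x$hill_coef, x$top, x$bottom))
}

#' @rdname fit_hill
#' @export
glance.response_fit <- function(x, ...) {
  tibble(rss = x$rss, converged = x$converged, nobs = nrow(x$data))
}

#' Normalise values to a reference (DMSO) maximum
#'
#' Divides values by the median of the reference set, so the reference
#' median maps to 1. Used to express maximum CDK activity relative to the
#' maximum obtained on release into solvent only.
#'
#' @param values Numeric vector.
#' @param reference_values Non-empty numeric vector of reference maxima.
#' @return `values / median(reference_values)`.
#' @export
normalize_to_reference <- function(values, reference_values) {
  if (!length(reference_values)) {
    abort("reference is empty", class = "cdkflow_normalisation_error")
  }
  ref <- median(reference_values)
  if (!is.finite(ref) || ref <= 0) {
    abort("reference median must be positive",
          class = "cdkflow_normalisation_error")
  }
  values / ref
}

#' Bin cell records and summarise activity per bin
#'
#' Equal-width binning of a size or level variable with per-bin counts and
#' activity summaries. Bins with fewer than `min_n` cells are flagged
#' (`low_n`), never dropped.
#'
#' @param records Tibble of cell records.
#' @param bin_var Column to bin on (e.g. `"length_um"`, `"volume_fl"`,
#'   `"cdk_level_au"`, `"area_px2"`).
#' @param bin_width Bin width in the variable's units (e.g. 500 for an
#'   area variable in px^2, 1 for length in um).
#' @param min_n Minimum cells per bin before the `low_n` flag is raised.
#' @param value_var Column summarised within bins (default
#'   `"activity_nc"`).
#' @param gated_only Use only records with `gated = TRUE` (default).
#' @return A `binned_response` tibble: `bin_mid`, `bin_lo`, `bin_hi`, `n`,
#'   `mean`, `sd`, `median`, `low_n`.
#' @export
binned_response <- function(records, bin_var, bin_width, min_n = 10,
                            value_var = "activity_nc", gated_only = TRUE) {
  if (!bin_var %in% names(records)) {
    abort(sprintf("column '%s' not in records", bin_var),
          class = "cdkflow_domain_error")
  }
  df <- records
  if (gated_only && "gated" %in% names(df)) df <- filter(df, .data$gated)
  df <- filter(df, is.finite(.data[[bin_var]]), is.finite(.data[[value_var]]))
  if (!nrow(df)) {
    abort("no gated records to bin", class = "cdkflow_empty_result")
  }
  v <- df[[bin_var]]
  lo <- floor(min(v) / bin_width) * bin_width
  idx <- floor((v - lo) / bin_width)
  out <- df %>%
    mutate(.bin = idx) %>%
    group_by(.data$.bin) %>%
    summarise(n = dplyr::n(),
              mean = mean(.data[[value_var]]),
              sd = sd(.data[[value_var]]),
              median = median(.data[[value_var]]),
              .groups = "drop") %>%
    mutate(bin_lo = lo + .data$.bin * bin_width,
           bin_hi = .data$bin_lo + bin_width,
           bin_mid = .data$bin_lo + bin_width / 2,
           low_n = .data$n < min_n) %>%
    select("bin_mid", "bin_lo", "bin_hi", "n", "mean", "sd", "median",
           "low_n") %>%
    arrange(.data$bin_mid)
  class(out) <- c("binned_response", class(out))
  attr(out, "bin_var") <- bin_var
  attr(out, "value_var") <- value_var
  out
}
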