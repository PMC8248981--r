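#' Division hazard P(Div) binned by size or level
#'
#' For every observed cell-timepoint the outcome is whether a C-CDK
#' degradation event (the anaphase marker) occurs by the next frame.
#' Timepoints are binned by the chosen state variable and the per-bin event
#' fraction is converted to a rate per minute by dividing by the frame
#' interval.
#'
#' @param traces A `lineage_traces` object ([simulate_lineages()] or
#'   [read_lineage_traces()]). Events default to the object's event table;
#'   pass `events` to use detector output instead
#'   ([detect_degradation()]).
#' @param bin_var `"size"` or `"level_au"` (any numeric frame column).
#' @param bin_width Bin width in the variable's units.
#' @param events Optional tibble with `cell_id`, `frame` of degradation
#'   events; defaults to the degradation events stored in `traces`.
#' @param min_n Bins with fewer cell-timepoints are flagged `low_n`.
#' @return A `pdiv_curve` tibble: `bin_mid`, `n_timepoints`, `n_events`,
#'   `rate_per_min`, `low_n`.
#' @examples
#' tr <- simulate_lineages(sim_config(seed = 8), 50, 240)
#' estimate_pdiv(tr, "size", 1)
#' @export
estimate_pdiv <- function(traces, bin_var = "size", bin_width = 1,
                          events = NULL, min_n = 20) {
  stopifnot(inherits(traces, "lineage_traces"))
  dt <- traces$frame_interval_min
  ev <- events %||%
    filter(traces$events,
           .data$kind %in% c("degradation", "degradation_without_division"))
  frames <- traces$frames
  # a timepoint is at risk if a next frame exists in the same trace
  risk <- frames %>%
    group_by(.data$cell_id) %>%
    filter(.data$frame < max(.data$frame)) %>%
    ungroup()
  if (!nrow(risk)) {
    abort("no at-risk cell-timepoints (traces need >= 2 frames)",
          class = "cdkflow_empty_result")
  }
  key <- paste(ev$cell_id, ev$frame)
  risk <- risk %>%
    mutate(event = paste(.data$cell_id, .data$frame + 1L) %in% key)
  v <- risk[[bin_var]]
  lo <- floor(min(v) / bin_width) * bin_width
  out <- risk %>%
    mutate(.bin = floor((.data[[bin_var]] - lo) / bin_width)) %>%
    group_by(.data$.bin) %>%
    summarise(n_timepoints = dplyr::n(), n_events = sum(.data$event),
              .groups = "drop") %>%
    mutate(bin_mid = lo + (.data$.bin + 0.5) * bin_width,
           rate_per_min = (.data$n_events / .data$n_timepoints) / dt,
           low_n = .data$n_timepoints < min_n) %>%
    select("bin_mid", "n_timepoints", "n_events", "rate_per_min", "low_n") %>%
    arrange(.data$bin_mid)
  class(out) <- c("pdiv_curve", class(out))
  attr(out, "bin_var") <- bin_var
  attr(out, "frame_interval_min") <- dt
  out
}

#' Size-binned C-CDK activation-threshold curve
#'
#' Within each cell-size bin, cells are grouped into sliding C-CDK-level
#' windows and the fraction with CDK activity above `activity_cut` is
#' computed per window. After isotonic (monotone non-decreasing) smoothing
#' of that exceedance fraction, the threshold is the smallest level at
#' which it crosses `fraction`, interpolated linearly between window
#' centres. Bins where the smoothed fraction never reaches `fraction`
#' within the observed levels carry `defined = FALSE` — the threshold is
#' unattainable there, never silently numeric.
#'
#' @param records Cell-record tibble with `cdk_level_au`, `activity_nc` and
#'   the size column.
#' @param size_var Size column for binning (default `"length_um"`).
#' @param size_bin_width Size bin width (default 1 um).
#' @param activity_cut Activity defining the "on" state (default 5).
#' @param fraction Exceedance fraction defining the threshold (default
#'   0.5).
#' @param level_window Sliding level-window width in AU (default 100, 50%
#'   overlap).
#' @param min_n Minimum cells per size bin and per level window.
#' @param gated_only Use only gated records (default).
#' @return A `threshold_curve` tibble: `bin_mid` (size), `n`,
#'   `threshold_level_au`, `defined`, `reason`.
#' @export
threshold_level <- function(records, size_var = "length_um",
                            size_bin_width = 1, activity_cut = 5,
                            fraction = 0.5, level_window = 100,
                            min_n = 30, gated_only = TRUE) {
  df <- records
  if (gated_only && "gated" %in% names(df)) df <- filter(df, .data$gated)
  df <- filter(df, is.finite(.data[[size_var]]),
               is.finite(.data$cdk_level_au), is.finite(.data$activity_nc))
  if (!nrow(df)) abort("no gated records", class = "cdkflow_empty_result")
  lo <- floor(min(df[[size_var]]) / size_bin_width) * size_bin_width
  df$.bin <- floor((df[[size_var]] - lo) / size_bin_width)
  bins <- sort(unique(df$.bin))
  rows <- purrr::map_dfr(bins, function(b) {
    sub <- df[df$.bin == b, ]
    res <- bin_threshold(sub$cdk_level_au, sub$activity_nc, activity_cut,
                         fraction, level_window, min_n)
    tibble(bin_mid = lo + (b + 0.5) * size_bin_width, n = nrow(sub),
           threshold_level_au = res$threshold, defined = res$defined,
           reason = res$reason)
  })
  class(rows) <- c("threshold_curve", class(rows))
  attr(rows, "activity_cut") <- activity_cut
  attr(rows, "fraction") <- fraction
  attr(rows, "size_var") <- size_var
  rows
}

# exceedance-fraction crossing within one size bin
bin_threshold <- function(level, activity, activity_cut, fraction,
                          level_window, min_n) {
  if (length(level) < min_n) {
    return(list(threshold = NA_real_, defined = FALSE, reason = "low_n"))
  }
  step <- level_window / 2  # 50% overlap
  starts <- seq(floor(min(level) / step) * step, max(level), by = step)
  centres <- starts + level_window / 2
  f <- vapply(starts, function(s) {
    inw <- level >= s & level < s + level_window
    if (sum(inw) < max(5, min_n / 10)) return(NA_real_)
    mean(activity[inw] > activity_cut)
  }, numeric(1))
  ok <- is.finite(f)
  if (sum(ok) < 2) {
    return(list(threshold = NA_real_, defined = FALSE, reason = "low_n"))
  }
  centres <- centres[ok]; f <- f[ok]
  # isotonic smoothing: the exceedance fraction is monotone in level under
  # the model; raw windows can dip at small n
  f_iso <- isoreg(centres, f)$yf
  if (max(f_iso) < fraction) {
    return(list(threshold = NA_real_, defined = FALSE,
                reason = "unattainable"))
  }
  i <- which(f_iso >= fraction)[1]
  thr <- if (i == 1) centres[1] else {
    f0 <- f_iso[i - 1]; f1 <- f_iso[i]
    if (f1 > f0) {
      centres[i - 1] + (fraction - f0) / (f1 - f0) *
        (centres[i] - centres[i - 1])
    } else {
      centres[i]
    }
  }
  list(threshold = thr, defined = TRUE, reason = NA_character_)
}

#' Decompose genotype threshold curves into regulatory contributions
#'
#' Subtraction algebra on four size-binned threshold curves (WT, AF,
#' WT PP2A-delta, AF PP2A-delta):
#' * `contrib_yphos_pp2a` = WT - AF: tyrosine phosphorylation with PP2A
#'   present;
#' * `contrib_yphos_alone` = WT_PP2AD - AF_PP2AD: tyrosine phosphorylation
#'   without PP2A;
#' * `contrib_pp2a_alone` = AF - AF_PP2AD: PP2A without tyrosine
#'   phosphorylation;
#' * `recomposed` = AF_PP2AD + yphos_alone + pp2a_alone;
#' * `synergy` = WT - recomposed.
#' Undefined thresholds are substituted by `cap` (default 1000 AU) before
#' subtraction and every capped bin is flagged per input curve, so a capped
#' value never enters the algebra silently. Zero synergy means the two
#' regulatory arms act additively; positive synergy in small-size bins
#' means their joint restriction exceeds the sum of their parts.
#'
#' @param curves Named list of `threshold_curve` objects with names `WT`,
#'   `AF`, `WT_PP2AD`, `AF_PP2AD`, on identical size bins.
#' @param cap Substitute for undefined thresholds (AU).
#' @return A `synergy_decomposition` tibble with one row per size bin:
#'   the four (possibly capped) input thresholds, capping flags, the three
#'   contributions, `recomposed` and `synergy`.
#' @export
decompose_synergy <- function(curves, cap = 1000) {
  need <- c("WT", "AF", "WT_PP2AD", "AF_PP2AD")
  if (!all(need %in% names(curves))) {
    abort(paste("curves must be named", paste(need, collapse = ", ")),
          class = "cdkflow_domain_error")
  }
  bins <- curves$WT$bin_mid
  for (g in need) {
    if (!isTRUE(all.equal(curves[[g]]$bin_mid, bins))) {
      abort("threshold curves are not on identical size bins",
            class = "cdkflow_alignment_error")
    }
  }
  val <- function(g) {
    cv <- curves[[g]]
    ifelse(cv$defined, cv$threshold_level_au, cap)
  }
  capped <- function(g) !curves[[g]]$defined
  wt <- val("WT"); af <- val("AF")
  wtp <- val("WT_PP2AD"); afp <- val("AF_PP2AD")
  out <- tibble(
    bin_mid = bins,
    wt = wt, af = af, wt_pp2ad = wtp, af_pp2ad = afp,
    capped_wt = capped("WT"), capped_af = capped("AF"),
    capped_wt_pp2ad = capped("WT_PP2AD"), capped_af_pp2ad = capped("AF_PP2AD"),
    contrib_yphos_pp2a = wt - af,
    contrib_yphos_alone = wtp - afp,
    contrib_pp2a_alone = af - afp,
    recomposed = afp + (wtp - afp) + (af - afp),
    synergy = wt - (afp + (wtp - afp) + (af - afp)),
    any_capped = capped("WT") | capped("AF") | capped("WT_PP2AD") |
      capped("AF_PP2AD")
  )
  class(out) <- c("synergy_decomposition", class(out))
  attr(out, "cap") <- cap
  out
}
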