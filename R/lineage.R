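#' Detect C-CDK degradation events in a level trace
#'
#' A degradation event is a frame at which the level falls by at least
#' `drop_frac` relative to the local pre-drop maximum within the preceding
#' `window` frames. After a detection the next `window` frames are
#' refractory, so one biological event is reported once.
#'
#' @param traces A `lineage_traces` object or a frames tibble with
#'   `cell_id`, `frame`, `level_au`.
#' @param drop_frac Minimum fractional drop (default 0.5).
#' @param window Look-back window in frames (default 2).
#' @return Tibble `cell_id`, `frame` of detected events (possibly empty).
#' @examples
#' tr <- simulate_lineages(sim_config(seed = 9), 20, 240)
#' detect_degradation(tr)
#' @export
detect_degradation <- function(traces, drop_frac = 0.5, window = 2) {
  frames <- trace_frames(traces)
  detect_drops(frames, "level_au", drop_frac, window)
}

#' Detect division events in a size trace
#'
#' Division is a steep decrease in cell size between consecutive frames:
#' a fractional drop of at least `drop_frac` (cells halve at division, so
#' the default 0.3 separates divisions from growth fluctuations).
#'
#' @inheritParams detect_degradation
#' @param drop_frac Minimum fractional size decrease (default 0.3).
#' @return Tibble `cell_id`, `frame` of division frames.
#' @export
detect_division <- function(traces, drop_frac = 0.3) {
  frames <- trace_frames(traces)
  detect_drops(frames, "size", drop_frac, window = 1)
}

trace_frames <- function(traces) {
  if (inherits(traces, "lineage_traces")) traces$frames else traces
}

# shared drop detector with refractory suppression
detect_drops <- function(frames, var, drop_frac, window) {
  frames %>%
    arrange(.data$cell_id, .data$frame) %>%
    group_by(.data$cell_id) %>%
    dplyr::group_modify(function(df, key) {
      v <- df[[var]]
      n <- length(v)
      hits <- integer(0)
      last_hit <- -window - 1L
      for (i in 2:n) {
        if (i - last_hit <= window) next
        lo <- max(1, i - window)
        pre_max <- max(v[lo:(i - 1)])
        if (pre_max > 0 && v[i] <= (1 - drop_frac) * pre_max) {
          hits <- c(hits, i)
          last_hit <- i
        }
      }
      tibble(frame = df$frame[hits])
    }) %>%
    ungroup()
}

#' Classify degradation events as divisions or skipped divisions
#'
#' Pairs each detected degradation event with a division event within
#' `lag_max` frames; unpaired degradations are labelled
#' `degradation_without_division` — the mitotic-skip phenotype in which
#' C-CDK is destroyed without the cell dividing. Returns the labelled
#' events and the population fraction with an exact binomial confidence
#' interval.
#'
#' @param traces A `lineage_traces` object (or frames tibble).
#' @param lag_max Maximum |frame difference| for pairing (default 3).
#' @param degradation,division Optional pre-computed event tibbles; by
#'   default the detectors run with their defaults.
#' @param conf_level Confidence level for the binomial CI.
#' @return List with `events` (tibble: `cell_id`, `frame`, `skipped`),
#'   `fraction`, `n_events`, `ci` (length-2), and `defined` (FALSE when no
#'   degradation events were found).
#' @export
classify_skipped_divisions <- function(traces, lag_max = 3,
                                       degradation = NULL, division = NULL,
                                       conf_level = 0.95) {
  deg <- degradation %||% detect_degradation(traces)
  div <- division %||% detect_division(traces)
  if (!nrow(deg)) {
    return(list(events = tibble(cell_id = character(), frame = integer(),
                                skipped = logical()),
                fraction = NA_real_, n_events = 0L,
                ci = c(NA_real_, NA_real_), defined = FALSE))
  }
  div_by_cell <- split(div$frame, div$cell_id)
  ev <- deg %>%
    mutate(skipped = purrr::map2_lgl(.data$cell_id, .data$frame,
                                     function(cid, f) {
      d <- div_by_cell[[cid]]
      is.null(d) || !any(abs(d - f) <= lag_max)
    })) %>%
    select("cell_id", "frame", "skipped")
  k <- sum(ev$skipped); n <- nrow(ev)
  ci <- as.numeric(stats::binom.test(k, n,
                                     conf.level = conf_level)$conf.int)
  list(events = ev, fraction = k / n, n_events = n, ci = ci, defined = TRUE)
}

#' Align activity traces to their peak
#'
#' Time-shifts each trace so that the maximum of the smoothed activity
#' (centred moving average over `smooth_window` frames) sits at 0 min.
#' Traces whose activity is flat carry `aligned = FALSE` and are returned
#' unshifted.
#'
#' @param traces A `lineage_traces` object or frames tibble with
#'   `activity_nc`.
#' @param smooth_window Moving-average window in frames (default 3).
#' @return Frames tibble with added `time_aligned_min`, `shift_min`,
#'   `aligned`.
#' @export
align_to_peak <- function(traces, smooth_window = 3) {
  frames <- trace_frames(traces)
  frames %>%
    arrange(.data$cell_id, .data$frame) %>%
    group_by(.data$cell_id) %>%
    dplyr::group_modify(function(df, key) {
      a <- moving_average(df$activity_nc, smooth_window)
      if (diff(range(a)) < .Machine$double.eps^0.5 * max(1, max(abs(a)))) {
        return(mutate(df, time_aligned_min = .data$time_min,
                      shift_min = 0, aligned = FALSE))
      }
      peak_t <- df$time_min[which.max(a)]
      mutate(df, time_aligned_min = .data$time_min - peak_t,
             shift_min = -peak_t, aligned = TRUE)
    }) %>%
    ungroup()
}

#' Automatic mitotic-entry call on an activity trace
#'
#' Entry is the first frame at which the smoothed activity exceeds the
#' baseline (median of the first quartile of frames) by `k` robust
#' standard deviations and then climbs to the trace peak without falling
#' back below the baseline. Returns `NA` with `defined = FALSE` when no
#' frame qualifies (e.g. flat traces). This criterion is a documented
#' convention of this package; it is one reasonable operationalisation of
#' "the activity has committed to its mitotic rise".
#'
#' @param trace One cell's frames (tibble with `frame`, `time_min`,
#'   `activity_nc`), e.g. one group of [align_to_peak()] output.
#' @param k Threshold in robust sds above baseline (default 3).
#' @param smooth_window Moving-average window (default 3).
#' @return List with `frame`, `time_min`, `defined`.
#' @export
detect_mitotic_entry <- function(trace, k = 3, smooth_window = 3) {
  a <- moving_average(trace$activity_nc, smooth_window)
  n <- length(a)
  q1 <- seq_len(max(2, floor(n / 4)))
  baseline <- median(a[q1])
  rsd <- mad(a[q1])
  thr <- baseline + k * rsd
  peak <- which.max(a)
  cand <- which(a > thr + .Machine$double.eps^0.5 * max(1, abs(thr)))
  cand <- cand[cand <= peak]
  for (i in cand) {
    if (all(a[i:peak] > baseline)) {
      return(list(frame = trace$frame[i], time_min = trace$time_min[i],
                  defined = TRUE))
    }
  }
  list(frame = NA_integer_, time_min = NA_real_, defined = FALSE)
}
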