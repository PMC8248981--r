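#' C-CDK level: mean of the brightest group of 9 pixels
#'
#' Concentration estimator for a fluorescence channel: the mean intensity
#' of the brightest group of 9 pixels within the cell. "Group" is read as a
#' contiguous 3 x 3 block — the estimator slides a 3 x 3 window over every
#' position fully inside the mask and returns the largest window mean,
#' which is robust to isolated hot pixels. The alternative reading (the 9
#' brightest pixels anywhere in the mask, not necessarily contiguous) is
#' available as `method = "top9"`.
#'
#' @param channel Numeric matrix.
#' @param mask A `cell_mask` (from [segment_cell()]) or a logical matrix.
#' @param method `"block"` (default, contiguous 3 x 3) or `"top9"`.
#' @return Scalar level in channel units (AU).
#' @examples
#' m <- matrix(TRUE, 9, 9)
#' ch <- matrix(1, 9, 9); ch[4:6, 4:6] <- 10
#' measure_level(ch, m)  # 10
#' @export
measure_level <- function(channel, mask, method = c("block", "top9")) {
  method <- match.arg(method)
  mk <- as_mask_matrix(mask, channel)
  if (!any(mk)) {
    abort("empty mask", class = "cdkflow_degenerate_cell")
  }
  if (method == "top9") {
    v <- sort(channel[mk], decreasing = TRUE)
    if (length(v) < 9) {
      abort("fewer than 9 pixels in mask", class = "cdkflow_degenerate_cell")
    }
    return(mean(v[1:9]))
  }
  sums <- window_sum3(channel)
  counts <- window_sum3(mk * 1)
  valid <- !is.na(counts) & counts > 8.5  # all 9 pixels inside the mask
  if (!any(valid)) {
    abort("no 3x3 window fits inside the mask",
          class = "cdkflow_degenerate_cell")
  }
  max(sums[valid]) / 9
}

as_mask_matrix <- function(mask, channel) {
  mk <- if (inherits(mask, "cell_mask")) mask$mask else mask
  if (!identical(dim(mk), dim(channel))) {
    abort("mask and channel shapes differ", class = "cdkflow_image_error")
  }
  mk
}

# 3x3 window sums at every interior centre via an integral image
window_sum3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  s <- matrix(0, nr + 1, nc + 1)
  s[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  out <- matrix(NA_real_, nr, nc)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  out[i, j] <- s[i + 2, j + 2] - s[i - 1, j + 2] - s[i + 2, j - 1] +
    s[i - 1, j - 1]
  out
}

#' Midline intensity profile of a cell
#'
#' Draws a line through the middle of the cell along its long axis (the
#' raster is first rotated so the major axis is horizontal), widens the
#' line by one pixel either side to a 3-px band, and records the mean band
#' intensity per position. The profile is restricted to columns where the
#' whole band lies inside the mask.
#'
#' @param channel Numeric matrix (same orientation as the mask's source
#'   image).
#' @param mask A `cell_mask` from [segment_cell()], or a logical matrix.
#' @return A `midline_profile`: list with `positions` (px along the axis),
#'   `intensities` (band means), and the band `width` (always 3).
#' @export
midline_profile <- function(channel, mask) {
  mk <- if (inherits(mask, "cell_mask")) mask else mask_geometry(mask, 1)
  if (mk$failed) abort("segmentation failed", class = "cdkflow_degenerate_cell")
  ch <- rotate_raster(channel, mk$angle_deg)
  m <- rotate_raster(mk$mask * 1, mk$angle_deg, binary = TRUE)
  idx <- which(m, arr.ind = TRUE)
  mid <- mean(range(idx[, 1]))
  # when the mask height is even the middle pixel is ambiguous; take the
  # candidate row whose band shows the stronger central contrast
  cand <- unique(c(floor(mid), ceiling(mid)))
  score <- vapply(cand, function(r) {
    if (r - 1 < 1 || r + 1 > nrow(m)) return(-Inf)
    b <- colMeans(ch[(r - 1):(r + 1), , drop = FALSE][, m[r, ], drop = FALSE])
    if (!length(b)) return(-Inf)
    max(abs(b - median(b)))
  }, numeric(1))
  mid_row <- cand[which.max(score)]
  band <- (mid_row - 1):(mid_row + 1)
  if (min(band) < 1 || max(band) > nrow(m) || !is.finite(max(score))) {
    abort("mask too thin for a 3-px band", class = "cdkflow_degenerate_cell")
  }
  cols <- which(m[mid_row, ])
  if (length(cols) < 3) {
    abort("mask too thin for a 3-px band", class = "cdkflow_degenerate_cell")
  }
  # band mean per column over in-mask pixels (tips keep partial bands)
  intens <- vapply(cols, function(j) {
    inb <- m[band, j]
    mean(ch[band[inb], j])
  }, numeric(1))
  mask_cols <- which(colSums(m) > 0)
  structure(list(positions = cols,
                 intensities = intens,
                 width = 3L,
                 centre = mean(range(mask_cols)),
                 half_extent = (diff(range(mask_cols)) + 1) / 2),
            class = "midline_profile")
}

#' @export
print.midline_profile <- function(x, ...) {
  cat("<midline_profile>", length(x$positions), "positions, range",
      paste(signif(range(x$intensities), 4), collapse = " - "), "\n")
  invisible(x)
}

#' CDK activity (N/C ratio) from a midline profile
#'
#' The biosensor accumulates in the nucleus under high CDK activity, so the
#' midline profile shows a central peak (or a central dip when activity is
#' low and the nucleus excludes the reporter). The cytoplasmic baseline is
#' the median intensity of the flat flanking segments between 15% and 35%
#' of the cell length from each end (tips are excluded to avoid cap
#' roll-off; the median resists nuclear-signal leakage in short cells). The
#' most
#' prominent central extremum — peak or dip — is compared against that
#' baseline; if its prominence does not exceed `prominence_k` times the
#' robust noise sd of the flanks, the profile is called flat and the
#' activity is 1 (N/C ratio of an inactive cell).
#'
#' @param profile A `midline_profile`.
#' @param prominence_k Multiplier of the flank robust sd used as the
#'   detection threshold (default 2).
#' @param flank Two fractions of profile length delimiting the flanking
#'   "flat" segments measured from each tip (default `c(0.15, 0.35)`).
#' @return Scalar `activity_nc` = extremum intensity / cytoplasmic
#'   baseline (dimensionless, > 0).
#' @export
activity_from_profile <- function(profile, prominence_k = 2,
                                  flank = c(0.15, 0.35)) {
  stopifnot(inherits(profile, "midline_profile"))
  y <- profile$intensities
  n <- length(y)
  if (n < 7) abort("profile too short", class = "cdkflow_degenerate_cell")
  # signed position relative to the cell centre, -1/+1 at the tips; windows
  # are anchored on the mask geometry so ragged tip truncation of the
  # profile cannot shift them
  centre <- profile$centre %||% mean(range(profile$positions))
  half <- profile$half_extent %||% (diff(range(profile$positions)) / 2)
  x <- (profile$positions - centre) / half
  # distance from the nearer tip as a fraction of cell length:
  # flank c(0.15, 0.35) keeps 15-35% from each end
  tipfrac <- (1 - abs(x)) / 2
  flank_idx <- tipfrac >= flank[1] & tipfrac <= flank[2]
  if (sum(flank_idx) < 2) flank_idx <- tipfrac <= flank[2]
  # median, not mean: in short cells the blurred nuclear signal can leak
  # into the inner edge of the flank windows
  baseline <- median(y[flank_idx])
  if (!is.finite(baseline) || baseline <= 0) {
    abort("non-positive cytoplasmic baseline",
          class = "cdkflow_quantification_error")
  }
  centre_idx <- which(tipfrac > flank[2])
  if (!length(centre_idx)) {
    abort("profile has no central region", class = "cdkflow_degenerate_cell")
  }
  dev <- abs(y[centre_idx] - baseline)
  # ties broken by proximity to the cell centre
  ord <- order(-dev, abs(x[centre_idx]))
  ext <- centre_idx[ord[1]]
  noise_sd <- mad(y[flank_idx])
  if (dev[ord[1]] <= prominence_k * noise_sd ||
      dev[ord[1]] < .Machine$double.eps^0.5 * max(1, baseline)) {
    return(1)
  }
  y[ext] / baseline
}

#' Apply imaging-flow-cytometry gates to cell records
#'
#' Flags in-focus singlet cells: gradient RMS above the focus cut (default
#' 65) and area/aspect-ratio within bounds consistent with single cells.
#' Records are flagged, never dropped.
#'
#' @param records Tibble of cell records with `focus_grad_rms`, `area_px2`,
#'   `aspect_ratio`.
#' @param gate_params List of `grad_rms_min` (default 65), `area` (c(min,
#'   max) px^2), `aspect` (c(min, max)).
#' @return `records` with a logical `gated` column.
#' @export
gate_records <- function(records,
                         gate_params = list()) {
  p <- modifyList(list(grad_rms_min = 65, area = c(100, Inf),
                       aspect = c(1.5, 10)),
                  gate_params)
  records %>%
    mutate(gated = .data$focus_grad_rms > p$grad_rms_min &
             .data$area_px2 >= p$area[1] & .data$area_px2 <= p$area[2] &
             .data$aspect_ratio >= p$aspect[1] &
             .data$aspect_ratio <= p$aspect[2])
}

#' Quantify one cell image into a cell record
#'
#' Full per-image chain: segment from the brightfield pair, estimate the
#' local background as the median intensity outside the mask (subtracted
#' from both fluorescence channels), measure the C-CDK level with the
#' brightest-9-pixel estimator, extract the midline profile of the
#' biosensor and convert it to an N/C activity ratio, compute geometry and
#' the gradient-RMS focus score.
#'
#' @param image A [cell_image()].
#' @param params Optional list with `segment` (passed to [segment_cell()]),
#'   `level_method`, `prominence_k`.
#' @return A one-row tibble (cell record). If segmentation fails the row
#'   carries `segmentation_failed = TRUE` and NA measurements.
#' @export
quantify_image <- function(image, params = list()) {
  stopifnot(inherits(image, "cell_image"))
  p <- modifyList(list(segment = list(), level_method = "block",
                       prominence_k = 2), params)
  mask <- segment_cell(image, p$segment)
  focus <- gradient_rms_focus(image$bf1)
  if (mask$failed) {
    return(tibble(length_um = NA_real_, radius_um = NA_real_,
                  area_px2 = NA_real_, volume_fl = NA_real_,
                  aspect_ratio = NA_real_,
                  cdk_level_au = NA_real_, activity_nc = NA_real_,
                  focus_grad_rms = focus,
                  segmentation_failed = TRUE, gated = FALSE))
  }
  bg_bio <- median(image$channels$biosensor[!mask$mask])
  bg_lev <- median(image$channels$level[!mask$mask])
  level <- tryCatch(measure_level(image$channels$level - bg_lev, mask,
                                  method = p$level_method),
                    error = function(e) NA_real_)
  act <- tryCatch({
    prof <- midline_profile(image$channels$biosensor - bg_bio, mask)
    activity_from_profile(prof, prominence_k = p$prominence_k)
  }, error = function(e) NA_real_)
  tibble(length_um = mask$length_um, radius_um = mask$radius_um,
         area_px2 = mask$area_px2,
         volume_fl = cylinder_volume(mask$radius_um, mask$length_um),
         aspect_ratio = mask$aspect_ratio,
         cdk_level_au = level, activity_nc = act,
         focus_grad_rms = focus,
         segmentation_failed = FALSE, gated = NA)
}
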