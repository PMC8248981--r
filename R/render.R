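#' Construct a multi-channel single-cell image
#'
#' Bundles the four rasters of one imaged cell — two brightfield renderings
#' plus the biosensor (nuclear-translocation reporter) and C-CDK level
#' fluorescence channels — with the pixel size. All rasters are plain
#' numeric matrices of identical shape, row-major with the cell's long axis
#' in whatever orientation the instrument produced.
#'
#' @param bf1,bf2 Brightfield rasters (numeric matrices, same shape).
#' @param biosensor,level Fluorescence rasters (same shape).
#' @param pixel_size Pixel size in um/px (> 0).
#' @return A `cell_image` object.
#' @export
cell_image <- function(bf1, bf2, biosensor, level, pixel_size) {
  dims <- dim(bf1)
  for (m in list(bf2, biosensor, level)) {
    if (!identical(dim(m), dims)) {
      abort("all rasters must share one shape", class = "cdkflow_image_error")
    }
  }
  check_pos(pixel_size, "pixel_size")
  structure(list(bf1 = bf1, bf2 = bf2,
                 channels = list(biosensor = biosensor, level = level),
                 pixel_size = pixel_size),
            class = "cell_image")
}

#' @export
print.cell_image <- function(x, ...) {
  cat("<cell_image>", paste(dim(x$bf1), collapse = " x "), "px,",
      x$pixel_size, "um/px\n")
  invisible(x)
}

#' Render a synthetic cell image from ground truth
#'
#' Draws a rod-shaped cell (rectangle with semicircular caps) lying
#' horizontally, with a circular nucleus at the cell mid-point. The
#' biosensor channel is uniform cytoplasmic intensity with the nucleus at
#' `cyto_au * nc` (so the true N/C ratio is imprinted exactly before
#' optics); the level channel is uniform at the true C-CDK level inside the
#' mask. The two brightfield renderings share the cell outline but carry
#' independent texture noise, so the per-pixel standard deviation across
#' the pair is elevated inside the cell — the cue the segmenter uses. All
#' channels are Gaussian-blurred by the point-spread sigma and given
#' additive background and read noise.
#'
#' @param truth One ground-truth row: a list/one-row data frame with
#'   `length_um`, `radius_um`, `cdk_level_au`, `activity_nc` (the true N/C
#'   ratio) and optionally `cell_id` (seeds the per-cell noise stream).
#' @param config A [sim_config()]; rendering parameters come from
#'   `config$imaging`.
#' @param dim Optional `c(rows, cols)` frame size in px. The default frame
#'   fits the cell with a comfortable margin; an explicit frame too small
#'   for the cell (less than 3 px margin) is an error.
#' @return A [cell_image()].
#' @examples
#' cfg <- sim_config(seed = 4)
#' img <- render_cell_image(
#'   list(cell_id = "c1", length_um = 10, radius_um = 1.75,
#'        cdk_level_au = 400, activity_nc = 2), cfg)
#' @export
render_cell_image <- function(truth, config, dim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  truth <- as.list(truth)
  im <- config$imaging
  px <- im$pixel_size
  len_px <- truth$length_um / px
  rad_px <- truth$radius_um / px
  margin <- max(4, ceiling(3 * im$psf_sigma) + 3)
  if (is.null(dim)) {
    dim <- c(ceiling(2 * rad_px) + 2 * margin, ceiling(len_px) + 2 * margin)
  } else if (dim[2] < len_px + 6 || dim[1] < 2 * rad_px + 6) {
    abort("cell does not fit in the requested frame with a 3 px margin",
          class = "cdkflow_sizing_error")
  }
  nr <- dim[1]; nc <- dim[2]
  use_substream(config$seed, paste0("render_", truth$cell_id %||% "cell"))

  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  row_i <- matrix(seq_len(nr), nr, nc)
  col_i <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  # distance to the rod's central segment
  half_seg <- max(len_px / 2 - rad_px, 0)
  dx <- pmax(abs(col_i - cx) - half_seg, 0)
  dist <- sqrt(dx^2 + (row_i - cy)^2)
  mask <- dist <= rad_px
  nucleus <- sqrt((col_i - cx)^2 + (row_i - cy)^2) <=
    im$nucleus_frac * rad_px

  biosensor <- matrix(0, nr, nc)
  biosensor[mask] <- im$cyto_au
  biosensor[nucleus & mask] <- im$cyto_au * truth$activity_nc
  level_ch <- matrix(0, nr, nc)
  level_ch[mask] <- truth$cdk_level_au

  # shared optics: the cell interior is darker than the background (the
  # dominant brightfield feature); frame-specific focal texture differs
  # between the two renderings, which is what the pair-sd segmentation cue
  # keys on
  texture <- function() {
    base <- matrix(rnorm(nr * nc, 0, 3), nr, nc)
    base[mask] <- base[mask] + rnorm(sum(mask), 0, im$bf_texture_sd)
    im$bf_background - im$bf_cell_contrast * mask + base
  }
  bf1 <- texture(); bf2 <- texture()

  blur <- function(m) {
    if (im$psf_sigma > 0) EBImage::gblur(m, sigma = im$psf_sigma) else m
  }
  noisy <- function(m) {
    m + im$background + matrix(rnorm(nr * nc, 0, im$noise_sd), nr, nc)
  }
  cell_image(bf1 = noisy(blur(bf1)), bf2 = noisy(blur(bf2)),
             biosensor = noisy(blur(biosensor)),
             level = noisy(blur(level_ch)),
             pixel_size = px)
}
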