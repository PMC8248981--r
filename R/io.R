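#' Read and write cell-record tables
#'
#' CSV (readr) and Parquet (arrow) round-trips for cell-record tibbles.
#' The format is inferred from the file extension. Logical flags and
#' missing values survive the round-trip in both formats.
#'
#' @param records Tibble to write.
#' @param path File path ending in `.csv` or `.parquet`.
#' @return `write_records` returns `path` invisibly; `read_records`
#'   returns a tibble.
#' @export
write_records <- function(records, path) {
  switch(table_format(path),
         csv = readr::write_csv(records, path, na = "NA"),
         parquet = arrow::write_parquet(records, path))
  invisible(path)
}

#' @rdname write_records
#' @param col_types Optional readr column specification for CSV.
#' @export
read_records <- function(path, col_types = NULL) {
  out <- switch(table_format(path),
                csv = readr::read_csv(path, col_types = col_types %||%
                                        readr::cols(),
                                      progress = FALSE,
                                      show_col_types = FALSE),
                parquet = as_tibble(arrow::read_parquet(path)))
  out
}

table_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv")) return("csv")
  if (ext %in% c("parquet", "pq")) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      abort("the 'arrow' package is required for Parquet I/O",
            class = "cdkflow_io_error")
    }
    return("parquet")
  }
  abort(sprintf("unsupported table format '%s' (use .csv or .parquet)", ext),
        class = "cdkflow_io_error")
}

#' Write a cell image as a multi-page TIFF with a JSON sidecar
#'
#' Channels are written as 32-bit float pages in the order BF1, BF2,
#' biosensor, level. TIFF float storage is defined on \[0, 1\], so
#' intensities are divided by `au_scale`; the scale, channel order and
#' pixel size are recorded in `<path>.json` and restored on read.
#'
#' @param image A [cell_image()].
#' @param path Output path (`.tif`/`.tiff`).
#' @param au_scale Intensity divisor (default 4096 AU full-scale).
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(image, path, au_scale = 4096) {
  stopifnot(inherits(image, "cell_image"))
  pages <- list(image$bf1, image$bf2, image$channels$biosensor,
                image$channels$level)
  # noise can take intensities slightly negative; shift by a recorded
  # offset so nothing is clamped by the [0, 1] float-TIFF convention
  au_offset <- min(0, vapply(pages, min, numeric(1)))
  tiff::writeTIFF(lapply(pages, function(m) {
    pmin(pmax((m - au_offset) / au_scale, 0), 1)
  }), path, bits.per.sample = 32L)
  meta <- list(channels = c("bf1", "bf2", "biosensor", "level"),
               pixel_size_um = image$pixel_size, au_scale = au_scale,
               au_offset = au_offset)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read cell images from TIFF files
#'
#' Reads one multi-page TIFF (or every `.tif`/`.tiff` in a directory) in
#' the documented channel order. Pixel size and intensity scale come from
#' the JSON sidecar when present (sidecar metadata wins over
#' `default_pixel_size`). Files that cannot be read or have the wrong
#' page count produce a warning and are skipped; the rest of the stream
#' continues.
#'
#' @param path A TIFF file or a directory of TIFFs.
#' @param default_pixel_size Fallback pixel size (um/px) when no sidecar
#'   exists.
#' @param default_au_scale Fallback intensity scale.
#' @return A named list of [cell_image()] objects.
#' @export
read_cell_images <- function(path, default_pixel_size = 0.3,
                             default_au_scale = 4096) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
               ignore.case = TRUE)
  } else {
    path
  }
  out <- list()
  for (f in files) {
    img <- tryCatch(read_one_tiff(f, default_pixel_size, default_au_scale),
                    error = function(e) {
                      warn(sprintf("skipping '%s': %s", f,
                                   conditionMessage(e)))
                      NULL
                    })
    if (!is.null(img)) out[[tools::file_path_sans_ext(basename(f))]] <- img
  }
  out
}

read_one_tiff <- function(f, default_pixel_size, default_au_scale) {
  pages <- tiff::readTIFF(f, all = TRUE)
  if (length(pages) != 4) {
    abort(sprintf("expected 4 channels (bf1, bf2, biosensor, level), got %d",
                  length(pages)),
          class = "cdkflow_io_error")
  }
  sidecar <- paste0(f, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  px <- meta$pixel_size_um %||% default_pixel_size
  sc <- meta$au_scale %||% default_au_scale
  off <- meta$au_offset %||% 0
  pages <- lapply(pages, function(p) {
    m <- matrix(as.vector(p), dim(p)[1], dim(p)[2])
    m * sc + off
  })
  cell_image(bf1 = pages[[1]], bf2 = pages[[2]], biosensor = pages[[3]],
             level = pages[[4]], pixel_size = px)
}

#' Read and write lineage traces
#'
#' Long-format CSV of frames (`cell_id`, `frame`, `time_min`, `size`,
#' `level_au`, `activity_nc`, ...) plus a JSON sidecar with the event
#' table and the frame interval.
#'
#' @param traces A `lineage_traces` object.
#' @param path CSV path; events go to `<path>.events.json`.
#' @return `path` invisibly; `read_lineage_traces` returns a
#'   `lineage_traces`.
#' @export
write_lineage_traces <- function(traces, path) {
  stopifnot(inherits(traces, "lineage_traces"))
  readr::write_csv(traces$frames, path, na = "NA")
  jsonlite::write_json(
    list(frame_interval_min = traces$frame_interval_min,
         events = traces$events),
    paste0(path, ".events.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lineage_traces
#' @param frame_interval_min Fallback frame interval when no sidecar
#'   exists.
#' @export
read_lineage_traces <- function(path, frame_interval_min = NULL) {
  frames <- readr::read_csv(path, progress = FALSE, show_col_types = FALSE)
  sidecar <- paste0(path, ".events.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    events <- as_tibble(meta$events)
    if (!nrow(events)) {
      events <- tibble(cell_id = character(), frame = integer(),
                       time_min = numeric(), kind = character())
    }
    dt <- meta$frame_interval_min
  } else {
    if (is.null(frame_interval_min)) {
      abort("no events sidecar; supply frame_interval_min",
            class = "cdkflow_io_error")
    }
    events <- tibble(cell_id = character(), frame = integer(),
                     time_min = numeric(), kind = character())
    dt <- frame_interval_min
  }
  new_lineage_traces(frames, events, dt)
}
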