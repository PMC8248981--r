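#' Simulate time-lapse lineages with division and degradation events
#'
#' Each lineage is one tracked cell imaged at a fixed frame interval. Length
#' grows linearly; C-CDK level accumulates in proportion to cell length;
#' activity follows the configured graded response of level and size. The
#' per-frame event probability is \eqn{1 - e^{-r \Delta t}} with rate
#' \eqn{r = \mathrm{baseline} \cdot \sigma(\mathrm{size}) \cdot
#' \sigma(\mathrm{level})} (logistic gates centred on `size_half` and
#' `level_half`). A triggered event degrades the level to a small floor;
#' with probability `1 - skip_division_prob` the cell also divides (length
#' halves), otherwise the event is a degradation without division — the
#' mitotic-skip phenotype of tyrosine-phosphorylation-deficient cells.
#'
#' @param config A [sim_config()].
#' @param n_lineages Number of independent tracked cells.
#' @param duration_min Total trace duration in minutes (>= 2 frames).
#' @param genotype Single genotype background for the response model.
#' @param ploidy `"haploid"` or `"diploid"`.
#' @return A `lineage_traces` object: list with `frames` (tibble: `cell_id`,
#'   `frame`, `time_min`, `size`, `level_au`, `activity_nc`), `events`
#'   (tibble: `cell_id`, `frame`, `time_min`, `kind`), and
#'   `frame_interval_min`. `size` is cell length in um.
#' @examples
#' tr <- simulate_lineages(sim_config(seed = 3), n_lineages = 5,
#'                         duration_min = 120)
#' dplyr::count(tr$events, kind)
#' @export
simulate_lineages <- function(config, n_lineages, duration_min,
                              genotype = "AF", ploidy = "haploid") {
  stopifnot(inherits(config, "sim_config"))
  genotype <- match.arg(genotype, names(config$response_params))
  ploidy <- match.arg(ploidy, c("haploid", "diploid"))
  dt <- config$frame_interval_min
  n_frames <- floor(duration_min / dt) + 1L
  if (n_frames < 2L) {
    abort("duration_min must span at least 2 frames",
          class = "cdkflow_config_error")
  }
  use_substream(config$seed, "lineages")

  n <- as.integer(n_lineages)
  rp <- config$response_params[[genotype]]
  hz <- config$hazard_params
  floor_au <- config$level_floor_au

  length_um <- rtruncnorm(n, config$size_dist$mean_length, config$size_dist$sd,
                          config$size_dist$min, config$size_dist$max)
  level <- floor_au + runif(n, 0, hz$level_half)

  size_mat <- matrix(NA_real_, n_frames, n)
  level_mat <- matrix(NA_real_, n_frames, n)
  ev_frame <- integer(0); ev_cell <- integer(0); ev_kind <- character(0)

  for (f in seq_len(n_frames)) {
    size_mat[f, ] <- length_um
    level_mat[f, ] <- pmax(level + rnorm(n, 0, trace_level_noise(config)),
                           0.5 * floor_au)
    if (f == n_frames) break
    rate <- hz$baseline *
      plogis(hz$sharpness * (length_um / hz$size_half - 1)) *
      plogis(hz$sharpness * (level / hz$level_half - 1))
    event <- runif(n) < (1 - exp(-rate * dt))
    if (any(event)) {
      divided <- runif(sum(event)) >= config$skip_division_prob
      ev_frame <- c(ev_frame, rep(f + 1L, sum(event)),
                    rep(f + 1L, sum(divided)))
      ev_cell <- c(ev_cell, which(event), which(event)[divided])
      ev_kind <- c(ev_kind,
                   ifelse(divided, "degradation",
                          "degradation_without_division"),
                   rep("division", sum(divided)))
      level[event] <- floor_au
      length_um[which(event)[divided]] <- length_um[which(event)[divided]] / 2
    }
    length_um <- length_um + config$growth_rate_um_min * dt
    level[!event] <- level[!event] +
      config$level_accum_rate * length_um[!event] * dt
  }

  k_eff <- rp$K0 * exp(-rp$size_coupling * (size_mat - config$ref_length_um)) +
    config$ploidy_inhibition$gamma *
      config$ploidy_inhibition$dna_units[[ploidy]] /
      cylinder_volume(config$radius_um[[ploidy]], size_mat)
  act_mat <- graded_activity(level_mat, k_eff, rp$slope_h, rp$top, rp$bottom) +
    matrix(rnorm(length(level_mat), 0, 0.15), nrow = n_frames)

  frames <- tibble(
    cell_id = rep(sprintf("lin_%05d", seq_len(n)), each = n_frames),
    frame = rep(seq_len(n_frames), n),
    time_min = (rep(seq_len(n_frames), n) - 1) * dt,
    size = as.vector(size_mat),
    level_au = as.vector(level_mat),
    activity_nc = pmax(as.vector(act_mat), 0.05),
    genotype = genotype,
    ploidy = if (ploidy == "diploid") 2L else 1L
  )
  events <- tibble(
    cell_id = sprintf("lin_%05d", ev_cell),
    frame = ev_frame,
    time_min = (ev_frame - 1) * dt,
    kind = ev_kind
  ) %>% arrange(.data$cell_id, .data$frame, .data$kind)

  new_lineage_traces(frames, events, dt)
}

# per-frame additive level measurement noise used in traces; kept well below
# the degradation drop so event detection is identifiable
trace_level_noise <- function(config) {
  min(5, config$level_params$noise_sd)
}

new_lineage_traces <- function(frames, events, frame_interval_min) {
  structure(list(frames = frames, events = events,
                 frame_interval_min = frame_interval_min),
            class = "lineage_traces")
}

#' @export
print.lineage_traces <- function(x, ...) {
  n_cells <- length(unique(x$frames$cell_id))
  cat("<lineage_traces>", n_cells, "cells,",
      nrow(x$frames), "cell-frames, frame interval",
      x$frame_interval_min, "min\n")
  if (nrow(x$events)) {
    tab <- table(x$events$kind)
    cat("  events:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  } else {
    cat("  events: none\n")
  }
  invisible(x)
}
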