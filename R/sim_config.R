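#' Simulation configuration for the synthetic-data generator
#'
#' Collects every parameter of the generator in one validated object: cell
#' geometry, C-CDK level model, per-genotype activity response, ploidy
#' (DNA-per-volume) inhibition, division hazard, time-lapse settings, and
#' image rendering. Defaults describe G2-arrested fission yeast populations
#' spanning roughly 7-14 um in length, with activity responses that are
#' bistable in tyrosine-phosphorylation-competent backgrounds and graded
#' without it.
#'
#' @param seed Integer root seed. All generator randomness derives from it;
#'   an identical config and seed reproduces outputs exactly.
#' @param n_cells Number of cells for [simulate_population()].
#' @param size_dist List with `mean_length`, `sd`, `min`, `max` (um): a
#'   truncated normal over cell length.
#' @param radius_um Named list of cell radii (um) per ploidy: `haploid`,
#'   `diploid`. Diploid cells are wider, so volume (not length) is the
#'   comparable size metric across ploidies.
#' @param level_mode `"size_scaled"` (level tracks cross-sectional area, as
#'   when expression runs from the endogenous cyclin promoter) or
#'   `"induction"` (level grows with time since induction, independent of
#'   size, as under a tetracycline promoter).
#' @param level_params Parameters of the active level mode. For
#'   `size_scaled`: `slope` (AU per um^2 of projected cell area),
#'   `intercept` (AU), `noise_sd` (AU). For `induction`: `rate` (AU/s),
#'   `start_lag` (s), `noise_sd` (AU), `sample_time` (end of the sequential
#'   sampling window, s since induction; cells are sampled uniformly
#'   between `start_lag` and `sample_time`, so levels span the whole ramp
#'   at every cell size).
#' @param response_params Named list per genotype background (`WT`, `AF`,
#'   `WT_PP2AD`, `AF_PP2AD`), each with `K0` (half-activation C-CDK level at
#'   the reference length, AU), `slope_h` (> 0, response steepness), `top`,
#'   `bottom` (activity plateaus, N/C-ratio units), `size_coupling`
#'   (d log K / d length, per um; positive couplings lower the threshold in
#'   longer cells), `bistable` (logical; two-state emission if `TRUE`) and
#'   `switch_noise` (activity sd about the state means).
#' @param ref_length_um Reference length at which `K0` applies (um).
#' @param ploidy_inhibition List with `gamma` (AU of extra effective
#'   threshold per unit DNA-per-volume, AU*fl) and `dna_units` per ploidy.
#'   `gamma = 0` switches the DNA-titration effect off.
#' @param hazard_params Division-hazard model for lineages: `baseline`
#'   (events/min at saturation), `size_half` (um), `level_half` (AU),
#'   `sharpness` (dimensionless logistic steepness applied to relative size
#'   and level).
#' @param growth_rate_um_min Linear length growth rate (um/min).
#' @param level_accum_rate Level accumulation per um of cell length per
#'   minute (AU/(um*min)) in time-lapse mode.
#' @param level_floor_au Residual level after mitotic degradation (AU).
#' @param frame_interval_min Time-lapse frame spacing (min).
#' @param skip_division_prob Probability that a triggered degradation event
#'   is not followed by division (degradation without division).
#' @param imaging List of rendering parameters: `pixel_size` (um/px),
#'   `psf_sigma` (px), `background` (AU), `noise_sd` (AU, fluorescence read
#'   noise), `bf_background` (AU), `bf_cell_contrast` (AU, how much darker
#'   the cell interior appears than the background, shared between the two
#'   brightfield frames), `bf_texture_sd` (AU, frame-specific focal texture
#'   inside the cell; the pair-sd segmentation cue), `cyto_au` (cytoplasmic
#'   biosensor intensity), `nucleus_frac` (nucleus radius as a fraction of
#'   cell radius).
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_cells = 100)
#' pop <- simulate_population(cfg)
#' @export
sim_config <- function(seed = 1L,
                       n_cells = 1000L,
                       size_dist = list(mean_length = 10, sd = 1.5,
                                        min = 7, max = 14),
                       radius_um = list(haploid = 1.75, diploid = 2.4),
                       level_mode = c("size_scaled", "induction"),
                       level_params = NULL,
                       response_params = NULL,
                       ref_length_um = 10,
                       ploidy_inhibition = list(
                         gamma = 12000,
                         dna_units = list(haploid = 1, diploid = 2)),
                       hazard_params = list(baseline = 0.05, size_half = 11,
                                            level_half = 400, sharpness = 8),
                       growth_rate_um_min = 0.04,
                       level_accum_rate = 0.5,
                       level_floor_au = 5,
                       frame_interval_min = 3,
                       skip_division_prob = 0.05,
                       imaging = list(pixel_size = 0.3, psf_sigma = 0.4,
                                      background = 5, noise_sd = 1,
                                      bf_background = 100, bf_cell_contrast = 40,
                                      bf_texture_sd = 30,
                                      cyto_au = 100, nucleus_frac = 0.5)) {
  level_mode <- match.arg(level_mode)
  level_params <- modifyList(default_level_params(level_mode),
                             level_params %||% list())
  response_params <- modify_response_params(response_params)
  size_dist <- modifyList(list(mean_length = 10, sd = 1.5, min = 7, max = 14),
                          size_dist)
  imaging <- modifyList(list(pixel_size = 0.3, psf_sigma = 0.4, background = 5,
                             noise_sd = 1, bf_background = 100,
                             bf_cell_contrast = 40, bf_texture_sd = 30,
                             cyto_au = 100, nucleus_frac = 0.5),
                        imaging)
  hazard_params <- modifyList(list(baseline = 0.05, size_half = 11,
                                   level_half = 400, sharpness = 8),
                              hazard_params)
  cfg <- structure(list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    size_dist = size_dist, radius_um = radius_um,
    level_mode = level_mode, level_params = level_params,
    response_params = response_params, ref_length_um = ref_length_um,
    ploidy_inhibition = ploidy_inhibition, hazard_params = hazard_params,
    growth_rate_um_min = growth_rate_um_min,
    level_accum_rate = level_accum_rate, level_floor_au = level_floor_au,
    frame_interval_min = frame_interval_min,
    skip_division_prob = skip_division_prob, imaging = imaging),
    class = "sim_config")
  validate_sim_config(cfg)
}

default_level_params <- function(level_mode) {
  if (level_mode == "size_scaled") {
    list(slope = 12, intercept = 50, noise_sd = 40)
  } else {
    list(rate = 0.25, start_lag = 1000, noise_sd = 40, sample_time = 5000)
  }
}

# genotype backgrounds: WT/AF = tyrosine phosphorylation present/absent,
# _PP2AD = ppa2 deletion. Couplings and K0s are chosen so WT raises the
# threshold most steeply in short cells and AF_PP2AD is shallow and graded.
default_response_params <- function() {
  list(
    WT = list(K0 = 900, slope_h = 8, top = 10, bottom = 1,
              size_coupling = 0.25, bistable = TRUE, switch_noise = 0.8),
    WT_PP2AD = list(K0 = 500, slope_h = 8, top = 10, bottom = 1,
                    size_coupling = 0.25, bistable = TRUE, switch_noise = 0.8),
    AF = list(K0 = 450, slope_h = 3, top = 10, bottom = 1,
              size_coupling = 0.12, bistable = FALSE, switch_noise = 0.8),
    AF_PP2AD = list(K0 = 250, slope_h = 1.5, top = 10, bottom = 1,
                    size_coupling = 0.06, bistable = FALSE, switch_noise = 0.8)
  )
}

modify_response_params <- function(user) {
  base <- default_response_params()
  if (is.null(user)) return(base)
  for (g in names(user)) {
    base[[g]] <- modifyList(base[[g]] %||% base$WT, user[[g]])
  }
  base
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    check_pos(n_cells, "n_cells")
    check_pos(size_dist$mean_length, "size_dist$mean_length")
    check_pos(size_dist$sd, "size_dist$sd")
    check_pos(size_dist$min, "size_dist$min")
    check_pos(size_dist$max, "size_dist$max")
    check_pos(radius_um$haploid, "radius_um$haploid")
    check_pos(radius_um$diploid, "radius_um$diploid")
    check_pos(ref_length_um, "ref_length_um")
    check_pos(frame_interval_min, "frame_interval_min")
    check_pos(growth_rate_um_min, "growth_rate_um_min")
    check_pos(level_accum_rate, "level_accum_rate")
    check_pos(level_floor_au, "level_floor_au")
    check_prob(skip_division_prob, "skip_division_prob")
    check_pos(ploidy_inhibition$gamma, "ploidy_inhibition$gamma",
              allow_zero = TRUE)
    check_pos(hazard_params$baseline, "hazard_params$baseline",
              allow_zero = TRUE)
    check_pos(hazard_params$size_half, "hazard_params$size_half")
    check_pos(hazard_params$level_half, "hazard_params$level_half")
    check_pos(hazard_params$sharpness, "hazard_params$sharpness")
    check_pos(imaging$pixel_size, "imaging$pixel_size")
    check_pos(imaging$psf_sigma, "imaging$psf_sigma", allow_zero = TRUE)
    check_pos(imaging$noise_sd, "imaging$noise_sd", allow_zero = TRUE)
    check_pos(imaging$background, "imaging$background", allow_zero = TRUE)
    for (g in names(response_params)) {
      rp <- response_params[[g]]
      check_pos(rp$K0, paste0("response_params$", g, "$K0"))
      check_pos(rp$slope_h, paste0("response_params$", g, "$slope_h"))
      if (!is.finite(rp$top) || !is.finite(rp$bottom) || rp$top < rp$bottom) {
        abort(sprintf("response_params$%s: need finite top >= bottom", g),
              class = "cdkflow_config_error")
      }
      if (!is.finite(rp$size_coupling)) {
        abort(sprintf("response_params$%s$size_coupling must be finite", g),
              class = "cdkflow_config_error")
      }
      check_pos(rp$switch_noise, paste0("response_params$", g, "$switch_noise"),
                allow_zero = TRUE)
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " n_cells:", x$n_cells, "\n")
  cat("  level_mode:", x$level_mode, "\n")
  cat("  genotypes:", paste(names(x$response_params), collapse = ", "), "\n")
  cat("  ploidy gamma:", x$ploidy_inhibition$gamma,
      " skip_division_prob:", x$skip_division_prob, "\n")
  invisible(x)
}

# effective half-activation threshold (AU): K0 scaled down exponentially in
# length about the reference, plus the additive DNA-per-volume term
k_effective <- function(cfg, genotype, length_um, ploidy = "haploid") {
  rp <- cfg$response_params[[genotype]]
  if (is.null(rp)) {
    abort(sprintf("unknown genotype background '%s'", genotype),
          class = "cdkflow_config_error")
  }
  radius <- cfg$radius_um[[ploidy]]
  vol <- cylinder_volume(radius, length_um)
  dna <- cfg$ploidy_inhibition$dna_units[[ploidy]]
  rp$K0 * exp(-rp$size_coupling * (length_um - cfg$ref_length_um)) +
    cfg$ploidy_inhibition$gamma * dna / vol
}

# graded mean response at a given level for an effective threshold
graded_activity <- function(level, k_eff, slope_h, top, bottom) {
  bottom + (top - bottom) / (1 + (k_eff / level)^slope_h)
}
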