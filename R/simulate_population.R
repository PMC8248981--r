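#' Simulate a single-timepoint cell population with ground truth
#'
#' Draws a steady-state population of G2-arrested cells: truncated-normal
#' lengths, a C-CDK level that either scales with cell size or follows a
#' size-independent induction ramp, and a CDK activity drawn from the
#' configured response model. The effective half-activation threshold of
#' each cell is \eqn{K_{eff} = K_0 e^{-c (L - L_{ref})} + \gamma\,
#' \mathrm{DNA}/V}: longer cells activate at lower C-CDK levels, and DNA
#' content per volume raises the threshold. Graded backgrounds emit the mean
#' response plus noise; bistable backgrounds switch "on" with the same
#' logistic probability and emit from the on- or off-state distribution.
#'
#' @param config A [sim_config()].
#' @param genotype Genotype background(s) to simulate, a subset of
#'   `names(config$response_params)`. Cells are split evenly.
#' @param ploidy `"haploid"`, `"diploid"`, or both.
#' @return A tibble with one row per cell: identifiers, geometry
#'   (`length_um`, `radius_um`, `volume_fl`, `area_px2`), `cdk_level_au`,
#'   `activity_nc`, plus ground-truth columns (`true_k_eff`, `true_on`,
#'   `true_activity_mean`).
#' @examples
#' pop <- simulate_population(sim_config(seed = 2, n_cells = 200))
#' dplyr::count(pop, genotype, true_on)
#' @export
simulate_population <- function(config,
                                genotype = names(config$response_params),
                                ploidy = "haploid") {
  stopifnot(inherits(config, "sim_config"))
  genotype <- match.arg(genotype, names(config$response_params),
                        several.ok = TRUE)
  ploidy <- match.arg(ploidy, c("haploid", "diploid"), several.ok = TRUE)
  use_substream(config$seed, "population")

  n <- config$n_cells
  combos <- expand.grid(genotype = genotype, ploidy = ploidy,
                        stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(combos)), length.out = n)
  geno <- combos$genotype[idx]
  plo <- combos$ploidy[idx]

  length_um <- rtruncnorm(n, config$size_dist$mean_length, config$size_dist$sd,
                          config$size_dist$min, config$size_dist$max)
  radius_um <- unlist(config$radius_um)[plo]
  volume_fl <- cylinder_volume(radius_um, length_um)
  # projected 2-D area of a rod of total length L with semicircular caps:
  # (L - 2r) * 2r + pi r^2
  area_um2 <- 2 * radius_um * length_um + (pi - 4) * radius_um^2
  area_px2 <- area_um2 / config$imaging$pixel_size^2

  lev <- draw_level(config, n, area_um2)
  level <- lev$level

  k_eff <- vapply(seq_len(n), function(i) {
    k_effective(config, geno[i], length_um[i], plo[i])
  }, numeric(1))

  act <- draw_activity(config, geno, level, k_eff)

  tibble(
    cell_id = sprintf("cell_%05d", seq_len(n)),
    sample_id = "sim",
    time_s = lev$time_s,
    genotype = geno,
    ploidy = ifelse(plo == "diploid", 2L, 1L),
    length_um = length_um,
    radius_um = unname(radius_um),
    area_px2 = area_px2,
    volume_fl = volume_fl,
    cdk_level_au = level,
    activity_nc = act$activity,
    gated = TRUE,
    true_k_eff = k_eff,
    true_on = act$on,
    true_activity_mean = act$mean
  )
}

# truncated normal by rejection; vectorised enough for n up to ~1e6
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)), mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

draw_level <- function(config, n, area_um2) {
  lp <- config$level_params
  if (config$level_mode == "size_scaled") {
    lev <- lp$slope * area_um2 + lp$intercept + rnorm(n, 0, lp$noise_sd)
    t_s <- rep(0, n)
  } else {
    # sequential sampling during induction: each cell is imaged at a
    # uniform time within the sampling window, so levels span the whole
    # ramp independently of cell size
    t_s <- runif(n, lp$start_lag, lp$sample_time)
    lev <- (t_s - lp$start_lag) * lp$rate + rnorm(n, 0, lp$noise_sd)
  }
  list(level = pmax(lev, 1), time_s = t_s)
}

draw_activity <- function(config, geno, level, k_eff) {
  n <- length(level)
  rp <- config$response_params
  slope_h <- vapply(geno, function(g) rp[[g]]$slope_h, numeric(1))
  top <- vapply(geno, function(g) rp[[g]]$top, numeric(1))
  bottom <- vapply(geno, function(g) rp[[g]]$bottom, numeric(1))
  noise <- vapply(geno, function(g) rp[[g]]$switch_noise, numeric(1))
  bist <- vapply(geno, function(g) isTRUE(rp[[g]]$bistable), logical(1))

  p_on <- 1 / (1 + (k_eff / level)^slope_h)
  mean_act <- bottom + (top - bottom) * p_on
  on <- rep(NA, n)
  activity <- numeric(n)

  gr <- !bist
  if (any(gr)) {
    activity[gr] <- mean_act[gr] + rnorm(sum(gr), 0, noise[gr])
  }
  if (any(bist)) {
    on_state <- runif(sum(bist)) < p_on[bist]
    on[bist] <- on_state
    centre <- ifelse(on_state, top[bist], bottom[bist])
    activity[bist] <- centre + rnorm(sum(bist), 0, noise[bist])
  }
  activity <- pmax(activity, 0.05)
  list(activity = activity, on = on, mean = mean_act)
}
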