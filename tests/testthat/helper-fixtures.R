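# small shared fixtures; everything is generated in code at test time

quiet_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, ...)
}

# noiseless imaging for exact render checks
noiseless_cfg <- function(seed = 1, psf_sigma = 0, ...) {
  sim_config(seed = seed,
             imaging = list(psf_sigma = psf_sigma, background = 0,
                            noise_sd = 0),
             ...)
}

truth_row <- function(cell_id = "t1", length_um = 10, radius_um = 1.75,
                      cdk_level_au = 300, activity_nc = 2) {
  list(cell_id = cell_id, length_um = length_um, radius_um = radius_um,
       cdk_level_au = cdk_level_au, activity_nc = activity_nc)
}

# hand-built profile for activity tests
make_profile <- function(values) {
  structure(list(positions = seq_along(values), intensities = values,
                 width = 3L, centre = (length(values) + 1) / 2,
                 half_extent = length(values) / 2),
            class = "midline_profile")
}

# brute-force oracle: best 3x3 block mean over windows fully inside mask
brute_force_level <- function(channel, mask) {
  nr <- nrow(channel); nc <- ncol(channel)
  best <- -Inf
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    win_m <- mask[(i - 1):(i + 1), (j - 1):(j + 1)]
    if (all(win_m)) {
      best <- max(best, mean(channel[(i - 1):(i + 1), (j - 1):(j + 1)]))
    }
  }
  best
}
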