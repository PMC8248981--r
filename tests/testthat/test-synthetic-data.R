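test_that("sim_config validates parameters and rejects bad values", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(skip_division_prob = 1.5),
               class = "cdkflow_config_error")
  expect_error(sim_config(size_dist = list(sd = -1)),
               class = "cdkflow_config_error")
  expect_error(sim_config(response_params = list(WT = list(slope_h = -2))),
               class = "cdkflow_config_error")
  expect_error(sim_config(imaging = list(pixel_size = 0)),
               class = "cdkflow_config_error")
})

test_that("population simulation is deterministic under a fixed seed", {
  cfg <- quiet_cfg(seed = 42, n_cells = 300)
  p1 <- simulate_population(cfg)
  p2 <- simulate_population(cfg)
  expect_identical(p1, p2)
  p3 <- simulate_population(quiet_cfg(seed = 43, n_cells = 300))
  expect_false(identical(p1$cdk_level_au, p3$cdk_level_au))
})

test_that("graded activity hits the midpoint at level = K_eff", {
  # gamma = 0, size_coupling = 0 => K_eff = K0 exactly
  cfg <- quiet_cfg(
    n_cells = 10,
    ploidy_inhibition = list(gamma = 0,
                             dna_units = list(haploid = 1, diploid = 2)),
    response_params = list(AF = list(K0 = 400, size_coupling = 0,
                                     switch_noise = 0, slope_h = 3)))
  k <- cdkflow:::k_effective(cfg, "AF", length_um = 12)
  expect_equal(k, 400)
  rp <- cfg$response_params$AF
  act <- cdkflow:::graded_activity(400, k, rp$slope_h, rp$top, rp$bottom)
  expect_equal(act, (rp$top + rp$bottom) / 2)
})

test_that("K_eff is monotone in DNA-per-volume at equal cell volume", {
  cfg <- quiet_cfg()
  # equalise volume: pick diploid length so pi r^2 L matches the haploid's
  hap_len <- 10
  vol <- pi * cfg$radius_um$haploid^2 * hap_len
  dip_len <- vol / (pi * cfg$radius_um$diploid^2)
  k_hap <- cdkflow:::k_effective(cfg, "AF_PP2AD", hap_len, "haploid")
  cfg_eq <- quiet_cfg(ref_length_um = 10)
  # compare at equal volume and matched size term (set coupling to 0)
  cfg0 <- quiet_cfg(response_params = list(AF_PP2AD = list(size_coupling = 0)))
  k_h <- cdkflow:::k_effective(cfg0, "AF_PP2AD", hap_len, "haploid")
  k_d <- cdkflow:::k_effective(cfg0, "AF_PP2AD", dip_len, "diploid")
  expect_gt(k_d, k_h)
})

test_that("empirical mean activity matches the closed-form curve", {
  # narrow size bin via a tight size distribution, graded mode
  cfg <- quiet_cfg(seed = 7, n_cells = 10000,
                   size_dist = list(mean_length = 10, sd = 0.01,
                                    min = 9.95, max = 10.05),
                   level_mode = "induction")
  pop <- simulate_population(cfg, genotype = "AF_PP2AD")
  k <- cdkflow:::k_effective(cfg, "AF_PP2AD", 10)
  rp <- cfg$response_params$AF_PP2AD
  for (lev in c(200, 400, 700)) {
    sub <- dplyr::filter(pop, abs(cdk_level_au - lev) < 25)
    expected <- cdkflow:::graded_activity(lev, k, rp$slope_h, rp$top,
                                          rp$bottom)
    se <- sd(sub$activity_nc) / sqrt(nrow(sub))
    # 3 standard errors plus the curve's slope across the 50-AU window
    slack <- 3 * se + 0.1
    expect_lt(abs(mean(sub$activity_nc) - expected), slack)
  }
})

test_that("level-size correlation is high in size_scaled mode, absent in induction", {
  cfg_s <- quiet_cfg(seed = 5, n_cells = 3000,
                     level_params = list(noise_sd = 10))
  pop_s <- simulate_population(cfg_s, genotype = "AF")
  expect_gt(cor(pop_s$cdk_level_au, pop_s$length_um), 0.9)

  cfg_i <- quiet_cfg(seed = 5, n_cells = 3000, level_mode = "induction")
  pop_i <- simulate_population(cfg_i, genotype = "AF")
  expect_lt(abs(cor(pop_i$cdk_level_au, pop_i$length_um)), 0.1)
})

test_that("lineages: zero hazard gives monotone growth and no events", {
  cfg <- quiet_cfg(seed = 2, hazard_params = list(baseline = 0))
  tr <- simulate_lineages(cfg, 10, 90)
  expect_equal(nrow(tr$events), 0)
  growth <- tr$frames %>%
    dplyr::group_by(cell_id) %>%
    dplyr::summarise(mono = all(diff(size) > 0))
  expect_true(all(growth$mono))
})

test_that("lineages: skip_division_prob = 1 yields only unpaired degradations", {
  cfg <- quiet_cfg(seed = 3, skip_division_prob = 1)
  tr <- simulate_lineages(cfg, 80, 300)
  expect_gt(nrow(tr$events), 0)
  expect_true(all(tr$events$kind == "degradation_without_division"))
})

test_that("constant-hazard event fraction matches the analytic value", {
  lambda <- 0.02
  cfg <- quiet_cfg(seed = 5,
                   hazard_params = list(baseline = lambda, size_half = 1e-6,
                                        level_half = 1e-6, sharpness = 8))
  tr <- simulate_lineages(cfg, 300, 150)  # >= 1e4 cell-frames
  dt <- tr$frame_interval_min
  at_risk <- tr$frames %>%
    dplyr::group_by(cell_id) %>%
    dplyr::filter(frame < max(frame)) %>% nrow()
  n_events <- sum(tr$events$kind != "division")
  p_hat <- n_events / at_risk
  p_true <- 1 - exp(-lambda * dt)
  se <- sqrt(p_true * (1 - p_true) / at_risk)
  expect_lt(abs(p_hat - p_true), 3 * se)
})

test_that("degradation-without-division fraction converges to skip_division_prob", {
  cfg <- quiet_cfg(seed = 8, skip_division_prob = 0.2)
  tr <- simulate_lineages(cfg, 300, 400)
  deg <- tr$events[tr$events$kind != "division", ]
  frac <- mean(deg$kind == "degradation_without_division")
  n <- nrow(deg)
  ci <- stats::binom.test(round(frac * n), n)$conf.int
  expect_gt(n, 500)
  expect_true(ci[1] <= 0.2 && 0.2 <= ci[2])
})
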