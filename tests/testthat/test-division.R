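# build a minimal lineage_traces object by hand
manual_traces <- function(level_by_cell, size_by_cell = NULL, dt = 5) {
  frames <- purrr::imap_dfr(level_by_cell, function(lv, id) {
    tibble::tibble(cell_id = id, frame = seq_along(lv),
                   time_min = (seq_along(lv) - 1) * dt,
                   size = if (is.null(size_by_cell)) 10 + seq_along(lv) * 0.1
                          else size_by_cell[[id]],
                   level_au = lv, activity_nc = 1)
  })
  cdkflow:::new_lineage_traces(frames,
                               tibble::tibble(cell_id = character(),
                                              frame = integer(),
                                              time_min = numeric(),
                                              kind = character()), dt)
}

test_that("estimate_pdiv trivial rates: no events and certain events", {
  tr <- manual_traces(list(a = c(100, 120, 140, 160)))
  pd <- estimate_pdiv(tr, "size", 10)
  expect_true(all(pd$rate_per_min == 0))

  # an event after every timepoint at dt = 5 min gives 0.2 per min
  tr2 <- manual_traces(list(a = c(100, 120, 140)))
  ev <- tibble::tibble(cell_id = "a", frame = 2:3)
  pd2 <- estimate_pdiv(tr2, "size", 100, events = ev)
  expect_equal(pd2$rate_per_min, 0.2)
})

test_that("estimate_pdiv matches the analytic constant-hazard rate", {
  lambda <- 0.02
  cfg <- quiet_cfg(seed = 5,
                   hazard_params = list(baseline = lambda, size_half = 1e-6,
                                        level_half = 1e-6, sharpness = 8))
  tr <- simulate_lineages(cfg, 300, 150)
  pd <- estimate_pdiv(tr, "size", 1000)  # one big bin
  dt <- tr$frame_interval_min
  p_true <- 1 - exp(-lambda * dt)
  se <- sqrt(p_true * (1 - p_true) / pd$n_timepoints)
  expect_gt(pd$n_timepoints, 1e4)
  expect_lt(abs(pd$rate_per_min - p_true / dt), 3 * se / dt)
})

test_that("pdiv rises with size under the generator's hazard", {
  cfg <- quiet_cfg(seed = 6)
  tr <- simulate_lineages(cfg, 200, 300)
  pd <- estimate_pdiv(tr, "size", 2)
  ok <- pd[!pd$low_n, ]
  expect_gt(ok$rate_per_min[nrow(ok)], ok$rate_per_min[1])
})

test_that("threshold_level trivial cases: always-on, never-on", {
  set.seed(1)
  recs <- tibble::tibble(length_um = runif(200, 9.2, 9.8),
                         cdk_level_au = runif(200, 100, 900),
                         activity_nc = 10, gated = TRUE)
  tc <- threshold_level(recs, min_n = 20)
  expect_true(tc$defined[1])
  # all cells on: threshold is the lowest occupied level window centre
  expect_lte(tc$threshold_level_au[1], min(recs$cdk_level_au) + 100)

  recs0 <- dplyr::mutate(recs, activity_nc = 0.2)
  tc0 <- threshold_level(recs0, min_n = 20)
  expect_false(any(tc0$defined))
  expect_true(all(tc0$reason[!tc0$defined] == "unattainable"))
})

test_that("threshold_level recovers a known logistic midpoint", {
  set.seed(2)
  n <- 5000
  recs <- tibble::tibble(
    length_um = runif(n, 9.2, 9.8),
    cdk_level_au = runif(n, 0, 1000),
    gated = TRUE)
  p_on <- stats::plogis((recs$cdk_level_au - 500) / 60)
  recs$activity_nc <- ifelse(stats::runif(n) < p_on, 10, 0.5)
  tc <- threshold_level(recs, min_n = 30)
  expect_true(tc$defined[1])
  expect_lt(abs(tc$threshold_level_au[1] - 500), 25)
})

test_that("threshold_level is monotone non-increasing in `fraction`", {
  set.seed(3)
  n <- 4000
  recs <- tibble::tibble(length_um = runif(n, 9.2, 9.8),
                         cdk_level_au = runif(n, 0, 1000), gated = TRUE)
  p_on <- stats::plogis((recs$cdk_level_au - 400) / 80)
  recs$activity_nc <- ifelse(stats::runif(n) < p_on, 10, 0.5)
  thr <- vapply(c(0.25, 0.5, 0.75), function(f) {
    threshold_level(recs, fraction = f, min_n = 30)$threshold_level_au[1]
  }, numeric(1))
  expect_true(all(diff(thr) >= 0))
})

test_that("synergy algebra is exact and flags caps", {
  mk <- function(vals, defined = rep(TRUE, length(vals))) {
    structure(tibble::tibble(bin_mid = seq_along(vals) + 0.5,
                             n = 100, threshold_level_au = vals,
                             defined = defined, reason = NA_character_),
              class = c("threshold_curve", "tbl_df", "tbl", "data.frame"))
  }
  # additive construction: WT = AF + WT_P - AF_P bin-wise => synergy 0
  af_p <- c(200, 180, 160); wt_p <- c(800, 600, 400); af <- c(500, 420, 340)
  wt <- af + wt_p - af_p
  dec <- decompose_synergy(list(WT = mk(wt), AF = mk(af),
                                WT_PP2AD = mk(wt_p), AF_PP2AD = mk(af_p)))
  expect_equal(dec$synergy, rep(0, 3))
  expect_equal(dec$contrib_yphos_alone, wt_p - af_p)
  expect_false(any(dec$any_capped))

  # the quoted subtraction: 800 - 200 = 600 units restricted by Y-phos
  expect_equal(dec$contrib_yphos_alone[1], 600)

  # undefined WT bin is capped at 1000 and flagged
  dec2 <- decompose_synergy(list(
    WT = mk(c(NA, wt[2:3]), c(FALSE, TRUE, TRUE)), AF = mk(af),
    WT_PP2AD = mk(wt_p), AF_PP2AD = mk(af_p)))
  expect_true(dec2$capped_wt[1])
  expect_true(dec2$any_capped[1])
  expect_equal(dec2$wt[1], 1000)

  # mismatched bins abort
  bad <- mk(af_p); bad$bin_mid <- bad$bin_mid + 1
  expect_error(decompose_synergy(list(WT = mk(wt), AF = mk(af),
                                      WT_PP2AD = mk(wt_p), AF_PP2AD = bad)),
               class = "cdkflow_alignment_error")
})
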