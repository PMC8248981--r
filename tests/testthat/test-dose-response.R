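test_that("hill_model identities: midpoint, limits, monotonicity", {
  for (h in c(-1.71, -0.5, 1, 3)) {
    expect_equal(hill_model(115.4, 115.4, h, top = 1, bottom = 0), 0.5)
  }
  # decreasing curve: top at dose 0, bottom at saturating dose
  expect_equal(hill_model(0, 115.4, -1.71, top = 1, bottom = 0.1), 1)
  expect_equal(hill_model(1e9, 115.4, -1.71, top = 1, bottom = 0.1), 0.1,
               tolerance = 1e-4)
  d <- seq(1, 1000, length.out = 50)
  expect_true(all(diff(hill_model(d, 100, -1.71)) < 0))
  expect_true(all(diff(hill_model(d, 100, 2)) > 0))
  expect_error(hill_model(-1, 100, 1), class = "cdkflow_domain_error")
})

test_that("hill_model matches an independent log-logistic evaluation", {
  # oracle: four-parameter log-logistic written directly from its formula
  loglogistic <- function(x, e, b, top, bottom) {
    bottom + (top - bottom) / (1 + exp(b * (log(x) - log(e))))
  }
  d <- exp(seq(log(5), log(2000), length.out = 20))
  ours <- hill_model(d, ic50 = 115.4, hill_coef = -1.71, top = 1,
                     bottom = 0.05)
  # (d/e)^(-h) = exp(-h (log d - log e)); with h = -1.71, b = 1.71
  oracle <- loglogistic(d, 115.4, 1.71, 1, 0.05)
  expect_equal(ours, oracle)
})

test_that("fit_hill recovers generating parameters from noiseless data", {
  d <- c(0, 31.25, 62.5, 125, 250, 500, 1000)
  y <- hill_model(d, ic50 = 115.4, hill_coef = -1.71, top = 1, bottom = 0)
  fit <- fit_hill(d, y)
  expect_true(fit$converged)
  expect_lt(abs(fit$ic50 - 115.4) / 115.4, 0.01)
  expect_lt(abs(fit$hill_coef - (-1.71)) / 1.71, 0.01)
})

test_that("flat responses do not converge", {
  d <- c(0, 10, 100, 1000, 10000)
  fit <- fit_hill(d, rep(0.4, 5))
  expect_false(fit$converged)
})

test_that("insufficient distinct doses raise an error", {
  expect_error(fit_hill(c(1, 1, 2, 2), c(1, 1, 0, 0)),
               class = "cdkflow_insufficient_data")
})

test_that("fitted RSS beats a 50x50 grid search with plateaus fixed", {
  set.seed(4)
  d <- c(0, 31.25, 62.5, 125, 250, 500, 1000)
  y <- hill_model(d, 115.4, -1.71) + rnorm(7, 0, 0.03)
  fit <- fit_hill(d, y)
  rss_at <- function(ic, h) {
    sum((y - hill_model(d, ic, h, fit$top, fit$bottom))^2)
  }
  grid_rss <- outer(exp(seq(log(20), log(800), length.out = 50)),
                    seq(-4, -0.2, length.out = 50), Vectorize(rss_at))
  expect_lte(fit$rss, min(grid_rss) + 1e-10)

  l <- exp(seq(log(20), log(1500), length.out = 25))
  a <- sigmoid_model(l, 372, 2, top = 10, bottom = 1) + rnorm(25, 0, 0.2)
  sfit <- fit_sigmoid(l, a)
  srss_at <- function(ec, s) {
    sum((a - sigmoid_model(l, ec, s, sfit$top, sfit$bottom))^2)
  }
  sgrid <- outer(exp(seq(log(100), log(1200), length.out = 50)),
                 seq(0.3, 6, length.out = 50), Vectorize(srss_at))
  expect_lte(sfit$rss, min(sgrid) + 1e-10)
})

test_that("fit_sigmoid recovers a known slope-1 sigmoid exactly", {
  l <- exp(seq(log(10), log(3000), length.out = 30))
  a <- sigmoid_model(l, ec50 = 500, slope = 1, top = 8, bottom = 0.5)
  fit <- fit_sigmoid(l, a)
  expect_true(fit$converged)
  expect_equal(fit$ic50, 500, tolerance = 1e-4)
  expect_equal(fit$hill_coef, 1, tolerance = 1e-4)
  expect_equal(fit$top, 8, tolerance = 1e-4)
})

test_that("EC50 bias under 5% noise stays below 3% over 200 replicates", {
  set.seed(10)
  l <- exp(seq(log(30), log(2000), length.out = 25))
  truth <- sigmoid_model(l, 372, 2, top = 10, bottom = 1)
  ec <- replicate(200, {
    fit <- fit_sigmoid(l, truth + rnorm(25, 0, 0.5))
    fit$ic50
  })
  expect_lt(abs(mean(ec) - 372) / 372, 0.03)
})

test_that("tidy/glance/predict/autoplot work on fits", {
  l <- exp(seq(log(10), log(2000), length.out = 20))
  fit <- fit_sigmoid(l, sigmoid_model(l, 372, 2, top = 10, bottom = 1))
  td <- tidy(fit)
  expect_setequal(td$term, c("ec50", "slope", "top", "bottom"))
  expect_true(glance(fit)$converged)
  expect_equal(predict(fit, tibble::tibble(x = 372)), 5.5, tolerance = 1e-3)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("diploid populations fit a larger EC50 than haploids when DNA titrates", {
  # compare at matched VOLUME (diploids are wider, so equal-length cells
  # have nearly equal DNA-per-volume): diploid lengths are scaled by the
  # radius ratio squared so the volume distributions coincide
  mk_cfg <- function(gamma, diploid = FALSE, seed = 55) {
    scale <- if (diploid) (1.75 / 2.4)^2 else 1
    quiet_cfg(seed = seed, n_cells = 8000, level_mode = "induction",
              size_dist = list(mean_length = 12 * scale, sd = 1.5 * scale,
                               min = 9 * scale, max = 15 * scale),
              ploidy_inhibition = list(
                gamma = gamma, dna_units = list(haploid = 1, diploid = 2)),
              response_params = list(AF_PP2AD = list(size_coupling = 0)))
  }
  fit_ec50 <- function(cfg, ploidy) {
    pop <- simulate_population(cfg, genotype = "AF_PP2AD", ploidy = ploidy)
    fit <- fit_sigmoid(pop$cdk_level_au, pop$activity_nc)
    expect_true(fit$converged)
    fit$ic50
  }
  e_h <- fit_ec50(mk_cfg(12000), "haploid")
  e_d <- fit_ec50(mk_cfg(12000, diploid = TRUE), "diploid")
  expect_gt(e_d, 1.1 * e_h)

  # with gamma = 0 the ploidy effect disappears
  e_h0 <- fit_ec50(mk_cfg(0, seed = 56), "haploid")
  e_d0 <- fit_ec50(mk_cfg(0, diploid = TRUE, seed = 56), "diploid")
  expect_lt(abs(e_d0 - e_h0) / e_h0, 0.1)
})

test_that("normalisation divides by the reference median", {
  expect_equal(normalize_to_reference(c(2, 2, 2), c(2, 2, 2)), c(1, 1, 1))
  expect_equal(normalize_to_reference(1, c(1, 2, 3)), 0.5)
  set.seed(2)
  v <- runif(50); ref <- runif(20, 1, 3)
  expect_equal(normalize_to_reference(v, ref), v / median(ref))
  expect_error(normalize_to_reference(1, numeric(0)),
               class = "cdkflow_normalisation_error")
  expect_error(normalize_to_reference(1, c(-2, -1)),
               class = "cdkflow_normalisation_error")
})

test_that("binned_response matches group-by means and flags small bins", {
  one <- tibble::tibble(area_px2 = 1234, activity_nc = 2.5, gated = TRUE)
  br <- binned_response(one, "area_px2", 500)
  expect_equal(nrow(br), 1)
  expect_equal(br$mean, 2.5)
  expect_true(br$low_n)

  set.seed(6)
  recs <- tibble::tibble(area_px2 = runif(500, 0, 5000),
                         activity_nc = rnorm(500, 3), gated = TRUE)
  br <- binned_response(recs, "area_px2", 500, min_n = 10)
  # group-by oracle at the conventional 500 px^2 area window
  oracle <- recs %>%
    dplyr::mutate(bin = floor(area_px2 / 500)) %>%
    dplyr::group_by(bin) %>%
    dplyr::summarise(m = mean(activity_nc), n = dplyr::n())
  expect_equal(br$mean, oracle$m)
  expect_equal(br$n, oracle$n)
  expect_equal(unique(br$bin_hi - br$bin_lo), 500)

  expect_error(binned_response(dplyr::mutate(recs, gated = FALSE),
                               "area_px2", 500),
               class = "cdkflow_empty_result")
})
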