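test_that("forward response evaluates the sigmoid exactly", {
  m <- calibration_model(0.2, 2.0, 6.5, 1.0)
  # midpoint at ph = pKa
  expect_equal(forward_response(m, 6.5), 1.1)
  # direct evaluation one pH unit above the pKa
  expect_equal(forward_response(m, 7.5), 0.2 + 1.8 / (1 + 10^(-1)),
               tolerance = 1e-12)
  # asymptotes approached but never reached
  expect_lt(forward_response(m, 12), 2.0)
  expect_gt(forward_response(m, 1), 0.2)
  expect_equal(forward_response(m, 14), 2.0, tolerance = 1e-6)
  expect_equal(forward_response(m, -1), 0.2, tolerance = 1e-6)
  expect_error(forward_response(m, NA_real_), "finite")
})

test_that("inversion returns pH in range and the sentinel outside", {
  m <- calibration_model(0.2, 2.0, 6.5, 1.0)
  expect_equal(invert_response(m, 1.1), 6.5)
  expect_equal(invert_response(m, 0.2 + 1.8 / (1 + 10^(-1))), 7.5,
               tolerance = 1e-12)
  # at or beyond the asymptotes: out-of-range sentinel, never an error
  expect_true(is.na(invert_response(m, 0.2)))
  expect_true(is.na(invert_response(m, 2.0)))
  expect_true(is.na(invert_response(m, -1)))
  expect_true(is.na(invert_response(m, Inf)))
})

test_that("forward/invert round-trip is the identity to 1e-9", {
  for (m in list(calibration_model(0.2, 2.0, 6.5, 1.0),
                 calibration_model(0.05, 1.3, 4.8, 0.7),
                 calibration_model(0.5, 3.0, 5.5, -1.4))) {
    eps <- 1e-6 * (m$r_max - m$r_min)
    r <- seq(m$r_min + eps, m$r_max - eps, length.out = 500)
    expect_equal(forward_response(m, invert_response(m, r)), r,
                 tolerance = 1e-9)
    ph <- seq(1, 12, length.out = 500)
    expect_equal(invert_response(m, forward_response(m, ph)), ph,
                 tolerance = 1e-9)
  }
})

test_that("forward response is strictly monotone with the hillslope sign", {
  grid <- seq(0, 14, length.out = 1000)
  up <- forward_response(calibration_model(0.2, 2.0, 6.5, 1.0), grid)
  expect_true(all(diff(up) > 0))
  down <- forward_response(calibration_model(0.2, 2.0, 6.5, -1.0), grid)
  expect_true(all(diff(down) < 0))
})

test_that("noiseless calibration points are recovered exactly", {
  truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
  pts <- data.frame(ph = buffer_series_recipes$ph)
  pts$ratio <- forward_response(truth, pts$ph)
  fit <- fit_calibration(pts)
  expect_equal(fit$r_min, 0.2, tolerance = 1e-6)
  expect_equal(fit$r_max, 2.0, tolerance = 1e-6)
  expect_equal(fit$pka, 6.5, tolerance = 1e-6)
  expect_equal(fit$hillslope, 1.0, tolerance = 1e-6)
  expect_equal(fit$ph_range, c(2.5, 8.0))
  # midpoint structural property of any converged fit
  expect_equal(forward_response(fit, fit$pka), (fit$r_min + fit$r_max) / 2)
  # decreasing-response fluorophore: same machinery, negative hillslope
  dtruth <- calibration_model(0.3, 1.5, 5.5, -0.8)
  dpts <- data.frame(ph = buffer_series_recipes$ph)
  dpts$ratio <- forward_response(dtruth, dpts$ph)
  dfit <- fit_calibration(dpts)
  expect_equal(dfit$hillslope, -0.8, tolerance = 1e-6)
  expect_equal(dfit$pka, 5.5, tolerance = 1e-6)
})

test_that("the fitted objective matches a brute-force grid-search oracle", {
  truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
  pts <- simulate_calibration_points(truth, sigma = 0.02, seed = 7)
  fit <- fit_calibration(pts)
  oracle <- grid_search_sigmoid(pts$ph, pts$ratio)
  expect_equal(fit$fit_stats$rss, oracle$objective, tolerance = 1e-6)
  expect_lte(fit$fit_stats$rss, oracle$objective + 1e-9)
})

test_that("fit requires enough points and respects weights", {
  truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
  few <- data.frame(ph = c(5, 6, 7, 8), ratio = forward_response(truth, c(5, 6, 7, 8)))
  expect_error(fit_calibration(few), "at least 5 points")
  # one wild point with weight 0 must not influence the fit
  pts <- data.frame(ph = buffer_series_recipes$ph)
  pts$ratio <- forward_response(truth, pts$ph)
  pts$weight <- 1
  spoiled <- rbind(pts, data.frame(ph = 5.2, ratio = 10, weight = 0))
  fit <- fit_calibration(spoiled)
  expect_equal(fit$pka, 6.5, tolerance = 1e-6)
})

test_that("mean fitted pKa over noisy replicates stays within 0.05 of truth", {
  truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
  pkas <- vapply(1:100, function(s)
    fit_calibration(simulate_calibration_points(truth, sigma = 0.02,
                                                seed = s))$pka,
    numeric(1))
  expect_lt(abs(mean(pkas) - 6.5), 0.05)
})

test_that("image-based calibration recovers the generating curve", {
  spec <- single_fluor_spec()
  stack <- simulate_calibration_stack(spec, noise = NULL, shape = c(16, 16),
                                      sensor_fraction = 1)
  model <- calibrate_from_images(stack)
  expect_equal(model$r_min, 0.1, tolerance = 1e-4)
  expect_equal(model$r_max, 0.9, tolerance = 1e-4)
  expect_equal(model$pka, 6.5, tolerance = 1e-4)
  expect_equal(model$hillslope, 1.0, tolerance = 1e-4)
})

test_that("image-based calibration is deterministic and matches a flat-loop oracle", {
  spec <- single_fluor_spec()
  s1 <- simulate_calibration_stack(spec, noise = noise_model(seed = 3),
                                   shape = c(24, 24), sensor_fraction = 0.3)
  s2 <- simulate_calibration_stack(spec, noise = noise_model(seed = 3),
                                   shape = c(24, 24), sensor_fraction = 0.3)
  expect_identical(lapply(s1, function(e) e$pair$indicator),
                   lapply(s2, function(e) e$pair$indicator))
  m1 <- calibrate_from_images(s1)
  m2 <- calibrate_from_images(s2)
  expect_identical(unclass(m1)[1:4], unclass(m2)[1:4])
  # per-image weighted mean ratio equals total indicator / total reference
  for (e in s1[c(1, 6, 12)]) {
    mask <- build_mask(e$pair$reference, 0)
    rf <- compute_ratio_field(e$pair, mask)
    expect_equal(sum(rf$weight * rf$ratio), flat_mean_ratio(e$pair, 0),
                 tolerance = 1e-12)
  }
})

test_that("calibration model and points survive serialization round trips", {
  truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
  pts <- simulate_calibration_points(truth, sigma = 0.02, seed = 11)
  fit <- fit_calibration(pts)
  jf <- withr::local_tempfile(fileext = ".json")
  write_calibration(fit, jf)
  back <- read_calibration(jf)
  expect_equal(back$pka, fit$pka)
  expect_equal(back$ph_range, fit$ph_range)
  cf <- withr::local_tempfile(fileext = ".csv")
  write_calibration_points(pts, cf)
  pts2 <- read_calibration_points(cf)
  expect_equal(pts2$ratio, pts$ratio)
  expect_equal(names(pts2), c("ph", "ratio", "weight", "n_pixels"))
})
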