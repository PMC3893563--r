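test_that("the response curve is the term-by-term sum of its fluorophores", {
  spec <- sensor_response_spec()  # dual default: pKa 4.8 + 6.5
  grid <- seq(2.5, 8.5, by = 0.05)
  rc <- response_curve(spec, grid)
  # independent hand summation
  hand <- spec$baseline +
    spec$amplitudes[1] / (1 + 10^((spec$pkas[1] - grid) * spec$hillslopes[1])) +
    spec$amplitudes[2] / (1 + 10^((spec$pkas[2] - grid) * spec$hillslopes[2]))
  expect_equal(rc$indicator, hand, tolerance = 1e-12)
  expect_true(all(rc$reference == spec$reference_amplitude))
  # at pH = 4.8 the acidic fluorophore contributes exactly half its amplitude
  at48 <- response_curve(spec, 4.8)$indicator
  one_term <- spec$baseline + spec$amplitudes[1] / 2 +
    spec$amplitudes[2] / (1 + 10^(6.5 - 4.8))
  expect_equal(at48, one_term, tolerance = 1e-12)
})

test_that("a single-fluorophore spec reduces to the calibration sigmoid", {
  spec <- single_fluor_spec()
  model <- single_fluor_model()
  grid <- seq(2, 9, by = 0.1)
  rc <- response_curve(spec, grid)
  expect_equal(rc$indicator / rc$reference, forward_response(model, grid),
               tolerance = 1e-12)
})

test_that("the dual-fluorophore default keeps sensitivity across the range", {
  spec <- sensor_response_spec()
  grid <- seq(3.0, 8.0, by = 0.01)
  ratio <- response_curve(spec, grid)$indicator / spec$reference_amplitude
  expect_true(all(diff(ratio) >= 0))  # monotone nondecreasing on [3, 8]
  # |dR/dpH| stays above 20% of its maximum over pH 4.0-7.5
  sens <- abs(diff(ratio)) / 0.01
  mid <- grid[-1] - 0.005
  win <- mid >= 4.0 & mid <= 7.5
  expect_gt(min(sens[win]), 0.2 * max(sens))
})

test_that("noiseless calibration stacks carry the exact analytic ratios", {
  spec <- single_fluor_spec()
  stack <- simulate_calibration_stack(spec, ph_values = c(4, 5, 6, 7),
                                      noise = NULL, shape = c(8, 8),
                                      sensor_fraction = 0.5)
  for (e in stack) {
    on <- e$pair$reference > 0
    expect_equal(unique(e$pair$indicator[on] / e$pair$reference[on]),
                 forward_response(single_fluor_model(), e$ph),
                 tolerance = 1e-12)
    expect_equal(unique(e$truth[!is.na(e$truth)]), e$ph)
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_calibration_stack(noise = noise_model(seed = 11),
                                  shape = c(16, 16))
  b <- simulate_calibration_stack(noise = noise_model(seed = 11),
                                  shape = c(16, 16))
  expect_identical(a, b)
  ph <- scene_phantom(c(12, 12), truth_ph = 6, density = 1500)
  s1 <- simulate_cell_scene(ph, noise = noise_model(seed = 4))
  s2 <- simulate_cell_scene(ph, noise = noise_model(seed = 4))
  expect_identical(s1$pair$indicator, s2$pair$indicator)
  s3 <- simulate_cell_scene(ph, noise = noise_model(seed = 5))
  expect_false(identical(s1$pair$indicator, s3$pair$indicator))
})

test_that("a noiseless scene runs through the pipeline back to truth", {
  spec <- single_fluor_spec()
  model <- single_fluor_model()
  set.seed(2)
  truth <- matrix(runif(32 * 32, 3.2, 7.6), 32, 32)
  density <- matrix(0, 32, 32)
  density[sample.int(1024, 300)] <- runif(300, 800, 3000)
  phantom <- scene_phantom(c(32, 32), truth, density)
  sim <- simulate_cell_scene(phantom, spec, noise = NULL)
  res <- measure_ph(sim$pair, model, threshold = 10)
  truth_at <- sim$truth[cbind(res$field$row, res$field$col)]
  expect_equal(res$field$ph, truth_at, tolerance = 1e-6)
  expect_equal(res$field$sentinel_fraction, 0)
  expect_equal(sum(res$histogram$mass) + res$histogram$out_of_range, 1,
               tolerance = 1e-12)
})

test_that("two compartments produce a bimodal weighted histogram", {
  spec <- single_fluor_spec()
  model <- single_fluor_model()
  truth <- matrix(NA_real_, 20, 20)
  density <- matrix(0, 20, 20)
  truth[3:8, 3:8] <- 4.5;  density[3:8, 3:8] <- 2000
  truth[13:18, 13:18] <- 7.0; density[13:18, 13:18] <- 2000
  sim <- simulate_cell_scene(scene_phantom(c(20, 20), truth, density),
                             spec, noise = NULL)
  res <- measure_ph(sim$pair, model, threshold = 10, bin_width = 0.2)
  h <- res$histogram
  mid <- h$breaks[-length(h$breaks)] + h$bin_width / 2
  occupied <- which(h$mass > 0.1)
  expect_equal(length(occupied), 2)
  expect_true(any(abs(mid[occupied] - 4.5) < 0.2))
  expect_true(any(abs(mid[occupied] - 7.0) < 0.2))
})

test_that("without bleed-through the reference channel ignores truth pH", {
  spec <- single_fluor_spec()
  d <- matrix(1000, 10, 10)
  acid <- simulate_cell_scene(scene_phantom(c(10, 10), 4.0, d), spec, NULL)
  base <- simulate_cell_scene(scene_phantom(c(10, 10), 7.5, d), spec, NULL)
  expect_identical(acid$pair$reference, base$pair$reference)
  # with bleed-through it does not
  acid_b <- simulate_cell_scene(
    scene_phantom(c(10, 10), 4.0, d, bleed_fraction = 0.1), spec, NULL)
  base_b <- simulate_cell_scene(
    scene_phantom(c(10, 10), 7.5, d, bleed_fraction = 0.1), spec, NULL)
  expect_true(all(base_b$pair$reference > acid_b$pair$reference))
})

test_that("time-lapse seeding is reproducible and acidification is monotone", {
  spec <- single_fluor_spec()
  model <- single_fluor_model()
  density <- matrix(2000, 16, 16)
  traj <- c(7.2, 6.6, 6.0, 5.4, 4.8)
  phantoms <- lapply(traj, function(p) scene_phantom(c(16, 16), p, density))
  # noiseless: weighted mean pH strictly decreasing along the trajectory
  frames <- simulate_timelapse(phantoms, spec, noise = NULL)
  means <- vapply(frames, function(fr) {
    summarize_ph(measure_ph(fr$pair, model, threshold = 10)$field)$mean_ph_weighted
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_equal(means, traj, tolerance = 1e-6)
  # per-frame seeds: reproducible from the master seed, distinct per frame
  n1 <- simulate_timelapse(phantoms, spec, noise = noise_model(seed = 7))
  n2 <- simulate_timelapse(phantoms, spec, noise = noise_model(seed = 7))
  expect_identical(n1[[3]]$pair$indicator, n2[[3]]$pair$indicator)
  expect_false(identical(n1[[1]]$pair$indicator, n1[[2]]$pair$indicator))
})

test_that("the mean of many noisy replicates converges to the noiseless image", {
  spec <- single_fluor_spec()
  phantom <- scene_phantom(c(16, 16), 6.0, matrix(2000, 16, 16))
  clean <- simulate_cell_scene(phantom, spec, noise = NULL)$pair$indicator
  n <- 1000
  acc <- matrix(0, 16, 16)
  for (s in seq_len(n)) {
    acc <- acc + simulate_cell_scene(phantom, spec,
                                     noise_model(seed = s))$pair$indicator
  }
  rel <- abs(acc / n - clean) / clean
  expect_lt(max(rel), 3 / sqrt(n))
})
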