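#' Spectral response specification of a simulated nanosensor
#'
#' Models the indicator channel as a baseline plus a sum of sigmoidal
#' fluorophore terms and the reference channel as a pH-independent
#' constant (TAMRA-like). The default is the extended-range
#' dual-fluorophore design: equal-amplitude terms at pKa 4.8 (Oregon
#' Green, acidic range) and 6.5 (FAM, near-neutral range), whose sum keeps
#' the sensor responsive across the full physiological range.
#'
#' @param amplitudes per-fluorophore indicator amplitudes (counts).
#' @param pkas per-fluorophore pKa values.
#' @param hillslopes per-fluorophore hillslopes.
#' @param reference_amplitude reference-channel intensity (counts).
#' @param baseline pH-independent indicator offset (counts).
#' @return An object of class `sensor_response_spec`.
#' @export
sensor_response_spec <- function(amplitudes = c(800, 800),
                                 pkas = c(fluorophore_pka[["oregon_green"]],
                                          fluorophore_pka[["fam"]]),
                                 hillslopes = rep(1, length(pkas)),
                                 reference_amplitude = 2000,
                                 baseline = 200) {
  stopifnot(length(amplitudes) == length(pkas),
            length(hillslopes) == length(pkas),
            all(amplitudes >= 0), reference_amplitude > 0, baseline >= 0)
  structure(list(amplitudes = amplitudes, pkas = pkas,
                 hillslopes = hillslopes,
                 reference_amplitude = reference_amplitude,
                 baseline = baseline),
            class = "sensor_response_spec")
}

#' Noise model for simulated micrographs
#'
#' Standard camera model: Poisson shot noise on the expected photon
#' counts, additive Gaussian read noise, then quantization to 16-bit
#' unsigned integers.
#'
#' @param shot logical; apply Poisson shot noise.
#' @param read_sd read-noise standard deviation, counts.
#' @param seed RNG seed; identical seeds give bit-identical images.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot = TRUE, read_sd = 5, seed = 1L) {
  stopifnot(read_sd >= 0)
  structure(list(shot = shot, read_sd = read_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Noiseless expected channel intensities at given pH
#'
#' @param spec a [sensor_response_spec()].
#' @param ph numeric vector of pH values.
#' @return A list with numeric vectors `indicator` and `reference`.
#' @export
response_curve <- function(spec, ph) {
  stopifnot(inherits(spec, "sensor_response_spec"))
  ind <- rep(spec$baseline, length(ph))
  for (f in seq_along(spec$pkas)) {
    ind <- ind + spec$amplitudes[f] /
      (1 + 10^((spec$pkas[f] - ph) * spec$hillslopes[f]))
  }
  list(indicator = ind,
       reference = rep(spec$reference_amplitude, length(ph)))
}

apply_noise <- function(expected, noise) {
  x <- expected
  if (noise$shot) x <- stats::rpois(length(x), lambda = x)
  if (noise$read_sd > 0) x <- x + stats::rnorm(length(x), 0, noise$read_sd)
  x <- round(x)
  x[x < 0] <- 0
  x[x > 65535] <- 65535
  matrix(x, nrow = nrow(expected), ncol = ncol(expected))
}

#' A synthetic cell scene with known ground truth
#'
#' @param shape image shape `c(rows, cols)`.
#' @param truth_ph per-pixel true pH (matrix or scalar, recycled).
#' @param density per-pixel expected reference counts (matrix or scalar);
#'   0 where no sensor is present.
#' @param background per-channel background offsets `c(indicator,
#'   reference)` in counts.
#' @param bleed_fraction fraction of indicator signal bleeding into the
#'   reference channel (0 = none).
#' @return An object of class `scene_phantom`.
#' @export
scene_phantom <- function(shape, truth_ph, density, background = c(0, 0),
                          bleed_fraction = 0) {
  truth_ph <- matrix(truth_ph, shape[1], shape[2])
  density <- matrix(density, shape[1], shape[2])
  stopifnot(all(density >= 0), all(background >= 0),
            bleed_fraction >= 0, bleed_fraction < 1)
  if (any(density > 0 & !is.finite(truth_ph)))
    stop("truth pH must be finite wherever sensor density > 0")
  structure(list(shape = shape, truth_ph = truth_ph, density = density,
                 background = background, bleed_fraction = bleed_fraction),
            class = "scene_phantom")
}

scene_expectation <- function(phantom, spec) {
  ph <- phantom$truth_ph
  ph[!is.finite(ph)] <- 7  # irrelevant where density is 0
  rc <- response_curve(spec, as.vector(ph))
  # density scales sensor load; ratio is load-invariant
  ref <- phantom$density
  ind <- phantom$density * matrix(rc$indicator, phantom$shape[1]) /
    spec$reference_amplitude
  ref <- ref + phantom$bleed_fraction * ind
  list(indicator = ind + phantom$background[1],
       reference = ref + phantom$background[2])
}

#' Simulate one two-channel scene from a phantom
#'
#' Expected intensities come from the response curve at each pixel's true
#' pH, scaled by the sensor density (so the indicator/reference ratio is
#' independent of sensor load), plus background and optional spectral
#' bleed-through; noise is then applied per the noise model.
#'
#' @param phantom a [scene_phantom()].
#' @param spec a [sensor_response_spec()].
#' @param noise a [noise_model()], or `NULL` for the noiseless expectation.
#' @return A list with `pair` (a [channel_pair()]) and `truth` (the truth
#'   pH matrix, `NA` where density is 0).
#' @export
simulate_cell_scene <- function(phantom, spec = sensor_response_spec(),
                                noise = noise_model()) {
  stopifnot(inherits(phantom, "scene_phantom"))
  ex <- scene_expectation(phantom, spec)
  if (is.null(noise)) {
    ind <- ex$indicator; ref <- ex$reference
  } else {
    set.seed(noise$seed)
    ind <- apply_noise(ex$indicator, noise)
    ref <- apply_noise(ex$reference, noise)
  }
  truth <- phantom$truth_ph
  truth[phantom$density == 0] <- NA_real_
  list(pair = channel_pair(ind, ref,
                           meta = list(synthetic = TRUE,
                                       bleed_fraction = phantom$bleed_fraction)),
       truth = truth)
}

#' Simulate a calibration image stack over a pH series
#'
#' One image pair per pH level: sensor pixels are placed by a uniform
#' density fraction, all at the level's (uniform) true pH, with expected
#' intensities from the response curve, then noise and background.
#'
#' @param spec a [sensor_response_spec()].
#' @param ph_values buffer pH levels (default the twelve-buffer series).
#' @param noise a [noise_model()] or `NULL`; per-level seeds are derived
#'   from the master seed.
#' @param shape image shape.
#' @param sensor_fraction fraction of pixels carrying sensors.
#' @param background per-channel offsets.
#' @return A list of manifest entries, each with `pair`, `ph` and `truth`,
#'   with the generating spec attached as attribute `spec`.
#' @export
simulate_calibration_stack <- function(spec = sensor_response_spec(),
                                       ph_values = buffer_series_recipes$ph,
                                       noise = noise_model(),
                                       shape = c(64, 64),
                                       sensor_fraction = 0.15,
                                       background = c(0, 0)) {
  stopifnot(length(ph_values) >= 1)
  entries <- lapply(seq_along(ph_values), function(i) {
    density <- matrix(0, shape[1], shape[2])
    if (!is.null(noise)) set.seed(noise$seed + i)
    n_sensor <- max(1L, round(sensor_fraction * prod(shape)))
    pick <- if (is.null(noise)) seq_len(n_sensor)
            else sample.int(prod(shape), n_sensor)
    density[pick] <- spec$reference_amplitude
    phantom <- scene_phantom(shape, truth_ph = ph_values[i],
                             density = density, background = background)
    frame_noise <- if (is.null(noise)) NULL
                   else noise_model(noise$shot, noise$read_sd, noise$seed + i)
    sim <- simulate_cell_scene(phantom, spec, frame_noise)
    list(pair = sim$pair, ph = ph_values[i], truth = sim$truth)
  })
  attr(entries, "spec") <- spec
  entries
}

#' Simulate a time-lapse of scenes along a truth pH trajectory
#'
#' Each frame reuses the same geometry (density field) with a
#' frame-specific truth pH; per-frame seeds are derived deterministically
#' from the master seed so the whole series is reproducible.
#'
#' @param phantoms list of [scene_phantom()]s, one per time point (at
#'   least 2), e.g. a progressive-acidification trajectory.
#' @param spec a [sensor_response_spec()].
#' @param noise a [noise_model()] or `NULL`.
#' @return A list of `simulate_cell_scene` results, one per frame.
#' @export
simulate_timelapse <- function(phantoms, spec = sensor_response_spec(),
                               noise = noise_model()) {
  stopifnot(is.list(phantoms), length(phantoms) >= 2L)
  lapply(seq_along(phantoms), function(t) {
    frame_noise <- if (is.null(noise)) NULL
                   else noise_model(noise$shot, noise$read_sd,
                                    noise$seed + 1000L * t)
    sim <- simulate_cell_scene(phantoms[[t]], spec, frame_noise)
    sim$pair$time <- t
    sim
  })
}

#' Simulate noisy calibration points directly (no images)
#'
#' Draws ratios from the single-sigmoid calibration curve with additive
#' Gaussian noise on each ratio, at the given pH levels. Used for
#' fit-recovery experiments where image formation is not under test.
#'
#' @param model the generating [calibration_model()].
#' @param ph_values pH levels (default the twelve-buffer series).
#' @param sigma Gaussian ratio-noise standard deviation (default 0.02).
#' @param seed RNG seed.
#' @return A data.frame of calibration points (`ph`, `ratio`, `weight`).
#' @export
simulate_calibration_points <- function(model,
                                        ph_values = buffer_series_recipes$ph,
                                        sigma = 0.02, seed = 1L) {
  stopifnot(inherits(model, "calibration_model"), sigma >= 0)
  set.seed(seed)
  ratio <- forward_response(model, ph_values) +
    stats::rnorm(length(ph_values), 0, sigma)
  ratio <- pmax(ratio, 1e-6)  # ratios are positive by construction
  data.frame(ph = ph_values, ratio = ratio, weight = 1)
}

#' Simulate a two-population scene for threshold selection
#'
#' Builds a scene containing bright sensor pixels whose ratios lie inside
#' the calibration range (true pH drawn uniformly within the sensor's
#' responsive span) and a dim noise population whose ratios fall below the
#' lower asymptote, mimicking autofluorescence/detector noise that the
#' reference-channel threshold must reject.
#'
#' @param model the [calibration_model()] defining in/out of range.
#' @param shape image shape (default 128 x 128).
#' @param n_sensor number of bright sensor pixels (default 500).
#' @param n_noise number of dim out-of-range pixels (default 2000).
#' @param sensor_reference range of reference counts for sensor pixels.
#' @param noise_reference range of reference counts for noise pixels.
#' @param ph_span span of true pH for sensor pixels (defaults to the
#'   model's calibrated range shrunk by 0.5 pH on each side).
#' @param seed RNG seed.
#' @return A list with `pair` (a [channel_pair()]) and the index vectors
#'   of the two populations.
#' @export
simulate_threshold_scene <- function(model, shape = c(128, 128),
                                     n_sensor = 500, n_noise = 2000,
                                     sensor_reference = c(1500, 2500),
                                     noise_reference = c(1, 30),
                                     ph_span = NULL, seed = 42L) {
  stopifnot(inherits(model, "calibration_model"),
            n_sensor + n_noise <= prod(shape))
  if (is.null(ph_span))
    ph_span <- c(model$ph_range[1] + 0.5, model$ph_range[2] - 0.5)
  set.seed(seed)
  ind <- matrix(0, shape[1], shape[2])
  ref <- matrix(0, shape[1], shape[2])
  pick <- sample.int(prod(shape), n_sensor + n_noise)
  i_sensor <- pick[seq_len(n_sensor)]
  i_noise <- pick[n_sensor + seq_len(n_noise)]
  # integer camera counts; sensor ratios stay in range (counts are large),
  # noise ratios stay strictly below the lower asymptote (floor only
  # lowers them)
  ref[i_sensor] <- round(stats::runif(n_sensor, sensor_reference[1],
                                      sensor_reference[2]))
  ind[i_sensor] <- round(forward_response(
    model, stats::runif(n_sensor, ph_span[1], ph_span[2])) * ref[i_sensor])
  ref[i_noise] <- round(stats::runif(n_noise, noise_reference[1],
                                     noise_reference[2]))
  ind[i_noise] <- floor(stats::runif(n_noise, 0.05, 0.75) * model$r_min *
                          ref[i_noise])
  list(pair = channel_pair(ind, ref), sensor_idx = i_sensor,
       noise_idx = i_noise)
}
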