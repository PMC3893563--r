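#' Construct a sigmoidal ratio-vs-pH calibration model
#'
#' The calibration relates the per-pixel indicator/reference intensity
#' ratio R to pH through a four-parameter sigmoid
#' \deqn{R(pH) = R_{min} + \frac{R_{max} - R_{min}}
#'   {1 + 10^{(pK_a - pH)\,\mathrm{hillslope}}}}
#' `r_min` and `r_max` are the lower and upper asymptotes, `pka` the pH at
#' half-maximal response and `hillslope` the steepness (negative for
#' fluorophores whose ratio decreases with pH).
#'
#' @param r_min lower asymptote of the ratio.
#' @param r_max upper asymptote of the ratio; must exceed `r_min`.
#' @param pka pH at half-maximal response.
#' @param hillslope steepness; nonzero.
#' @param ph_range length-2 numeric, the calibrated buffer pH interval.
#'   pH values inverted outside this interval are reported as out-of-range.
#' @param fit_stats optional list of fit diagnostics (populated by
#'   [fit_calibration()]).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(r_min, r_max, pka, hillslope,
                              ph_range = c(2.5, 8.0), fit_stats = NULL) {
  stopifnot(is.numeric(r_min), is.numeric(r_max), is.numeric(pka),
            is.numeric(hillslope), length(ph_range) == 2L)
  if (!is.finite(r_min) || !is.finite(r_max) || r_max <= r_min)
    stop("calibration model requires finite r_max > r_min")
  if (!is.finite(hillslope) || hillslope == 0)
    stop("hillslope must be finite and nonzero")
  if (!is.finite(pka)) stop("pka must be finite")
  if (ph_range[2] < ph_range[1]) stop("ph_range must be ordered [lo, hi]")
  structure(
    list(r_min = as.numeric(r_min), r_max = as.numeric(r_max),
         pka = as.numeric(pka), hillslope = as.numeric(hillslope),
         ph_range = as.numeric(ph_range), fit_stats = fit_stats),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Sigmoidal ratio-pH calibration model\n")
  cat(sprintf("  r_min = %.4g, r_max = %.4g, pKa = %.4g, hillslope = %.4g\n",
              x$r_min, x$r_max, x$pka, x$hillslope))
  cat(sprintf("  calibrated pH range: [%.2f, %.2f]\n",
              x$ph_range[1], x$ph_range[2]))
  if (!is.null(x$fit_stats))
    cat(sprintf("  fit: RSS = %.4g, converged = %s\n",
                x$fit_stats$rss, x$fit_stats$converged))
  invisible(x)
}

#' Evaluate the calibration sigmoid at given pH values
#'
#' @param model a [calibration_model()].
#' @param ph numeric vector of pH values; must be finite.
#' @return Predicted indicator/reference ratios, strictly between
#'   `r_min` and `r_max`.
#' @examples
#' m <- calibration_model(0.2, 2.0, 6.5, 1.0)
#' forward_response(m, 6.5)  # midpoint: (0.2 + 2.0) / 2 = 1.1
#' @export
forward_response <- function(model, ph) {
  stopifnot(inherits(model, "calibration_model"))
  if (!is.numeric(ph) || any(!is.finite(ph)))
    stop("ph must be finite numeric")
  model$r_min + (model$r_max - model$r_min) /
    (1 + 10^((model$pka - ph) * model$hillslope))
}

#' Invert the calibration sigmoid: ratio to pH
#'
#' Ratios strictly inside `(r_min, r_max)` map to
#' \deqn{pH = pK_a - \frac{\log_{10}\!\big(\frac{R_{max}-R_{min}}
#'   {R - R_{min}} - 1\big)}{\mathrm{hillslope}}}
#' Ratios at or beyond either asymptote (or non-finite ratios) cannot be
#' assigned a pH and return `NA`, the out-of-range sentinel; reports render
#' such pixels as the "pH > 10" class rather than a clamped number.
#'
#' @param model a [calibration_model()].
#' @param ratio numeric vector of indicator/reference ratios.
#' @return Numeric vector of pH values with `NA` where out of range.
#' @export
invert_response <- function(model, ratio) {
  stopifnot(inherits(model, "calibration_model"))
  out <- rep(NA_real_, length(ratio))
  ok <- is.finite(ratio) & ratio > model$r_min & ratio < model$r_max
  if (any(ok)) {
    arg <- (model$r_max - model$r_min) / (ratio[ok] - model$r_min) - 1
    out[ok] <- model$pka - log10(arg) / model$hillslope
  }
  out
}

#' Is a ratio within the calibrated range?
#'
#' A ratio counts as in range when it lies strictly inside
#' `(r_min, r_max)` and its inverted pH falls within the calibrated
#' buffer interval `ph_range`.
#'
#' @inheritParams invert_response
#' @return Logical vector.
#' @export
in_calibration_range <- function(model, ratio) {
  ph <- invert_response(model, ratio)
  !is.na(ph) & ph >= model$ph_range[1] & ph <= model$ph_range[2]
}

sigmoid_rss <- function(par, ph, ratio, weight) {
  pred <- par[1] + (par[2] - par[1]) / (1 + 10^((par[3] - ph) * par[4]))
  sum(weight * (ratio - pred)^2)
}

#' Fit the sigmoidal calibration curve to ratio observations
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt) for the four
#' sigmoid parameters. Starting values are data-driven: the observed ratio
#' extremes for the asymptotes, the pH of the point nearest the mid-ratio
#' for `pka`, and hillslope +1, with a multi-start fallback over
#' hillslope in {-2, -1, 1, 2} if the first attempt does not converge.
#'
#' @param points a data.frame with columns `ph`, `ratio` and optionally
#'   `weight` (nonnegative, default 1) and `n_pixels`.
#' @param weighted logical; use the `weight` column (default `TRUE`).
#' @return A [calibration_model()] with `ph_range` set to the span of the
#'   calibration pH values and `fit_stats` holding the residual sum of
#'   squares, parameter standard errors, residuals and a convergence flag.
#' @examples
#' truth <- calibration_model(0.2, 2.0, 6.5, 1.0)
#' pts <- data.frame(ph = seq(3, 8, 0.5))
#' pts$ratio <- forward_response(truth, pts$ph)
#' fit <- fit_calibration(pts)
#' @export
fit_calibration <- function(points, weighted = TRUE) {
  stopifnot(is.data.frame(points), all(c("ph", "ratio") %in% names(points)))
  ph <- as.numeric(points$ph)
  ratio <- as.numeric(points$ratio)
  w <- if (weighted && "weight" %in% names(points))
    as.numeric(points$weight) else rep(1, length(ph))
  if (any(!is.finite(ph)) || any(!is.finite(ratio)) || any(ratio <= 0))
    stop("calibration points must have finite ph and positive finite ratio")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (length(ph) < 5L || length(unique(ph)) < 4L)
    stop("need at least 5 points over at least 4 distinct pH values")

  # data-driven start
  mid <- (min(ratio) + max(ratio)) / 2
  start0 <- c(r_min = min(ratio), r_max = max(ratio),
              pka = ph[which.min(abs(ratio - mid))], hillslope = 1)
  # nlsLM needs r_max > r_min strictly
  if (start0["r_max"] <= start0["r_min"])
    start0["r_max"] <- start0["r_min"] + 1e-6

  try_fit <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        ratio ~ r_min + (r_max - r_min) / (1 + 10^((pka - ph) * hillslope)),
        data = data.frame(ph = ph, ratio = ratio),
        start = as.list(start), weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) e)
  }

  fit <- try_fit(start0)
  tried <- list(start0)
  if (inherits(fit, "error")) {
    for (hs in c(-2, -1, 1, 2)) {
      st <- start0; st["hillslope"] <- hs
      # a decreasing response swaps the asymptote roles
      fit <- try_fit(st)
      tried <- c(tried, list(st))
      if (!inherits(fit, "error")) break
    }
  }
  if (inherits(fit, "error"))
    stop("calibration fit did not converge from any start; last error: ",
         conditionMessage(fit))

  est <- stats::coef(fit)
  # canonicalize: the sigmoid is invariant under
  # (r_min, r_max, hillslope) -> (r_max, r_min, -hillslope)
  if (est["r_max"] < est["r_min"]) {
    est[c("r_min", "r_max")] <- est[c("r_max", "r_min")]
    est["hillslope"] <- -est["hillslope"]
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  res <- stats::resid(fit)
  stats <- list(
    rss = sum(w * res^2),
    std_errors = stats::setNames(as.numeric(se), names(est)),
    residuals = as.numeric(res),
    n_points = length(ph),
    weighted = weighted,
    converged = fit$convInfo$isConv %||% TRUE)
  calibration_model(est[["r_min"]], est[["r_max"]], est[["pka"]],
                    est[["hillslope"]],
                    ph_range = range(ph), fit_stats = stats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a calibration model from a set of calibration images
#'
#' Runs the measurement pipeline stages over each calibration image
#' (background subtraction, reference-channel masking, per-pixel ratio with
#' reference-intensity weighting), reduces each image to its weighted mean
#' ratio, averages images within a pH level weighted by their total
#' reference intensity, and fits the sigmoid to the resulting points with
#' weights proportional to total reference intensity.
#'
#' @param manifest a list of entries, each a list with elements `pair` (a
#'   [channel_pair()]) and `ph` (the buffer pH the image was acquired in).
#' @param background a [background_estimate()] applied to every image, or
#'   `NULL` for none.
#' @param threshold reference-channel mask threshold used during
#'   calibration (the exact value is not critical at this stage; default 0
#'   keeps every positive-reference pixel).
#' @param weighted passed to [fit_calibration()].
#' @return A [calibration_model()].
#' @export
calibrate_from_images <- function(manifest, background = NULL, threshold = 0,
                                  weighted = TRUE) {
  stopifnot(is.list(manifest), length(manifest) >= 1L)
  phs <- vapply(manifest, function(e) as.numeric(e$ph), numeric(1))
  if (length(unique(phs)) < 5L)
    stop("calibration requires images at >= 5 distinct pH levels")

  per_image <- lapply(manifest, function(entry) {
    pair <- entry$pair
    if (!is.null(background)) pair <- subtract_background(pair, background)
    mask <- build_mask(pair$reference, threshold)
    if (mask$n_pixels == 0L) return(NULL)
    rf <- tryCatch(compute_ratio_field(pair, mask), error = function(e) NULL)
    if (is.null(rf)) return(NULL)
    list(ph = as.numeric(entry$ph),
         mean_ratio = sum(rf$weight * rf$ratio),   # weights already sum to 1
         total_reference = rf$total_reference,
         n_pixels = length(rf$ratio))
  })
  dropped <- vapply(per_image, is.null, logical(1))
  if (any(dropped))
    warning(sum(dropped), " calibration image(s) had an empty mask and were excluded")
  per_image <- per_image[!dropped]
  if (length(per_image) == 0L) stop("all calibration images were empty")

  df <- do.call(rbind, lapply(per_image, as.data.frame))
  pts <- do.call(rbind, lapply(split(df, df$ph), function(g) {
    data.frame(ph = g$ph[1],
               ratio = sum(g$mean_ratio * g$total_reference) /
                 sum(g$total_reference),
               weight = sum(g$total_reference),
               n_pixels = sum(g$n_pixels))
  }))
  if (length(unique(pts$ph)) < 5L)
    stop("fewer than 5 pH levels survived masking; cannot calibrate")
  fit_calibration(pts, weighted = weighted)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a [calibration_model()].
#' @param path file path to write to.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns the restored [calibration_model()].
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- list(
    r_min = model$r_min, r_max = model$r_max, pka = model$pka,
    hillslope = model$hillslope,
    ph_lo = model$ph_range[1], ph_hi = model$ph_range[2],
    fit_stats = model$fit_stats,
    software_version = as.character(utils::packageVersion("nanosensR")))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(j$r_min, j$r_max, j$pka, j$hillslope,
                    ph_range = c(j$ph_lo, j$ph_hi), fit_stats = j$fit_stats)
}

#' Read / write calibration points as CSV
#'
#' The CSV schema is `ph,ratio,weight,n_pixels`.
#'
#' @param points data.frame of calibration points.
#' @param path file path.
#' @return `read_calibration_points` returns the data.frame.
#' @export
write_calibration_points <- function(points, path) {
  stopifnot(all(c("ph", "ratio") %in% names(points)))
  if (is.null(points$weight)) points$weight <- 1
  if (is.null(points$n_pixels)) points$n_pixels <- NA_integer_
  utils::write.csv(points[, c("ph", "ratio", "weight", "n_pixels")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_calibration_points
#' @export
read_calibration_points <- function(path) {
  utils::read.csv(path)
}
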