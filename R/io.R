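#' Read a two-channel micrograph from TIFF
#'
#' Accepts either one multi-channel/multi-page TIFF (with `channels`
#' giving the indicator and reference page or channel indices) or two
#' single-channel files. 8- and 16-bit unsigned input is supported;
#' intensities are returned as raw integer counts.
#'
#' @param path path to the TIFF, or length-2 character
#'   `c(indicator, reference)` paths.
#' @param channels for a single file: integer `c(indicator, reference)`
#'   page/channel indices (default `c(1, 2)`).
#' @param slice page index of the in-focus slice when each channel is a
#'   multi-page stack of two single-channel files (default 1); the
#'   in-focus slice is user-designated, not auto-detected.
#' @return A [channel_pair()].
#' @export
read_channel_pair <- function(path, channels = c(1L, 2L), slice = 1L) {
  load_pages <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    img <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    lapply(img, function(m) {
      if (length(dim(m)) == 3L) {
        # planar RGB/multi-sample page: split samples into channels
        lapply(seq_len(dim(m)[3]), function(k) m[, , k])
      } else list(m)
    })
  }
  if (length(path) == 2L) {
    a <- load_pages(path[1]); b <- load_pages(path[2])
    if (slice > length(a) || slice > length(b))
      stop("slice index ", slice, " exceeds the number of pages")
    ind <- a[[slice]][[1]]; ref <- b[[slice]][[1]]
  } else {
    pages <- load_pages(path)
    chans <- unlist(pages, recursive = FALSE)
    if (max(channels) > length(chans))
      stop("requested channel ", max(channels), " but file has ",
           length(chans))
    ind <- chans[[channels[1]]]; ref <- chans[[channels[2]]]
  }
  if (!identical(dim(ind), dim(ref)))
    stop(sprintf(
      "indicator (%s) and reference (%s) channels differ in shape; check channel mapping",
      paste(dim(ind), collapse = "x"), paste(dim(ref), collapse = "x")))
  if (max(ind, ref) >= 2^16)
    stop("only 8- and 16-bit unsigned TIFF input is supported")
  channel_pair(ind, ref, meta = list(source = path))
}

#' Write a two-channel micrograph as a two-page 16-bit TIFF
#'
#' @param pair a [channel_pair()] with integer counts in `[0, 65535]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_channel_pair <- function(pair, path) {
  stopifnot(inherits(pair, "channel_pair"))
  if (max(pair$indicator, pair$reference) > 65535)
    stop("counts exceed the 16-bit range")
  tiff::writeTIFF(list(pair$indicator / 65535, pair$reference / 65535),
                  path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# pH maps: 32-bit float two-page TIFF. Page 1 stores pH / PH_SCALE in
# [0, 1]; page 2 stores a code plane (0 unmasked, 0.5 numeric, 1 sentinel).
# The installed TIFF writer clamps values outside [0, 1] and does not
# preserve NaN, so sentinels are carried in the code plane instead.
PH_SCALE <- 14

#' Write / read a per-pixel pH map as float TIFF
#'
#' The on-disk encoding is a two-page 32-bit float TIFF: a pH plane scaled
#' into `[0, 1]` by 1/14, and a code plane distinguishing unmasked pixels,
#' numeric pH and out-of-range sentinels. `read_ph_map` restores a numeric
#' matrix with `NA` at unmasked pixels and `NaN` at sentinels.
#'
#' @param field a [ratios_to_ph()] result.
#' @param path output path.
#' @return `write_ph_map` returns `path` invisibly; `read_ph_map` returns
#'   the pH matrix.
#' @export
write_ph_map <- function(field, path) {
  stopifnot(inherits(field, "ph_field"))
  ph_plane <- matrix(0, field$shape[1], field$shape[2])
  code <- matrix(0, field$shape[1], field$shape[2])
  pix <- cbind(field$row, field$col)
  sentinel <- is.na(field$ph)
  ph_plane[pix[!sentinel, , drop = FALSE]] <- field$ph[!sentinel] / PH_SCALE
  code[pix[!sentinel, , drop = FALSE]] <- 0.5
  code[pix[sentinel, , drop = FALSE]] <- 1
  tiff::writeTIFF(list(ph_plane, code), path, bits.per.sample = 32L,
                  reduce = FALSE)
  invisible(path)
}

#' @rdname write_ph_map
#' @export
read_ph_map <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 2L) stop("not a pH map: expected 2 pages")
  ph <- pages[[1]] * PH_SCALE
  code <- pages[[2]]
  ph[code < 0.25] <- NA_real_
  ph[code > 0.75] <- NaN
  ph
}

#' Validate a run configuration
#'
#' Checks types and rejects unknown keys before any computation runs.
#'
#' @param config a named list, e.g. parsed from JSON/YAML. Recognised
#'   keys: `channel_indicator`, `channel_reference`, `slice`,
#'   `background_method` (roi/image/constant), `background_roi`,
#'   `background_value`, `threshold` ("auto" or number), `mode`
#'   (pixel/region/image), `bin_width`, `min_size`, `max_size`, `seed`,
#'   `output_dir`.
#' @return The config list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  defaults <- list(channel_indicator = 1L, channel_reference = 2L,
                   slice = 1L, background_method = "constant",
                   background_roi = NULL, background_value = 0,
                   threshold = "auto", mode = "pixel", bin_width = 0.2,
                   min_size = 1L, max_size = Inf, seed = 1L,
                   output_dir = ".")
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$mode %in% c("pixel", "region", "image"))
    stop("mode must be pixel, region or image")
  if (!cfg$background_method %in% c("roi", "image", "constant"))
    stop("background_method must be roi, image or constant")
  if (!identical(cfg$threshold, "auto") &&
      (!is.numeric(cfg$threshold) || cfg$threshold < 0))
    stop("threshold must be \"auto\" or a nonnegative number")
  if (cfg$bin_width <= 0) stop("bin_width must be positive")
  cfg
}

#' Write a complete measurement result set to disk
#'
#' Emits the pH map (float TIFF), colour map (PNG), histogram and summary
#' (CSV), and a sidecar provenance JSON carrying the configuration, the
#' calibration model and the software version, so a result is fully
#' re-traceable.
#'
#' @param result a [measure_ph()] result.
#' @param dir output directory (created if missing).
#' @param model the [calibration_model()] used.
#' @param config the validated [run_config()].
#' @param prefix file-name prefix (default `"measurement"`).
#' @return Named character vector of the files written.
#' @export
write_results <- function(result, dir, model, config = run_config(),
                          prefix = "measurement") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(ext) file.path(dir, paste0(prefix, ext))
  files <- c(ph_map = p("_ph.tif"), colormap = p("_colormap.png"),
             histogram = p("_histogram.csv"), summary = p("_summary.csv"),
             provenance = p("_provenance.json"))
  write_ph_map(result$field, files[["ph_map"]])
  cm <- render_colormap(result$field)
  png::writePNG(cm$rgb, files[["colormap"]])
  h <- result$histogram
  hist_df <- data.frame(bin_lo = c(h$breaks[-length(h$breaks)], NA),
                        bin_hi = c(h$breaks[-1], NA),
                        mass = c(h$mass, h$out_of_range),
                        bin = c(rep("numeric", length(h$mass)), "pH > 10"))
  utils::write.csv(hist_df, files[["histogram"]], row.names = FALSE)
  utils::write.csv(result$summary, files[["summary"]], row.names = FALSE)
  prov <- list(
    config = config[!vapply(config, is.null, logical(1))],
    calibration = list(r_min = model$r_min, r_max = model$r_max,
                       pka = model$pka, hillslope = model$hillslope,
                       ph_lo = model$ph_range[1], ph_hi = model$ph_range[2]),
    threshold = result$threshold,
    counts = list(n_masked = length(result$field$ph),
                  sentinel_fraction = result$field$sentinel_fraction),
    software_version = as.character(utils::packageVersion("nanosensR")))
  jsonlite::write_json(prov, files[["provenance"]], auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  files
}

#' Read a calibration manifest CSV and its images
#'
#' The manifest schema is `path,channel_indicator,channel_reference,ph`;
#' paths are resolved relative to the manifest's directory.
#'
#' @param path manifest CSV path.
#' @return A manifest list suitable for [calibrate_from_images()].
#' @export
read_calibration_manifest <- function(path) {
  df <- utils::read.csv(path)
  need <- c("path", "channel_indicator", "channel_reference", "ph")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  base <- dirname(normalizePath(path))
  lapply(seq_len(nrow(df)), function(i) {
    f <- df$path[i]
    if (!file.exists(f)) f <- file.path(base, f)
    list(pair = read_channel_pair(f, channels = c(df$channel_indicator[i],
                                                  df$channel_reference[i])),
         ph = df$ph[i])
  })
}
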