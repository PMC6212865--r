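#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Pages are ordered frame-major: all channels of frame 1 (in the stack's
#' channel order), then all channels of frame 2, and so on. Intensities are
#' stored as 16-bit integers, so integer-valued stacks up to 65535 round-trip
#' losslessly.
#'
#' @param stack a [frame_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  d <- dim(stack$data)
  if (max(stack$data) > 65535) {
    stop("intensities exceed the 16-bit range; rescale before writing",
         call. = FALSE)
  }
  pages <- vector("list", d[3] * d[4])
  k <- 1L
  for (f in seq_len(d[4])) {
    for (ci in seq_len(d[3])) {
      pages[[k]] <- stack$data[, , ci, f] / 65535
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a frame stack
#'
#' Expects the page layout produced by [write_stack()]: frame-major pages
#' with `length(channels)` channels per frame.
#'
#' @param path TIFF file path.
#' @param channels channel names, in page order within each frame.
#' @param frame_interval seconds per frame (metadata; not stored in the TIFF).
#' @param pixel_size microns per pixel, or `NA`.
#' @return A [frame_stack]. Integer-valued images written by [write_stack()]
#'   are recovered exactly.
#' @export
read_stack <- function(path, channels = c("marker", "cargo"),
                       frame_interval = 1, pixel_size = NA_real_) {
  if (!file.exists(path)) {
    stop(sprintf("input file does not exist: %s", path), call. = FALSE)
  }
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop(sprintf("could not read '%s' as TIFF: %s",
                                   path, conditionMessage(e)), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  nch <- length(channels)
  if (length(pages) %% nch != 0) {
    stop(sprintf(paste0("axis mismatch: %d TIFF page(s) cannot be split into ",
                        "%d channel(s) per frame"), length(pages), nch),
         call. = FALSE)
  }
  nf <- length(pages) %/% nch
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(h, w, nch, nf))
  k <- 1L
  for (f in seq_len(nf)) {
    for (ci in seq_len(nch)) {
      p <- pages[[k]]
      if (nrow(p) != h || ncol(p) != w) {
        stop("axis mismatch: TIFF pages differ in size", call. = FALSE)
      }
      arr[, , ci, f] <- round(p * 65535)
      k <- k + 1L
    }
  }
  frame_stack(arr, channels = channels, frame_interval = frame_interval,
              pixel_size = pixel_size)
}

#' Write ground truth tables as CSV
#'
#' @param truth a `ground_truth` object.
#' @param dir output directory (created if needed). Writes `vesicles.csv`
#'   and, when tracks exist, `tracks.csv`.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth$vesicles, file.path(dir, "vesicles.csv"),
                   row.names = FALSE)
  if (nrow(truth$tracks) > 0) {
    utils::write.csv(truth$tracks, file.path(dir, "tracks.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

# --- run configuration -------------------------------------------------------

run_config_schema <- list(
  top = c("input", "simulation", "channels", "detection", "coloc", "tracking",
          "output_dir", "seed", "log_level"),
  input = c("path", "frame_interval", "pixel_size"),
  channels = c("marker", "cargo", "punctum"),
  detection = c("sigma_low", "sigma_high", "threshold_method", "percentile",
                "min_area", "max_area", "discard_border"),
  coloc = c("k", "dilation_radius", "threshold_mode", "fixed_thresholds"),
  tracking = c("max_displacement", "max_gap", "max_lag_fraction",
               "directed_cutoff", "confined_cutoff", "max_distance",
               "min_frames")
)

check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a run configuration
#'
#' The configuration is a YAML file with exactly one of an `input:` block
#' (`path`, optional `frame_interval`, `pixel_size`) or a `simulation:` block
#' (any [simulation_config()] argument), plus optional `channels:`
#' (`marker`/`cargo`/`punctum` page indices), `detection:`, `coloc:` and
#' `tracking:` parameter blocks, `output_dir`, `seed` and `log_level`
#' (`"info"` or `"quiet"`). Unknown keys anywhere are rejected.
#'
#' @param path YAML file path, or a list already parsed.
#' @param seed optional seed overriding the configured one.
#' @return A validated list of class `run_config`.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) {
      stop(sprintf("config file does not exist: %s", path), call. = FALSE)
    }
    yaml::read_yaml(path)
  } else as.list(path)
  check_keys(cfg, run_config_schema$top, "config")
  has_input <- !is.null(cfg$input)
  has_sim <- !is.null(cfg$simulation)
  if (has_input == has_sim) {
    stop("config must contain exactly one of 'input' or 'simulation'",
         call. = FALSE)
  }
  if (has_input) check_keys(cfg$input, run_config_schema$input, "input")
  if (has_sim) {
    check_keys(cfg$simulation, names(formals(simulation_config)), "simulation")
  }
  for (blk in c("channels", "detection", "coloc", "tracking")) {
    if (!is.null(cfg[[blk]])) check_keys(cfg[[blk]], run_config_schema[[blk]], blk)
  }
  if (!is.null(cfg$channels)) {
    idx <- unlist(cfg$channels)
    if (anyDuplicated(idx)) stop("channel indices must be distinct",
                                 call. = FALSE)
  }
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$output_dir)) cfg$output_dir <- "."
  if (is.null(cfg$log_level)) cfg$log_level <- "info"
  structure(cfg, class = "run_config")
}

log_stage <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[vesiquant] ", fmt), ...))
}

# Build the frame_stack a run operates on: simulate or read from disk.
resolve_stack <- function(cfg, timelapse = FALSE) {
  if (!is.null(cfg$simulation)) {
    args <- cfg$simulation
    args$seed <- cfg$seed
    if (!is.null(args$ring_radius_range)) {
      args$ring_radius_range <- as.numeric(unlist(args$ring_radius_range))
    }
    if (!is.null(args$motion_mix)) {
      args$motion_mix <- unlist(args$motion_mix)
    }
    sim_cfg <- do.call(simulation_config, args)
    sim <- if (timelapse) simulate_timelapse(sim_cfg) else simulate_field(sim_cfg)
    log_stage(cfg, "simulated %d-frame stack (%d vesicles)",
              n_frames(sim$stack), nrow(sim$truth$vesicles))
    sim
  } else {
    channels <- if (!is.null(cfg$channels)) {
      names(sort(unlist(cfg$channels)))
    } else c("marker", "cargo")
    stack <- read_stack(cfg$input$path, channels = channels,
                        frame_interval = cfg$input$frame_interval %||% 1,
                        pixel_size = cfg$input$pixel_size %||% NA_real_)
    log_stage(cfg, "read %d-frame stack from %s", n_frames(stack),
              cfg$input$path)
    list(stack = stack, truth = NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

build_detection_params <- function(cfg) {
  do.call(detection_params, cfg$detection %||% list())
}

# Byte-stable provenance record: config hash, seed, package version.
# The output directory and log level do not affect results, so they are
# excluded from the hash: the same analysis run elsewhere hashes identically.
write_provenance <- function(cfg, dir) {
  clean <- unclass(cfg)
  clean$output_dir <- NULL
  clean$log_level <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(clean, tf)
  prov <- list(config_hash = unname(tools::md5sum(tf)),
               seed = cfg$seed,
               package = "vesiquant",
               version = as.character(utils::packageVersion("vesiquant")))
  yaml::write_yaml(prov, file.path(dir, "provenance.yaml"))
}

#' Run the marker-mask colocalization analysis
#'
#' The full object-based workflow on a still field: segment the marker
#' channel into filled vesicle ROIs, estimate the cargo background outside
#' the (dilated) ROIs, call each vesicle cargo-positive or negative, report
#' the percentage-positive summary, and compute masked pixel statistics
#' (Pearson, Manders) within the ROI mask. Writes `per_object.csv`,
#' `summary.csv` and `provenance.yaml` into the output directory; reruns
#' with the same config and seed are byte-identical.
#'
#' @param config a `run_config` (see [read_run_config()]), or a path to one.
#' @return Invisibly, a list with `rois`, `calls`, `summary`, `pixel`,
#'   and `output_dir`. Zero detected vesicles is reported (undefined
#'   percentage), not an error.
#' @export
run_rab_coloc <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  src <- resolve_stack(cfg, timelapse = FALSE)
  marker <- get_frame(src$stack, "marker", 1)
  cargo <- get_frame(src$stack, "cargo", 1)
  rois <- detect_vesicles(marker, build_detection_params(cfg))
  log_stage(cfg, "detected %d vesicle ROI(s)", nrow(rois$table))
  k <- cfg$coloc$k %||% 3
  dil <- cfg$coloc$dilation_radius %||% 3
  if (nrow(rois$table) == 0) {
    warning("no vesicles detected; percentage undefined")
    summary <- percent_positive(logical(0))
    calls <- classify_objects(cargo, rois,
                              structure(list(median = stats::median(cargo),
                                             mad = 0, n_pixels_used = length(cargo),
                                             low_n = FALSE),
                                        class = "background_model"), k)
    pixel <- NULL
  } else {
    bg <- estimate_background(cargo, rois$label_map, dilation_radius = dil)
    calls <- classify_objects(cargo, rois, bg, k = k)
    summary <- percent_positive(calls)
    pixel <- pixel_coloc(marker, cargo, rois$label_map > 0,
                         threshold_mode = cfg$coloc$threshold_mode %||%
                           "background-model",
                         fixed_thresholds = cfg$coloc$fixed_thresholds,
                         k = k)
    log_stage(cfg, "%d / %d cargo-positive (%.1f%%)", summary$n_positive,
              summary$n_objects, summary$percent_positive)
  }
  per_object <- merge(rois$table, calls, by = "label_id", sort = TRUE)
  utils::write.csv(per_object, file.path(cfg$output_dir, "per_object.csv"),
                   row.names = FALSE)
  sm <- data.frame(n_objects = summary$n_objects,
                   n_positive = summary$n_positive,
                   percent_positive = summary$percent_positive,
                   ci_low = summary$ci_low, ci_high = summary$ci_high,
                   pearson_r = if (is.null(pixel)) NA_real_ else pixel$pearson_r,
                   m1 = if (is.null(pixel)) NA_real_ else pixel$manders_m1,
                   m2 = if (is.null(pixel)) NA_real_ else pixel$manders_m2)
  utils::write.csv(sm, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  write_provenance(cfg, cfg$output_dir)
  invisible(list(rois = rois, calls = calls, summary = summary, pixel = pixel,
                 truth = src$truth, output_dir = cfg$output_dir))
}

#' Run the co-transport analysis on a time-lapse stack
#'
#' Detects vesicles on the cargo channel and puncta on the punctum channel in
#' every frame, links vesicles into trajectories, computes per-track MSD and
#' motion class, and measures the fraction of vesicles that carry an
#' associated punctum. Writes `tracks.csv`, `motion.csv`, `cotransport.csv`,
#' `summary.csv` and `provenance.yaml`.
#'
#' @param config a `run_config` with a time-lapse source (>= 2 frames) whose
#'   stack includes `cargo` and `punctum` channels.
#' @return Invisibly, a list with `tracks`, `motion`, `cotransport`,
#'   `summary`, `output_dir`.
#' @export
run_cotransport <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else read_run_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  src <- resolve_stack(cfg, timelapse = TRUE)
  stack <- src$stack
  if (!all(c("cargo", "punctum") %in% stack$channels)) {
    stop("co-transport analysis needs 'cargo' and 'punctum' channels",
         call. = FALSE)
  }
  nf <- n_frames(stack)
  if (nf < 2) stop("co-transport analysis needs at least 2 frames",
                   call. = FALSE)
  dp <- build_detection_params(cfg)
  pp <- punctum_params()
  rois_pf <- vector("list", nf)
  puncta_pf <- vector("list", nf)
  for (f in seq_len(nf)) {
    rois_pf[[f]] <- detect_vesicles(get_frame(stack, "cargo", f), dp)
    puncta_pf[[f]] <- detect_puncta(get_frame(stack, "punctum", f), pp)
  }
  log_stage(cfg, "per-frame detection done (%d frames, %d ROIs in frame 1)",
            nf, nrow(rois_pf[[1]]$table))
  tr_cfg <- cfg$tracking %||% list()
  maxd <- tr_cfg$max_displacement %||% 10
  ct <- cotransport_fraction(rois_pf, puncta_pf,
                             max_distance = tr_cfg$max_distance %||% 5,
                             min_frames = tr_cfg$min_frames,
                             link_max_displacement = maxd)
  dets <- lapply(rois_pf, function(r) r$table[, c("row", "col")])
  tracks <- link_detections(dets, max_displacement = maxd,
                            max_gap = tr_cfg$max_gap %||% 1L)
  motion <- if (nrow(tracks) > 0) {
    classify_tracks(tracks, frame_interval = stack$frame_interval,
                    max_lag_fraction = tr_cfg$max_lag_fraction %||% 0.25,
                    directed_cutoff = tr_cfg$directed_cutoff %||% 1.4,
                    confined_cutoff = tr_cfg$confined_cutoff %||% 0.7)
  } else {
    classify_tracks(data.frame(track_id = integer(0), frame = integer(0),
                               row = numeric(0), col = numeric(0)))
  }
  summary <- ct$summary
  if (summary$undefined) warning("no vesicles detected; percentage undefined")
  log_stage(cfg, "linked %d track(s); co-transport %.1f%%",
            length(unique(tracks$track_id)),
            if (summary$undefined) NA else summary$percent_positive)
  utils::write.csv(tracks, file.path(cfg$output_dir, "tracks.csv"),
                   row.names = FALSE)
  utils::write.csv(motion, file.path(cfg$output_dir, "motion.csv"),
                   row.names = FALSE)
  utils::write.csv(ct$per_vesicle, file.path(cfg$output_dir, "cotransport.csv"),
                   row.names = FALSE)
  sm <- data.frame(n_objects = summary$n_objects,
                   n_positive = summary$n_positive,
                   percent_positive = summary$percent_positive,
                   ci_low = summary$ci_low, ci_high = summary$ci_high)
  utils::write.csv(sm, file.path(cfg$output_dir, "summary.csv"),
                   row.names = FALSE)
  write_provenance(cfg, cfg$output_dir)
  invisible(list(tracks = tracks, motion = motion, cotransport = ct,
                 summary = summary, truth = src$truth,
                 output_dir = cfg$output_dir))
}
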