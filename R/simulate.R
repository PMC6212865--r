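#' Simulation parameters for synthetic vesicle fields
#'
#' Describes a synthetic dual-channel acquisition: ring-shaped membrane-marker
#' signal on the endosome surface, cargo signal filling the lumen of a random
#' subset of vesicles, optional punctate particles riding on cargo-positive
#' vesicles, and a standard camera noise model (Poisson shot noise over a
#' uniform background, then additive Gaussian read noise).
#'
#' Geometry per vesicle of radius `r`: the marker channel receives a hard
#' annulus of outer radius `r` and thickness `ring_thickness`; the cargo
#' channel (for cargo-positive vesicles) receives a filled disk of radius
#' `r - ring_thickness`, strictly inside the ring. Both are blurred with an
#' isotropic Gaussian PSF. Marker and cargo therefore occupy disjoint
#' sub-structures of the same object, which is why downstream scoring is
#' object-based rather than pixel-overlap based.
#'
#' @param image_height,image_width image size in pixels.
#' @param n_vesicles number of vesicles to place.
#' @param coloc_fraction probability in \[0,1\] that a vesicle is cargo-positive.
#' @param ring_radius_range length-2 numeric, min/max outer ring radius (px).
#' @param ring_thickness radial thickness of the marker ring (px).
#' @param marker_amplitude,cargo_amplitude,punctum_amplitude signal amplitude
#'   in photons/pixel above background (the punctum amplitude is its
#'   integrated intensity, spread by the PSF).
#' @param background_level uniform background, photons/pixel.
#' @param psf_sigma standard deviation of the Gaussian PSF (px).
#' @param read_noise_sigma standard deviation of the Gaussian read noise
#'   (photons); applied after Poisson shot noise.
#' @param min_separation minimum distance between vesicle centers (px).
#'   The default, three times the maximum ring radius, keeps objects far
#'   enough apart that segmentation is unambiguous.
#' @param n_frames number of frames (1 for a still field).
#' @param frame_interval seconds per frame; the default of 1 s matches
#'   typical live-cell acquisition at one frame per second.
#' @param motion_mix named fractions for motion classes `directed`,
#'   `diffusive`, `confined`; must sum to 1.
#' @param speed directed-motion speed, pixels/frame.
#' @param diffusion_coefficient D for diffusive and confined motion,
#'   pixels^2/frame.
#' @param confinement_radius confinement radius about the start point (px).
#' @param position_noise_sigma localization jitter added independently per
#'   frame to directed tracks (px).
#' @param punctum_attach_fraction probability that a cargo-positive vesicle
#'   carries an attached punctum.
#' @param seed integer seed; the same config yields bit-identical output.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_field()], [simulate_timelapse()], [simulate_tracks()]
#' @export
simulation_config <- function(image_height = 256L,
                              image_width = 256L,
                              n_vesicles = 50L,
                              coloc_fraction = 0.5,
                              ring_radius_range = c(4, 6),
                              ring_thickness = 2,
                              marker_amplitude = 200,
                              cargo_amplitude = 150,
                              punctum_amplitude = 400,
                              background_level = 20,
                              psf_sigma = 1,
                              read_noise_sigma = 2,
                              min_separation = 3 * max(ring_radius_range),
                              n_frames = 1L,
                              frame_interval = 1,
                              motion_mix = c(directed = 1/3, diffusive = 1/3,
                                             confined = 1/3),
                              speed = 2,
                              diffusion_coefficient = 1,
                              confinement_radius = 3,
                              position_noise_sigma = 0.5,
                              punctum_attach_fraction = 0,
                              seed = 1L) {
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_vesicles = as.integer(n_vesicles),
    coloc_fraction = coloc_fraction,
    ring_radius_range = as.numeric(ring_radius_range),
    ring_thickness = ring_thickness,
    marker_amplitude = marker_amplitude,
    cargo_amplitude = cargo_amplitude,
    punctum_amplitude = punctum_amplitude,
    background_level = background_level,
    psf_sigma = psf_sigma,
    read_noise_sigma = read_noise_sigma,
    min_separation = min_separation,
    n_frames = as.integer(n_frames),
    frame_interval = frame_interval,
    motion_mix = motion_mix,
    speed = speed,
    diffusion_coefficient = diffusion_coefficient,
    confinement_radius = confinement_radius,
    position_noise_sigma = position_noise_sigma,
    punctum_attach_fraction = punctum_attach_fraction,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  num <- unlist(cfg[c("image_height", "image_width", "n_vesicles",
                      "coloc_fraction", "ring_radius_range", "ring_thickness",
                      "marker_amplitude", "cargo_amplitude", "punctum_amplitude",
                      "background_level", "psf_sigma", "read_noise_sigma",
                      "min_separation", "n_frames", "frame_interval", "speed",
                      "diffusion_coefficient", "confinement_radius",
                      "position_noise_sigma", "punctum_attach_fraction",
                      "motion_mix")])
  if (any(!is.finite(num))) stop("simulation config contains non-finite values",
                                 call. = FALSE)
  stopifnot(
    cfg$image_height > 0, cfg$image_width > 0, cfg$n_vesicles >= 0,
    cfg$n_frames >= 1, cfg$frame_interval > 0, cfg$ring_thickness > 0,
    length(cfg$ring_radius_range) == 2,
    cfg$ring_radius_range[1] <= cfg$ring_radius_range[2],
    cfg$ring_radius_range[1] > cfg$ring_thickness
  )
  if (cfg$coloc_fraction < 0 || cfg$coloc_fraction > 1) {
    stop("coloc_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$punctum_attach_fraction < 0 || cfg$punctum_attach_fraction > 1) {
    stop("punctum_attach_fraction must lie in [0, 1]", call. = FALSE)
  }
  mm <- cfg$motion_mix
  if (length(mm) != 3 ||
      !setequal(names(mm), c("directed", "diffusive", "confined"))) {
    stop("motion_mix must name directed, diffusive and confined", call. = FALSE)
  }
  if (any(mm < 0) || abs(sum(mm) - 1) > 1e-8) {
    stop("motion_mix fractions must be non-negative and sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

# --- placement ---------------------------------------------------------------

# Uniform rejection sampling of vesicle centers. Centers keep a margin of
# 2 * max radius from every edge so no object is truncated; each vesicle has a
# budget of 10 * n_vesicles attempts before the density is declared infeasible.
place_vesicles <- function(cfg) {
  n <- cfg$n_vesicles
  if (n == 0L) {
    return(data.frame(center_row = numeric(0), center_col = numeric(0),
                      radius = numeric(0)))
  }
  margin <- 2 * cfg$ring_radius_range[2]
  lo_r <- 1 + margin; hi_r <- cfg$image_height - margin
  lo_c <- 1 + margin; hi_c <- cfg$image_width - margin
  if (hi_r <= lo_r || hi_c <= lo_c) {
    stop("image too small for the requested vesicle radius and edge margin",
         call. = FALSE)
  }
  budget <- 10L * n
  rows <- cols <- numeric(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(budget)) {
      r <- stats::runif(1, lo_r, hi_r)
      c <- stats::runif(1, lo_c, hi_c)
      if (i == 1L ||
          min((rows[seq_len(i - 1)] - r)^2 + (cols[seq_len(i - 1)] - c)^2) >=
            cfg$min_separation^2) {
        rows[i] <- r; cols[i] <- c; placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop(sprintf(paste0("could not place %d vesicles with min_separation = ",
                          "%g px in a %d x %d field: density constraint ",
                          "violated after %d attempts"),
                   n, cfg$min_separation, cfg$image_height, cfg$image_width,
                   budget), call. = FALSE)
    }
  }
  radius <- stats::runif(n, cfg$ring_radius_range[1], cfg$ring_radius_range[2])
  data.frame(center_row = rows, center_col = cols, radius = radius)
}

# --- rendering ---------------------------------------------------------------

SUPERSAMPLE <- 4L

# Rasterize the indicator of r_inner <= dist(center) <= r_outer into `img`,
# scaled by `amplitude`, using 4x supersampling so sub-pixel centers render
# smoothly. r_inner = 0 gives a filled disk. Modifies a copy; returns it.
add_annulus <- function(img, center_row, center_col, r_outer, r_inner,
                        amplitude) {
  s <- SUPERSAMPLE
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, floor(center_row - r_outer - 1))
  r1 <- min(h, ceiling(center_row + r_outer + 1))
  c0 <- max(1L, floor(center_col - r_outer - 1))
  c1 <- min(w, ceiling(center_col + r_outer + 1))
  if (r1 < r0 || c1 < c0) return(img)
  # subpixel sample coordinates: pixel i covers [i - 0.5, i + 0.5)
  sub <- (seq_len(s) - 0.5) / s - 0.5
  rr <- rep(r0:r1, each = s) + sub
  cc <- rep(c0:c1, each = s) + sub
  d2 <- outer((rr - center_row)^2, (cc - center_col)^2, `+`)
  inside <- d2 <= r_outer^2 & d2 >= r_inner^2
  # average s x s blocks back to pixel resolution
  nr <- r1 - r0 + 1L; nc <- c1 - c0 + 1L
  dim(inside) <- c(s, nr, s, nc)
  frac <- apply(inside, c(2, 4), mean)
  img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + amplitude * frac
  img
}

# Deposit a point source at a sub-pixel position via bilinear weights; the PSF
# blur applied afterwards turns it into a Gaussian spot of total `amplitude`.
add_point_source <- function(img, row, col, amplitude) {
  h <- nrow(img); w <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  pts <- rbind(c(r0, c0, (1 - fr) * (1 - fc)),
               c(r0 + 1, c0, fr * (1 - fc)),
               c(r0, c0 + 1, (1 - fr) * fc),
               c(r0 + 1, c0 + 1, fr * fc))
  for (k in seq_len(nrow(pts))) {
    r <- pts[k, 1]; c <- pts[k, 2]
    if (r >= 1 && r <= h && c >= 1 && c <= w) {
      img[r, c] <- img[r, c] + amplitude * pts[k, 3]
    }
  }
  img
}

blur_psf <- function(img, sigma) {
  if (sigma <= 0) return(img)
  # the Gaussian brush must fit inside the image; cap it for small images
  size <- 2 * ceiling(3 * sigma) + 1
  limit <- min(dim(img))
  if (limit %% 2 == 0) limit <- limit - 1L
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = min(size, limit)))
}

# Shot noise then read noise, quantized to integer ADU and clamped at zero,
# as a photon-counting camera would record.
apply_noise <- function(noiseless, cfg) {
  n <- length(noiseless)
  shot <- stats::rpois(n, lambda = pmax(noiseless, 0))
  out <- shot + stats::rnorm(n, mean = 0, sd = cfg$read_noise_sigma)
  out <- pmax(round(out), 0)
  matrix(out, nrow = nrow(noiseless))
}

# Noiseless render (background included) of one frame given vesicle geometry
# and positions. `positions` has columns row, col aligned with `vesicles`;
# `puncta` has columns row, col (may have zero rows).
render_frame <- function(vesicles, positions, puncta, cfg,
                         include_punctum_channel) {
  h <- cfg$image_height; w <- cfg$image_width
  marker <- matrix(0, h, w)
  cargo <- matrix(0, h, w)
  for (i in seq_len(nrow(vesicles))) {
    r <- vesicles$radius[i]
    marker <- add_annulus(marker, positions$row[i], positions$col[i],
                          r_outer = r, r_inner = r - cfg$ring_thickness,
                          amplitude = cfg$marker_amplitude)
    if (vesicles$is_cargo_positive[i]) {
      cargo <- add_annulus(cargo, positions$row[i], positions$col[i],
                           r_outer = r - cfg$ring_thickness, r_inner = 0,
                           amplitude = cfg$cargo_amplitude)
    }
  }
  marker <- blur_psf(marker, cfg$psf_sigma) + cfg$background_level
  cargo <- blur_psf(cargo, cfg$psf_sigma) + cfg$background_level
  out <- list(marker = marker, cargo = cargo)
  if (include_punctum_channel) {
    pim <- matrix(0, h, w)
    if (nrow(puncta) > 0) {
      for (k in seq_len(nrow(puncta))) {
        pim <- add_point_source(pim, puncta$row[k], puncta$col[k],
                                cfg$punctum_amplitude)
      }
    }
    out$punctum <- blur_psf(pim, cfg$psf_sigma) + cfg$background_level
  }
  out
}

# --- ground truth ------------------------------------------------------------

new_ground_truth <- function(vesicles, tracks) {
  structure(list(vesicles = vesicles, tracks = tracks), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d vesicles (%d cargo-positive, %d with punctum)",
              nrow(x$vesicles), sum(x$vesicles$is_cargo_positive),
              sum(x$vesicles$has_punctum)))
  if (nrow(x$tracks) > 0) {
    cat(sprintf(", %d tracked objects over %d frames",
                length(unique(x$tracks$track_id)), max(x$tracks$frame)))
  }
  cat("\n")
  invisible(x)
}

# --- public simulators -------------------------------------------------------

#' Simulate one still dual-channel vesicle field
#'
#' Places vesicles by rejection sampling, renders the marker-ring / cargo-lumen
#' geometry at 4x supersampling, blurs with the Gaussian PSF, adds the uniform
#' background, then applies Poisson shot noise and Gaussian read noise.
#' Identical configs (including seed) yield bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return A list with elements `stack` (a [frame_stack] with one frame;
#'   channels `marker`, `cargo`, and `punctum` when
#'   `punctum_attach_fraction > 0`) and `truth` (a `ground_truth` object whose
#'   `$vesicles` data frame records id, center, radius, cargo and punctum
#'   status of every vesicle).
#' @export
simulate_field <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  withr::with_seed(cfg$seed, {
    ves <- place_vesicles(cfg)
    n <- nrow(ves)
    ves$vesicle_id <- seq_len(n)
    ves$is_cargo_positive <- stats::runif(n) < cfg$coloc_fraction
    ves$has_punctum <- ves$is_cargo_positive &
      stats::runif(n) < cfg$punctum_attach_fraction
    include_punctum <- cfg$punctum_attach_fraction > 0
    positions <- data.frame(row = ves$center_row, col = ves$center_col)
    puncta <- positions[ves$has_punctum, , drop = FALSE]
    ch <- render_frame(ves, positions, puncta, cfg, include_punctum)
    mats <- lapply(ch, apply_noise, cfg = cfg)
    arr <- array(unlist(mats, use.names = FALSE),
                 dim = c(cfg$image_height, cfg$image_width, length(mats), 1L))
    stack <- frame_stack(arr, channels = names(ch),
                         frame_interval = cfg$frame_interval)
    truth <- new_ground_truth(
      vesicles = ves[, c("vesicle_id", "center_row", "center_col", "radius",
                         "is_cargo_positive", "has_punctum")],
      tracks = empty_track_table()
    )
    list(stack = stack, truth = truth)
  })
}

empty_track_table <- function() {
  data.frame(track_id = integer(0), vesicle_id = integer(0),
             object_type = character(0), motion_class = character(0),
             frame = integer(0), row = numeric(0), col = numeric(0))
}

# One trajectory of n_frames positions from a start point.
# Diffusive steps have per-axis variance 2*D*dt so the squared planar
# displacement per frame averages 4*D*dt.
make_trajectory <- function(start, motion_class, cfg) {
  nf <- cfg$n_frames
  dt <- 1  # motion parameters are expressed per frame
  if (motion_class == "directed") {
    theta <- stats::runif(1, 0, 2 * pi)
    t <- seq_len(nf) - 1
    row <- start[1] + cfg$speed * t * sin(theta)
    col <- start[2] + cfg$speed * t * cos(theta)
    if (cfg$position_noise_sigma > 0) {
      row <- row + stats::rnorm(nf, 0, cfg$position_noise_sigma)
      col <- col + stats::rnorm(nf, 0, cfg$position_noise_sigma)
      row[1] <- start[1]; col[1] <- start[2]
    }
  } else {
    sd_step <- sqrt(2 * cfg$diffusion_coefficient * dt)
    row <- start[1] + c(0, cumsum(stats::rnorm(nf - 1, 0, sd_step)))
    col <- start[2] + c(0, cumsum(stats::rnorm(nf - 1, 0, sd_step)))
    if (motion_class == "confined") {
      # reflect radially about the start whenever a step leaves the cage
      rc <- cfg$confinement_radius
      for (i in 2:nf) {
        dr <- row[i] - start[1]; dc <- col[i] - start[2]
        d <- sqrt(dr^2 + dc^2)
        while (d > rc && d > 0) {
          scale <- (2 * rc - d) / d
          if (scale < 0) scale <- 0  # pathological long step: clamp to center
          dr <- dr * scale; dc <- dc * scale
          # subsequent increments are relative; shift the remaining path
          shift_r <- (start[1] + dr) - row[i]
          shift_c <- (start[2] + dc) - col[i]
          row[i:nf] <- row[i:nf] + shift_r
          col[i:nf] <- col[i:nf] + shift_c
          d <- sqrt(dr^2 + dc^2)
        }
      }
    }
  }
  cbind(row = row, col = col)
}

#' Simulate ground-truth trajectories without rendering images
#'
#' Draws motion classes from `motion_mix` and generates per-frame positions
#' for `n_vesicles` objects: constant-velocity motion with a random fixed
#' heading plus per-frame localization jitter (`directed`), a 2-D random walk
#' with per-frame squared displacement 4 D dt (`diffusive`), or the same walk
#' reflected at `confinement_radius` about the start (`confined`). Useful for
#' testing trajectory statistics at scales where rendering every frame would
#' be wasteful.
#'
#' @param config a [simulation_config()] with `n_frames >= 2`.
#' @param bounded clamp positions to keep objects two radii inside the image
#'   (the behaviour used when rendering); set `FALSE` for free trajectories.
#' @return A data frame with columns `track_id`, `vesicle_id`, `object_type`,
#'   `motion_class`, `frame`, `row`, `col`.
#' @export
simulate_tracks <- function(config, bounded = FALSE) {
  validate_simulation_config(config)
  cfg <- config
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2 for trajectories",
                              call. = FALSE)
  withr::with_seed(cfg$seed, simulate_tracks_impl(cfg, bounded)$tracks)
}

# Shared by simulate_tracks and simulate_timelapse (which seeds externally).
simulate_tracks_impl <- function(cfg, bounded) {
  ves <- place_vesicles(cfg)
  n <- nrow(ves)
  ves$vesicle_id <- seq_len(n)
  ves$is_cargo_positive <- stats::runif(n) < cfg$coloc_fraction
  ves$has_punctum <- ves$is_cargo_positive &
    stats::runif(n) < cfg$punctum_attach_fraction
  classes <- c("directed", "diffusive", "confined")
  ves$motion_class <- if (n > 0) {
    sample(classes, n, replace = TRUE, prob = cfg$motion_mix[classes])
  } else character(0)
  nf <- cfg$n_frames
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- make_trajectory(c(ves$center_row[i], ves$center_col[i]),
                          ves$motion_class[i], cfg)
    if (bounded) {
      m <- 2 * ves$radius[i]
      tr[, "row"] <- pmin(pmax(tr[, "row"], 1 + m), cfg$image_height - m)
      tr[, "col"] <- pmin(pmax(tr[, "col"], 1 + m), cfg$image_width - m)
    }
    rows[[i]] <- data.frame(track_id = i, vesicle_id = i,
                            object_type = "vesicle",
                            motion_class = ves$motion_class[i],
                            frame = seq_len(nf),
                            row = tr[, "row"], col = tr[, "col"])
  }
  tracks <- if (n > 0) do.call(rbind, rows) else empty_track_table()
  # attached puncta copy their vesicle's positions exactly
  pidx <- which(ves$has_punctum)
  if (length(pidx) > 0) {
    ptracks <- lapply(seq_along(pidx), function(k) {
      i <- pidx[k]
      v <- rows[[i]]
      data.frame(track_id = n + k, vesicle_id = i, object_type = "punctum",
                 motion_class = ves$motion_class[i], frame = v$frame,
                 row = v$row, col = v$col)
    })
    tracks <- rbind(tracks, do.call(rbind, ptracks))
  }
  list(vesicles = ves, tracks = tracks)
}

#' Build vesicle ROIs directly from simulator ground truth
#'
#' Constructs the ideal segmentation a perfect detector would produce: one
#' filled lumen disk (radius `radius - ring_thickness`) per ground-truth
#' vesicle, labeled 1..K in centroid (row, col) order like
#' [detect_vesicles()] output. This bypasses detection entirely and is the
#' oracle against which the detection-based pipeline is validated.
#'
#' @param truth a `ground_truth` object from [simulate_field()] or
#'   [simulate_timelapse()].
#' @param dim image dimensions `c(height, width)` in pixels.
#' @param ring_thickness the ring thickness used in the simulation.
#' @param marker_image optional marker matrix used to fill
#'   `mean_marker_intensity` (otherwise `NA`).
#' @return A `vesicle_rois` object; attribute `vesicle_id` maps each table
#'   row to its ground-truth vesicle.
#' @export
rois_from_truth <- function(truth, dim, ring_thickness = 2,
                            marker_image = NULL) {
  stopifnot(inherits(truth, "ground_truth"), length(dim) == 2)
  tv <- truth$vesicles
  ord <- order(tv$center_row, tv$center_col)
  tv <- tv[ord, ]
  lab <- matrix(0L, dim[1], dim[2])
  n <- nrow(tv)
  rowc <- colc <- area <- numeric(n)
  for (i in seq_len(n)) {
    r <- tv$radius[i] - ring_thickness
    r0 <- max(1L, floor(tv$center_row[i] - r))
    r1 <- min(dim[1], ceiling(tv$center_row[i] + r))
    c0 <- max(1L, floor(tv$center_col[i] - r))
    c1 <- min(dim[2], ceiling(tv$center_col[i] + r))
    d2 <- outer((r0:r1 - tv$center_row[i])^2, (c0:c1 - tv$center_col[i])^2, `+`)
    sel <- d2 <= r^2
    sub <- lab[r0:r1, c0:c1]
    sub[sel] <- i
    lab[r0:r1, c0:c1] <- sub
    px <- which(sel, arr.ind = TRUE)
    rowc[i] <- mean(px[, 1] + r0 - 1)
    colc[i] <- mean(px[, 2] + c0 - 1)
    area[i] <- sum(sel)
  }
  tab <- data.frame(label_id = seq_len(n), row = rowc, col = colc,
                    area = as.integer(area),
                    mean_marker_intensity = NA_real_)
  if (!is.null(marker_image) && n > 0) {
    idx <- which(lab > 0)
    m <- tapply(marker_image[idx], lab[idx], mean)
    tab$mean_marker_intensity <- as.numeric(m[as.character(tab$label_id)])
  }
  res <- new_vesicle_rois(tab, lab)
  attr(res, "vesicle_id") <- tv$vesicle_id
  res
}

#' Simulate a dual-channel time-lapse stack with known motion
#'
#' Generates trajectories as in [simulate_tracks()] (positions clamped to stay
#' two radii inside the field), renders every frame with the still-field
#' geometry and noise model of [simulate_field()], and returns the full
#' per-frame ground truth.
#'
#' @param config a [simulation_config()] with `n_frames >= 2`.
#' @return A list with `stack` (a [frame_stack]) and `truth` (vesicle table
#'   plus per-frame track table).
#' @export
simulate_timelapse <- function(config) {
  validate_simulation_config(config)
  cfg <- config
  if (cfg$n_frames < 2L) stop("n_frames must be >= 2 for a time-lapse",
                              call. = FALSE)
  withr::with_seed(cfg$seed, {
    sim <- simulate_tracks_impl(cfg, bounded = TRUE)
    ves <- sim$vesicles
    tracks <- sim$tracks
    # time-lapse stacks always carry the punctum channel (pure background when
    # no punctum realizes) so co-transport analyses run uniformly
    include_punctum <- TRUE
    nf <- cfg$n_frames
    nch <- if (include_punctum) 3L else 2L
    arr <- array(0, dim = c(cfg$image_height, cfg$image_width, nch, nf))
    vt <- tracks[tracks$object_type == "vesicle", ]
    pt <- tracks[tracks$object_type == "punctum", ]
    for (f in seq_len(nf)) {
      vf <- vt[vt$frame == f, ]
      vf <- vf[order(vf$vesicle_id), ]
      positions <- data.frame(row = vf$row, col = vf$col)
      puncta <- pt[pt$frame == f, c("row", "col")]
      ch <- render_frame(ves, positions, puncta, cfg, include_punctum)
      mats <- lapply(ch, apply_noise, cfg = cfg)
      for (ci in seq_along(mats)) arr[, , ci, f] <- mats[[ci]]
    }
    channels <- c("marker", "cargo", if (include_punctum) "punctum")
    stack <- frame_stack(arr, channels = channels,
                         frame_interval = cfg$frame_interval)
    truth <- new_ground_truth(
      vesicles = ves[, c("vesicle_id", "center_row", "center_col", "radius",
                         "is_cargo_positive", "has_punctum", "motion_class")],
      tracks = tracks
    )
    list(stack = stack, truth = truth)
  })
}
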