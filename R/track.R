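#' Link per-frame detections into trajectories
#'
#' Greedy nearest-neighbor linking: for each frame transition, all
#' (track, detection) candidate pairs within `max_displacement` are processed
#' in ascending distance order (ties broken by the lower track id) and
#' assigned first-come-first-served. Tracks that miss a detection persist for
#' up to `max_gap` frames; if they are re-acquired, the missing positions are
#' filled by linear interpolation and counted in the track's `gaps`.
#' Detections left unmatched start new tracks, ids assigned in (row, col)
#' order. The procedure is fully deterministic.
#'
#' @param detections a list, one element per frame, each a data frame with
#'   numeric columns `row` and `col` (zero-row frames allowed).
#' @param max_displacement maximum link distance per frame transition, pixels.
#' @param max_gap maximum number of consecutive missed frames (default 0).
#' @return A data frame of class `tracks` with columns `track_id`, `frame`,
#'   `row`, `col`, `interpolated` (logical). Tracks with a single point are
#'   dropped. Empty input gives an empty table.
#' @export
link_detections <- function(detections, max_displacement, max_gap = 0L) {
  stopifnot(is.list(detections), max_displacement > 0, max_gap >= 0)
  empty <- structure(data.frame(track_id = integer(0), frame = integer(0),
                                row = numeric(0), col = numeric(0),
                                interpolated = logical(0)),
                     class = c("tracks", "data.frame"))
  nf <- length(detections)
  if (nf == 0) return(empty)
  det <- lapply(detections, function(d) {
    d <- as.data.frame(d)
    if (nrow(d) > 0) d <- d[order(d$row, d$col), c("row", "col")]
    d
  })
  # active track state: id, last detected (row, col), frame of last detection
  active <- data.frame(id = integer(0), row = numeric(0), col = numeric(0),
                       last_frame = integer(0))
  points <- list()  # per track id: data.frame(frame, row, col, interpolated)
  next_id <- 1L
  start_tracks <- function(d, f) {
    for (i in seq_len(nrow(d))) {
      points[[next_id]] <<- data.frame(frame = f, row = d$row[i],
                                       col = d$col[i], interpolated = FALSE)
      active <<- rbind(active, data.frame(id = next_id, row = d$row[i],
                                          col = d$col[i], last_frame = f))
      next_id <<- next_id + 1L
    }
  }
  start_tracks(det[[1]], 1L)
  for (f in seq_len(nf)[-1]) {
    d <- det[[f]]
    nd <- nrow(d)
    matched_det <- logical(nd)
    matched_trk <- logical(nrow(active))
    if (nd > 0 && nrow(active) > 0) {
      dist2 <- outer(active$row, d$row, `-`)^2 + outer(active$col, d$col, `-`)^2
      cand <- which(dist2 <= max_displacement^2, arr.ind = TRUE)
      if (nrow(cand) > 0) {
        ord <- order(dist2[cand], active$id[cand[, 1]])
        for (kk in ord) {
          ti <- cand[kk, 1]; di <- cand[kk, 2]
          if (matched_trk[ti] || matched_det[di]) next
          matched_trk[ti] <- TRUE; matched_det[di] <- TRUE
          id <- active$id[ti]
          lastf <- active$last_frame[ti]
          if (f - lastf > 1L) {  # close the gap by linear interpolation
            gf <- (lastf + 1L):(f - 1L)
            wt <- (gf - lastf) / (f - lastf)
            points[[id]] <- rbind(points[[id]], data.frame(
              frame = gf,
              row = active$row[ti] + wt * (d$row[di] - active$row[ti]),
              col = active$col[ti] + wt * (d$col[di] - active$col[ti]),
              interpolated = TRUE))
          }
          points[[id]] <- rbind(points[[id]], data.frame(
            frame = f, row = d$row[di], col = d$col[di], interpolated = FALSE))
          active$row[ti] <- d$row[di]; active$col[ti] <- d$col[di]
          active$last_frame[ti] <- f
        }
      }
    }
    # retire tracks that exceeded the gap budget
    keep <- active$last_frame >= f - max_gap
    active <- active[keep | matched_trk, , drop = FALSE]
    if (nd > 0 && any(!matched_det)) {
      start_tracks(d[!matched_det, , drop = FALSE], f)
    }
  }
  points <- points[lengths(points) > 0]
  out <- do.call(rbind, lapply(seq_along(points), function(i) {
    p <- points[[i]]
    if (nrow(p) < 2) return(NULL)
    cbind(track_id = i, p)
  }))
  if (is.null(out)) return(empty)
  # renumber track ids consecutively in original creation order
  out$track_id <- match(out$track_id, unique(out$track_id))
  rownames(out) <- NULL
  class(out) <- c("tracks", "data.frame")
  out
}

#' Mean squared displacement of one trajectory
#'
#' Time-averaged MSD: for lag tau, the average over all ordered pairs of
#' points separated by tau frames of their squared Euclidean displacement.
#' Lags run from one frame up to `max_lag_fraction` of the track duration;
#' the tail is excluded because long-lag MSD values average very few pairs
#' and are dominated by noise.
#'
#' @param track a data frame with columns `frame`, `row`, `col` for a single
#'   trajectory (consecutive frames; at least 4 points).
#' @param frame_interval seconds per frame.
#' @param max_lag_fraction fraction of the track duration to use (default
#'   0.25).
#' @return A data frame of class `msd_profile` with columns `lag` (seconds),
#'   `msd` (pixels^2) and `n_pairs`; the frame interval is kept as attribute
#'   `frame_interval`.
#' @export
compute_msd <- function(track, frame_interval = 1, max_lag_fraction = 0.25) {
  track <- as.data.frame(track)
  stopifnot(all(c("frame", "row", "col") %in% names(track)),
            frame_interval > 0, max_lag_fraction > 0)
  track <- track[order(track$frame), ]
  n <- nrow(track)
  if (n < 4) stop("track must have at least 4 points", call. = FALSE)
  if (any(diff(track$frame) != 1)) {
    stop("track frames must be consecutive", call. = FALSE)
  }
  max_lag <- max(1L, floor(max_lag_fraction * (n - 1)))
  lags <- seq_len(max_lag)
  msd <- numeric(max_lag)
  np <- integer(max_lag)
  for (tau in lags) {
    d2 <- (track$row[(1 + tau):n] - track$row[1:(n - tau)])^2 +
      (track$col[(1 + tau):n] - track$col[1:(n - tau)])^2
    msd[tau] <- mean(d2)
    np[tau] <- n - tau
  }
  structure(data.frame(lag = lags * frame_interval, msd = msd, n_pairs = np),
            frame_interval = frame_interval,
            class = c("msd_profile", "data.frame"))
}

#' Classify motion from an MSD profile
#'
#' Fits `log(MSD) ~ log(tau)` by least squares over the usable lags (those
#' with MSD > 0). The slope is the anomalous-diffusion exponent alpha:
#' directed/active transport gives alpha near 2, free diffusion alpha near 1,
#' confined motion a flattening curve with alpha < 1. Classes are assigned by
#' thresholds `alpha >= directed_cutoff` (directed),
#' `alpha < confined_cutoff` (confined), diffusive in between. For a
#' diffusive trajectory MSD(tau) = 4 D tau, so D is recovered from the fit
#' intercept as `exp(intercept) / 4`; for a directed classification a speed
#' is additionally estimated from a through-origin fit of `sqrt(MSD)` on tau.
#'
#' @param msd a [compute_msd()] result.
#' @param directed_cutoff,confined_cutoff class boundaries on alpha
#'   (defaults 1.4 and 0.7).
#' @return A list of class `motion_estimate`: `alpha`,
#'   `diffusion_coefficient` (pixels^2/s), `velocity` (pixels/s; `NA` unless
#'   directed), `r_squared`, `motion_class` (one of `"directed"`,
#'   `"diffusive"`, `"confined"`, or `"unclassifiable"` when fewer than 3
#'   usable lags remain).
#' @export
classify_motion <- function(msd, directed_cutoff = 1.4, confined_cutoff = 0.7) {
  stopifnot(inherits(msd, "msd_profile"), directed_cutoff > confined_cutoff)
  use <- msd$msd > 0
  if (sum(use) < 3) {
    return(structure(list(alpha = NA_real_,
                          diffusion_coefficient = NA_real_,
                          velocity = NA_real_, r_squared = NA_real_,
                          motion_class = "unclassifiable"),
                     class = "motion_estimate"))
  }
  lt <- log(msd$lag[use]); lm_ <- log(msd$msd[use])
  fit <- stats::lm.fit(cbind(1, lt), lm_)
  alpha <- fit$coefficients[2]
  intercept <- fit$coefficients[1]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lm_ - mean(lm_))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  cls <- if (alpha >= directed_cutoff) "directed"
         else if (alpha >= confined_cutoff) "diffusive" else "confined"
  velocity <- NA_real_
  if (cls == "directed") {
    # sqrt(MSD) = v * tau for pure directed motion
    s <- sqrt(msd$msd[use]); tau <- msd$lag[use]
    velocity <- sum(s * tau) / sum(tau^2)
  }
  structure(list(alpha = unname(alpha),
                 diffusion_coefficient = unname(exp(intercept) / 4),
                 velocity = velocity,
                 r_squared = r2,
                 motion_class = cls),
            class = "motion_estimate")
}

#' @export
print.motion_estimate <- function(x, ...) {
  cat(sprintf("motion_estimate: %s (alpha = %.3g, D = %.3g px^2/s%s)\n",
              x$motion_class, x$alpha, x$diffusion_coefficient,
              if (is.finite(x$velocity))
                sprintf(", v = %.3g px/s", x$velocity) else ""))
  invisible(x)
}

#' Classify every track in a linked track table
#'
#' Convenience wrapper applying [compute_msd()] + [classify_motion()] per
#' track; tracks too short for an MSD are reported as unclassifiable.
#'
#' @param tracks a [link_detections()] result (or any data frame with
#'   `track_id`, `frame`, `row`, `col`).
#' @inheritParams compute_msd
#' @inheritParams classify_motion
#' @return A data frame, one row per track: `track_id`, `n_points`, `alpha`,
#'   `diffusion_coefficient`, `velocity`, `r_squared`, `motion_class`.
#' @export
classify_tracks <- function(tracks, frame_interval = 1, max_lag_fraction = 0.25,
                            directed_cutoff = 1.4, confined_cutoff = 0.7) {
  ids <- unique(tracks$track_id)
  if (length(ids) == 0) {
    return(data.frame(track_id = integer(0), n_points = integer(0),
                      alpha = numeric(0), diffusion_coefficient = numeric(0),
                      velocity = numeric(0), r_squared = numeric(0),
                      motion_class = character(0)))
  }
  rows <- lapply(ids, function(id) {
    tr <- tracks[tracks$track_id == id, ]
    est <- if (nrow(tr) >= 4) {
      classify_motion(compute_msd(tr, frame_interval, max_lag_fraction),
                      directed_cutoff, confined_cutoff)
    } else {
      list(alpha = NA_real_, diffusion_coefficient = NA_real_,
           velocity = NA_real_, r_squared = NA_real_,
           motion_class = "unclassifiable")
    }
    data.frame(track_id = id, n_points = nrow(tr), alpha = est$alpha,
               diffusion_coefficient = est$diffusion_coefficient,
               velocity = est$velocity, r_squared = est$r_squared,
               motion_class = est$motion_class)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fraction of vesicles co-transported with a punctum
#'
#' Vesicle ROIs detected per frame are first linked across frames (by their
#' centroids, via [link_detections()]); a vesicle is punctum-associated in a
#' frame when some punctum lies within `max_distance` of its centroid or
#' inside its pixel set, and is counted co-transported when associated in at
#' least `min_frames` frames.
#'
#' @param rois_per_frame list of `vesicle_rois`, one per frame.
#' @param puncta_per_frame list of [detect_puncta()] tables, one per frame.
#' @param max_distance association radius, pixels (default 5).
#' @param min_frames minimum associated frames for a positive call
#'   (default: half the number of frames, rounded up).
#' @param link_max_displacement maximum per-frame vesicle movement used for
#'   linking (default `2 * max_distance`).
#' @return A list with `summary` (a `coloc_summary` over vesicles) and
#'   `per_vesicle` (data frame: `track_id`, `n_frames_tracked`,
#'   `n_frames_associated`, `is_positive`).
#' @export
cotransport_fraction <- function(rois_per_frame, puncta_per_frame,
                                 max_distance = 5,
                                 min_frames = NULL,
                                 link_max_displacement = 2 * max_distance) {
  stopifnot(is.list(rois_per_frame), is.list(puncta_per_frame),
            length(rois_per_frame) == length(puncta_per_frame),
            max_distance > 0)
  nf <- length(rois_per_frame)
  if (nf == 0 || all(vapply(rois_per_frame,
                            function(r) nrow(r$table) == 0, logical(1)))) {
    return(list(summary = percent_positive(logical(0)),
                per_vesicle = data.frame(track_id = integer(0),
                                         n_frames_tracked = integer(0),
                                         n_frames_associated = integer(0),
                                         is_positive = logical(0))))
  }
  if (is.null(min_frames)) min_frames <- ceiling(nf / 2)
  if (nf == 1) {
    tab <- rois_per_frame[[1]]$table
    tracks <- data.frame(track_id = tab$label_id, frame = 1L,
                         row = tab$row, col = tab$col)
  } else {
    dets <- lapply(rois_per_frame, function(r) r$table[, c("row", "col")])
    tracks <- link_detections(dets, max_displacement = link_max_displacement,
                              max_gap = 1L)
  }
  if (nrow(tracks) == 0) {
    return(list(summary = percent_positive(logical(0)),
                per_vesicle = data.frame(track_id = integer(0),
                                         n_frames_tracked = integer(0),
                                         n_frames_associated = integer(0),
                                         is_positive = logical(0))))
  }
  assoc <- vapply(seq_len(nrow(tracks)), function(i) {
    f <- tracks$frame[i]
    p <- puncta_per_frame[[f]]
    if (is.null(p) || nrow(p) == 0) return(FALSE)
    d2 <- (p$row - tracks$row[i])^2 + (p$col - tracks$col[i])^2
    if (min(d2) <= max_distance^2) return(TRUE)
    # fall back to pixel-set membership for large vesicles
    lm_ <- rois_per_frame[[f]]$label_map
    lab_here <- lm_[pmin(pmax(round(tracks$row[i]), 1), nrow(lm_)),
                    pmin(pmax(round(tracks$col[i]), 1), ncol(lm_))]
    if (lab_here == 0) return(FALSE)
    pr <- pmin(pmax(round(p$row), 1), nrow(lm_))
    pc <- pmin(pmax(round(p$col), 1), ncol(lm_))
    any(lm_[cbind(pr, pc)] == lab_here)
  }, logical(1))
  ids <- unique(tracks$track_id)
  per <- data.frame(
    track_id = ids,
    n_frames_tracked = as.integer(tapply(tracks$frame, tracks$track_id,
                                         length)[as.character(ids)]),
    n_frames_associated = as.integer(tapply(assoc, tracks$track_id,
                                            sum)[as.character(ids)])
  )
  per$is_positive <- per$n_frames_associated >= min_frames
  list(summary = percent_positive(per$is_positive), per_vesicle = per)
}
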