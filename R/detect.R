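#' Vesicle detection parameters
#'
#' Controls the marker-channel segmentation pipeline: band-pass difference of
#' Gaussians, global threshold, binary hole filling (so ring-shaped marker
#' signal becomes a filled, lumen-covering region), 4-connected labeling, and
#' an area filter.
#'
#' @param sigma_low DoG fine scale, pixels; of the order of the PSF width.
#' @param sigma_high DoG coarse scale, pixels; of the order of the vesicle
#'   diameter so rings survive the band-pass.
#' @param threshold_method `"otsu"` (default; intensity-scale invariant) or
#'   `"percentile"` (fixed upper quantile of the band-passed image).
#' @param percentile quantile used when `threshold_method = "percentile"`.
#' @param min_area,max_area ROI area bounds in pixels.
#' @param discard_border drop ROIs touching the image border (default) to
#'   avoid biased partial-object intensities.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(sigma_low = 1, sigma_high = 6,
                             threshold_method = c("otsu", "percentile"),
                             percentile = 0.99,
                             min_area = 9, max_area = Inf,
                             discard_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(sigma_low > 0, sigma_high > sigma_low,
            percentile > 0, percentile < 1,
            min_area >= 1, max_area >= min_area)
  structure(list(sigma_low = sigma_low, sigma_high = sigma_high,
                 threshold_method = threshold_method, percentile = percentile,
                 min_area = min_area, max_area = max_area,
                 discard_border = discard_border),
            class = "detection_params")
}

check_image <- function(img, min_dim = 16L) {
  if (!is.matrix(img) || !is.numeric(img)) {
    stop("image must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(img))) stop("image contains non-finite pixels",
                                 call. = FALSE)
  if (nrow(img) < min_dim || ncol(img) < min_dim) {
    stop(sprintf("image must be at least %d x %d pixels", min_dim, min_dim),
         call. = FALSE)
  }
  invisible(img)
}

empty_roi_table <- function() {
  data.frame(label_id = integer(0), row = numeric(0), col = numeric(0),
             area = integer(0), mean_marker_intensity = numeric(0))
}

new_vesicle_rois <- function(table, label_map) {
  structure(list(table = table, label_map = label_map),
            class = "vesicle_rois")
}

#' @export
print.vesicle_rois <- function(x, ...) {
  cat(sprintf("vesicle_rois: %d ROI(s) in a %d x %d label map\n",
              nrow(x$table), nrow(x$label_map), ncol(x$label_map)))
  invisible(x)
}

#' Segment marker-channel vesicles into filled ROIs
#'
#' Builds the object mask used for object-based colocalization. The membrane
#' marker decorates the endosome surface, so its raw signal is a ring; hole
#' filling converts each ring into a filled region covering the lumen, which
#' is where lumenal cargo must be measured.
#'
#' Pipeline: difference-of-Gaussians band-pass -> global threshold (Otsu on
#' the min-max-normalized band-passed image by default) -> hole filling ->
#' 4-connected component labeling -> area filter -> optional border-ROI
#' removal. ROIs are sorted by centroid (row, col) and relabeled 1..K so the
#' output is reproducible and diff-stable.
#'
#' @param marker_image numeric matrix of marker intensities, at least 16 x 16.
#' @param params a [detection_params()].
#' @return An object of class `vesicle_rois`: `$table` is a data frame with
#'   columns `label_id`, `row`, `col` (centroid), `area`,
#'   `mean_marker_intensity`; `$label_map` is an integer matrix (0 =
#'   background) whose positive values are exactly the `label_id`s.
#'   A constant image yields zero ROIs, not an error.
#' @export
detect_vesicles <- function(marker_image, params = detection_params()) {
  check_image(marker_image)
  stopifnot(inherits(params, "detection_params"))
  lm0 <- matrix(0L, nrow(marker_image), ncol(marker_image))
  if (diff(range(marker_image)) <= 0) {
    return(new_vesicle_rois(empty_roi_table(), lm0))
  }
  dog <- blur_psf(marker_image, params$sigma_low) -
    blur_psf(marker_image, params$sigma_high)
  rng <- range(dog)
  if (rng[2] - rng[1] <= 0) return(new_vesicle_rois(empty_roi_table(), lm0))
  norm <- (dog - rng[1]) / (rng[2] - rng[1])
  thr <- switch(params$threshold_method,
                otsu = EBImage::otsu(EBImage::Image(norm)),
                percentile = stats::quantile(norm, params$percentile,
                                             names = FALSE))
  # robust noise floor: on signal-free images Otsu necessarily splits the
  # noise; requiring the threshold to clear the bulk of the band-passed
  # distribution suppresses those spurious clumps (scale-invariant, since
  # median and MAD are computed on the normalized image)
  floor_thr <- stats::median(norm) + 5 * 1.4826 * stats::mad(norm, constant = 1)
  binary <- norm > max(thr, floor_thr)
  if (!any(binary)) return(new_vesicle_rois(empty_roi_table(), lm0))
  filled <- EBImage::fillHull(EBImage::Image(binary * 1))
  labels <- EBImage::bwlabel(filled)  # 4-connected components
  lab <- matrix(as.integer(EBImage::imageData(labels)),
                nrow(marker_image), ncol(marker_image))
  build_rois(lab, marker_image, params)
}

# Area-filter, border-filter, sort and relabel a raw component map.
build_rois <- function(lab, intensity_image, params) {
  h <- nrow(lab); w <- ncol(lab)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0) return(new_vesicle_rois(empty_roi_table(), lab))
  idx <- which(lab > 0)
  px_lab <- lab[idx]
  px_row <- ((idx - 1) %% h) + 1
  px_col <- ((idx - 1) %/% h) + 1
  area <- tapply(px_row, px_lab, length)
  crow <- tapply(px_row, px_lab, mean)
  ccol <- tapply(px_col, px_lab, mean)
  meanint <- tapply(intensity_image[idx], px_lab, mean)
  touches_border <- tapply(px_row == 1 | px_row == h | px_col == 1 | px_col == w,
                           px_lab, any)
  keep <- area >= params$min_area & area <= params$max_area
  if (params$discard_border) keep <- keep & !touches_border
  kept_ids <- as.integer(names(area))[keep]
  if (length(kept_ids) == 0) {
    return(new_vesicle_rois(empty_roi_table(),
                            matrix(0L, h, w)))
  }
  tab <- data.frame(old_id = kept_ids,
                    row = as.numeric(crow[keep]),
                    col = as.numeric(ccol[keep]),
                    area = as.integer(area[keep]),
                    mean_marker_intensity = as.numeric(meanint[keep]))
  tab <- tab[order(tab$row, tab$col), ]
  tab$label_id <- seq_len(nrow(tab))
  remap <- integer(max(ids))
  remap[tab$old_id] <- tab$label_id
  new_lab <- matrix(0L, h, w)
  keep_px <- px_lab %in% tab$old_id
  new_lab[idx[keep_px]] <- remap[px_lab[keep_px]]
  rownames(tab) <- NULL
  new_vesicle_rois(tab[, c("label_id", "row", "col", "area",
                           "mean_marker_intensity")],
                   new_lab)
}

#' Pixel coordinates of one ROI
#'
#' @param rois a `vesicle_rois` object.
#' @param label_id ROI label.
#' @return A two-column matrix of (row, col) pixel coordinates.
#' @export
roi_pixels <- function(rois, label_id) {
  stopifnot(inherits(rois, "vesicle_rois"))
  idx <- which(rois$label_map == label_id)
  h <- nrow(rois$label_map)
  cbind(row = ((idx - 1) %% h) + 1, col = ((idx - 1) %/% h) + 1)
}

#' Punctum detection parameters
#'
#' @param sigma blob scale in pixels (roughly the PSF sigma of a
#'   diffraction-limited particle).
#' @param k threshold in robust sigmas: a local maximum is kept when its
#'   intensity exceeds `median + k * 1.4826 * MAD` of the image.
#' @return A list of class `punctum_params`.
#' @export
punctum_params <- function(sigma = 1.5, k = 5) {
  stopifnot(sigma > 0, k > 0)
  structure(list(sigma = sigma, k = k), class = "punctum_params")
}

#' Detect punctate particles
#'
#' Laplacian-of-Gaussian style blob detection (implemented as a difference of
#' Gaussians at scales `sigma` and `1.6 * sigma`), keeping 8-neighborhood
#' local maxima whose original intensity exceeds a robust background
#' threshold, with sub-pixel localization by intensity-weighted centroid over
#' a 3 x 3 window of background-subtracted intensities.
#'
#' @param punctum_image numeric matrix, at least 16 x 16.
#' @param params a [punctum_params()].
#' @return A data frame with columns `row`, `col` (sub-pixel position) and
#'   `peak_intensity`, sorted by (row, col). Empty when nothing exceeds the
#'   threshold.
#' @export
detect_puncta <- function(punctum_image, params = punctum_params()) {
  check_image(punctum_image)
  stopifnot(inherits(params, "punctum_params"))
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      peak_intensity = numeric(0))
  bg_med <- stats::median(punctum_image)
  bg_mad <- stats::mad(punctum_image, constant = 1)
  # the epsilon keeps FFT convolution ripple from passing a degenerate
  # (MAD = 0) threshold on noiseless images
  eps <- 1e-8 * diff(range(punctum_image))
  thr <- bg_med + max(params$k * 1.4826 * bg_mad, eps)
  dog <- blur_psf(punctum_image, params$sigma) -
    blur_psf(punctum_image, 1.6 * params$sigma)
  h <- nrow(dog); w <- ncol(dog)
  if (h < 3 || w < 3) return(empty)
  core <- dog[2:(h - 1), 2:(w - 1)]
  is_max <- core > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- dog[2:(h - 1) + dr, 2:(w - 1) + dc]
    # strict on the lexicographically earlier neighbor breaks plateau ties
    is_max <- is_max & if (dr < 0 || (dr == 0 && dc < 0)) core > nb else core >= nb
  }
  cand <- which(is_max)
  if (length(cand) == 0) return(empty)
  r <- ((cand - 1) %% (h - 2)) + 2
  c <- ((cand - 1) %/% (h - 2)) + 2
  keep <- punctum_image[cbind(r, c)] > thr
  r <- r[keep]; c <- c[keep]
  if (length(r) == 0) return(empty)
  pos <- t(vapply(seq_along(r), function(i) {
    win_r <- (r[i] - 1):(r[i] + 1)
    win_c <- (c[i] - 1):(c[i] + 1)
    wts <- pmax(punctum_image[win_r, win_c] - bg_med, 0)
    if (sum(wts) == 0) return(c(r[i], c[i]))
    c(sum(outer(win_r, rep(1, 3)) * wts) / sum(wts),
      sum(outer(rep(1, 3), win_c) * wts) / sum(wts))
  }, numeric(2)))
  out <- data.frame(row = pos[, 1], col = pos[, 2],
                    peak_intensity = punctum_image[cbind(r, c)])
  out <- out[order(out$row, out$col), ]
  rownames(out) <- NULL
  out
}
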