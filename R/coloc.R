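#' Robust background model for a cargo channel
#'
#' Estimates the background of the cargo image from pixels that belong to no
#' vesicle: the label map is dilated by `dilation_radius` (a disc) before
#' exclusion so PSF bleed around objects does not contaminate the estimate.
#' Median and (unscaled) MAD are used rather than mean and SD because the
#' bright-vesicle tail would otherwise bias a moment-based estimate.
#'
#' @param cargo_image numeric matrix.
#' @param label_map integer matrix (0 = background) of matching shape, e.g.
#'   `detect_vesicles(...)$label_map`.
#' @param dilation_radius pixels of dilation applied to the ROI mask before
#'   exclusion (default 3).
#' @return A list of class `background_model` with fields `median`, `mad`
#'   (unscaled MAD), `n_pixels_used`, and `low_n` (`TRUE`, with a warning,
#'   when fewer than 100 background pixels were available).
#' @export
estimate_background <- function(cargo_image, label_map, dilation_radius = 3) {
  check_image(cargo_image)
  if (!all(dim(label_map) == dim(cargo_image))) {
    stop("label_map shape does not match the cargo image", call. = FALSE)
  }
  mask <- label_map > 0
  if (any(mask) && dilation_radius > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(dilation_radius) + 1, shape = "disc")
    mask <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask * 1),
                                               brush)) > 0
  }
  bg <- cargo_image[!mask]
  if (length(bg) == 0) {
    stop("no background pixels remain outside the dilated ROIs", call. = FALSE)
  }
  low_n <- length(bg) < 100
  if (low_n) {
    warning(sprintf("background estimated from only %d pixels", length(bg)))
  }
  structure(list(median = stats::median(bg),
                 mad = stats::mad(bg, constant = 1),
                 n_pixels_used = length(bg),
                 low_n = low_n),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf("background_model: median %.3g, MAD %.3g (n = %d%s)\n",
              x$median, x$mad, x$n_pixels_used,
              if (x$low_n) ", LOW" else ""))
  invisible(x)
}

#' Score each vesicle ROI as cargo-positive or cargo-negative
#'
#' For every ROI the mean cargo intensity over its pixel set is compared with
#' a robust background threshold `median + k * 1.4826 * MAD`; the factor
#' 1.4826 makes the MAD a consistent sigma estimate under Gaussian noise.
#' The comparison is strict, so with a degenerate background (MAD = 0) an ROI
#' is positive only if strictly above the background median. The mean (not
#' the maximum) is used because lumenal cargo is an extended signal; a
#' maximum would be driven by single noisy pixels.
#'
#' @param cargo_image numeric matrix.
#' @param rois a `vesicle_rois` object (label map aligned with the image).
#' @param bg a [estimate_background()] result.
#' @param k threshold in robust sigmas (default 3).
#' @return A data frame, one row per ROI in input order: `label_id`,
#'   `cargo_mean`, `threshold_used`, `is_positive`.
#' @export
classify_objects <- function(cargo_image, rois, bg, k = 3) {
  check_image(cargo_image)
  stopifnot(inherits(rois, "vesicle_rois"), inherits(bg, "background_model"),
            k > 0)
  if (!all(dim(rois$label_map) == dim(cargo_image))) {
    stop("label map shape does not match the cargo image", call. = FALSE)
  }
  tab <- rois$table
  out <- data.frame(label_id = tab$label_id,
                    cargo_mean = numeric(nrow(tab)),
                    threshold_used = numeric(nrow(tab)),
                    is_positive = logical(nrow(tab)))
  if (nrow(tab) == 0) return(out)
  idx <- which(rois$label_map > 0)
  means <- tapply(cargo_image[idx], rois$label_map[idx], mean)
  thr <- bg$median + k * 1.4826 * bg$mad
  out$cargo_mean <- as.numeric(means[as.character(tab$label_id)])
  out$threshold_used <- thr
  out$is_positive <- out$cargo_mean > thr
  out
}

#' Summarize object calls into a percentage-positive statistic
#'
#' @param calls data frame from [classify_objects()] (only `is_positive` is
#'   used), or a logical vector.
#' @param conf_level confidence level of the Wilson score interval reported
#'   alongside the percentage.
#' @return A list of class `coloc_summary`: `n_objects`, `n_positive`,
#'   `percent_positive` (in \[0,100\]; `NA` with `undefined = TRUE` when
#'   there are no objects), and `ci_low`/`ci_high` (Wilson, percent).
#' @export
percent_positive <- function(calls, conf_level = 0.95) {
  pos <- if (is.data.frame(calls)) calls$is_positive else as.logical(calls)
  n <- length(pos)
  np <- sum(pos)
  if (n == 0) {
    return(structure(list(n_objects = 0L, n_positive = 0L,
                          percent_positive = NA_real_, undefined = TRUE,
                          ci_low = NA_real_, ci_high = NA_real_),
                     class = "coloc_summary"))
  }
  ci <- suppressWarnings(
    stats::prop.test(np, n, conf.level = conf_level, correct = FALSE)$conf.int
  )
  structure(list(n_objects = as.integer(n), n_positive = as.integer(np),
                 percent_positive = 100 * np / n, undefined = FALSE,
                 ci_low = 100 * ci[1], ci_high = 100 * ci[2]),
            class = "coloc_summary")
}

#' @export
print.coloc_summary <- function(x, ...) {
  if (x$undefined) {
    cat("coloc_summary: no objects (percentage undefined)\n")
  } else {
    cat(sprintf("coloc_summary: %d / %d positive = %.1f%% (95%% CI %.1f-%.1f)\n",
                x$n_positive, x$n_objects, x$percent_positive,
                x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Masked pixel-based colocalization (Pearson and Manders)
#'
#' Computes, over the pixels selected by `mask`, the Pearson correlation of
#' the two channels and the Manders coefficients
#' M1 = sum(a\[b > t_b\]) / sum(a) and M2 = sum(b\[a > t_a\]) / sum(b).
#' Pixel-based statistics answer a different question from the object-based
#' percentage: they measure intensity co-variation inside the mask, and are
#' near zero by construction when two signals occupy disjoint sub-structures
#' (ring vs lumen) of the same object.
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @param mask logical or integer matrix of the same shape; pixels with
#'   `mask > 0` are analyzed.
#' @param threshold_mode how the Manders thresholds are chosen:
#'   `"background-model"` (default): per channel, `median + k * 1.4826 * MAD`
#'   of the pixels *outside* the mask; `"otsu"`: Otsu's threshold of each
#'   full min-max-normalized channel, mapped back to intensity units;
#'   `"fixed"`: caller-supplied `fixed_thresholds`.
#' @param fixed_thresholds numeric length-2 `(t_a, t_b)` for `"fixed"`.
#' @param k robust-sigma multiplier for `"background-model"` (default 3).
#' @return A list of class `pixel_coloc`: `pearson_r`, `manders_m1`,
#'   `manders_m2`, `threshold_a`, `threshold_b`, `mask_area`, plus logical
#'   flags `pearson_defined`, `m1_defined`, `m2_defined` (a statistic whose
#'   denominator degenerates is `NA` with its flag unset).
#' @export
pixel_coloc <- function(image_a, image_b, mask,
                        threshold_mode = c("background-model", "otsu", "fixed"),
                        fixed_thresholds = NULL, k = 3) {
  threshold_mode <- match.arg(threshold_mode)
  check_image(image_a, min_dim = 2L)
  check_image(image_b, min_dim = 2L)
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images must have identical shape", call. = FALSE)
  }
  if (!all(dim(mask) == dim(image_a))) {
    stop("mask shape does not match the images", call. = FALSE)
  }
  sel <- mask > 0
  if (!any(sel)) stop("mask selects no pixels", call. = FALSE)
  a <- image_a[sel]; b <- image_b[sel]
  thr <- switch(threshold_mode,
    "background-model" = {
      out <- !sel
      if (!any(out)) stop("background-model thresholding needs pixels outside the mask",
                          call. = FALSE)
      c(stats::median(image_a[out]) + k * 1.4826 * stats::mad(image_a[out], constant = 1),
        stats::median(image_b[out]) + k * 1.4826 * stats::mad(image_b[out], constant = 1))
    },
    "otsu" = c(otsu_threshold(image_a), otsu_threshold(image_b)),
    "fixed" = {
      if (is.null(fixed_thresholds) || length(fixed_thresholds) != 2) {
        stop("threshold_mode = 'fixed' requires fixed_thresholds = c(t_a, t_b)",
             call. = FALSE)
      }
      as.numeric(fixed_thresholds)
    })
  pearson_defined <- stats::sd(a) > 0 && stats::sd(b) > 0
  pearson_r <- if (pearson_defined) stats::cor(a, b) else NA_real_
  sum_a <- sum(a); sum_b <- sum(b)
  m1_defined <- sum_a > 0
  m2_defined <- sum_b > 0
  structure(list(
    pearson_r = pearson_r,
    manders_m1 = if (m1_defined) sum(a[b > thr[2]]) / sum_a else NA_real_,
    manders_m2 = if (m2_defined) sum(b[a > thr[1]]) / sum_b else NA_real_,
    threshold_a = thr[1], threshold_b = thr[2],
    mask_area = sum(sel),
    pearson_defined = pearson_defined,
    m1_defined = m1_defined, m2_defined = m2_defined
  ), class = "pixel_coloc")
}

# Otsu threshold of a full image in original intensity units.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) return(rng[1])
  norm <- (img - rng[1]) / (rng[2] - rng[1])
  t01 <- EBImage::otsu(EBImage::Image(norm))
  rng[1] + t01 * (rng[2] - rng[1])
}

#' @export
print.pixel_coloc <- function(x, ...) {
  cat(sprintf("pixel_coloc over %d px: Pearson r = %s, M1 = %s, M2 = %s\n",
              x$mask_area,
              formatC(x$pearson_r, digits = 3),
              formatC(x$manders_m1, digits = 3),
              formatC(x$manders_m2, digits = 3)))
  invisible(x)
}
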