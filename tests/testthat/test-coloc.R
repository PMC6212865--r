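make_disk_label <- function(h, w, centers, radius) {
  lab <- matrix(0L, h, w)
  for (i in seq_len(nrow(centers))) {
    d2 <- outer((seq_len(h) - centers[i, 1])^2, (seq_len(w) - centers[i, 2])^2, `+`)
    lab[d2 <= radius^2] <- i
  }
  lab
}

test_that("background model ignores ROI pixels and their dilated halo", {
  img <- matrix(100, 64, 64)
  lab <- make_disk_label(64, 64, rbind(c(20, 20), c(45, 45)), 5)
  img[lab > 0] <- 1e4
  bg <- estimate_background(img, lab, dilation_radius = 3)
  expect_identical(bg$median, 100)
  expect_identical(bg$mad, 0)
  expect_false(bg$low_n)
  # constant field: any mask still gives median 100, mad 0
  bg2 <- estimate_background(matrix(100, 64, 64), lab)
  expect_identical(bg2$median, 100)
  expect_identical(bg2$mad, 0)
})

test_that("background median recovers the simulated Poisson background", {
  meds <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_vesicles = 20, background_level = 50, seed = s)
    sim <- simulate_field(cfg)
    rois <- detect_vesicles(get_frame(sim$stack, "marker"))
    estimate_background(get_frame(sim$stack, "cargo"), rois$label_map)$median
  }, numeric(1))
  expect_true(all(abs(meds - 50) <= 1))
})

test_that("too few background pixels raises the low-n flag", {
  img <- matrix(10, 32, 32)
  lab <- matrix(1L, 32, 32)
  lab[1:2, 1:20] <- 0L
  expect_warning(bg <- estimate_background(img, lab, dilation_radius = 0),
                 "only")
  expect_true(bg$low_n)
  lab_all <- matrix(1L, 32, 32)
  expect_error(estimate_background(img, lab_all, dilation_radius = 0),
               "no background")
})

test_that("object calls implement the strict robust-threshold rule", {
  img <- matrix(100, 64, 64)
  lab <- make_disk_label(64, 64, rbind(c(20, 20), c(45, 45)), 4)
  rois <- vesiquant:::new_vesicle_rois(
    data.frame(label_id = 1:2, row = c(20, 45), col = c(20, 45),
               area = c(sum(lab == 1), sum(lab == 2)),
               mean_marker_intensity = NA_real_), lab)
  bg <- estimate_background(img, lab)
  # constant image: mad = 0, threshold = median, strict inequality fails
  calls <- classify_objects(img, rois, bg, k = 3)
  expect_false(any(calls$is_positive))
  # lift one ROI well above the threshold
  img2 <- img
  img2[lab == 2] <- bg$median + 10 * 1.4826 * max(bg$mad, 1)
  bg2 <- structure(list(median = 100, mad = 1, n_pixels_used = 1000,
                        low_n = FALSE), class = "background_model")
  calls2 <- classify_objects(img2, rois, bg2, k = 3)
  expect_identical(calls2$is_positive, c(FALSE, TRUE))
  expect_equal(calls2$threshold_used, rep(100 + 3 * 1.4826, 2))
})

test_that("raising k never increases the number of positives", {
  sim <- simulate_field(simulation_config(n_vesicles = 40, coloc_fraction = 0.5,
                                          cargo_amplitude = 30, seed = 13))
  cargo <- get_frame(sim$stack, "cargo")
  rois <- detect_vesicles(get_frame(sim$stack, "marker"))
  bg <- estimate_background(cargo, rois$label_map)
  np <- vapply(c(0.5, 1, 2, 3, 5, 10), function(k) {
    sum(classify_objects(cargo, rois, bg, k = k)$is_positive)
  }, numeric(1))
  expect_true(all(diff(np) <= 0))
})

test_that("high-SNR calls on perfect masks equal the ground truth", {
  cfg <- simulation_config(n_vesicles = 40, coloc_fraction = 0.4, seed = 19)
  sim <- simulate_field(cfg)
  cargo <- get_frame(sim$stack, "cargo")
  rois <- rois_from_truth(sim$truth, dim(cargo), cfg$ring_thickness)
  bg <- estimate_background(cargo, rois$label_map)
  calls <- classify_objects(cargo, rois, bg)
  tv <- sim$truth$vesicles
  tv <- tv[order(tv$center_row, tv$center_col), ]
  expect_identical(calls$is_positive, tv$is_cargo_positive)
})

test_that("percent_positive counts, percentage, and edge cases are exact", {
  s <- percent_positive(c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(s$n_objects, 4L)
  expect_identical(s$n_positive, 2L)
  expect_identical(s$percent_positive, 50)
  expect_identical(percent_positive(rep(TRUE, 7))$percent_positive, 100)
  empty <- percent_positive(logical(0))
  expect_true(empty$undefined)
  expect_true(is.na(empty$percent_positive))
  # permutation invariance and brute-force equality
  set.seed(1)
  x <- runif(57) < 0.4
  expect_identical(percent_positive(x)$percent_positive,
                   percent_positive(sample(x))$percent_positive)
  expect_identical(percent_positive(x)$n_positive, sum(x))
})

test_that("Wilson interval brackets the point estimate", {
  s <- percent_positive(c(rep(TRUE, 30), rep(FALSE, 70)))
  expect_lt(s$ci_low, 30)
  expect_gt(s$ci_high, 30)
  expect_gt(s$ci_low, 0)
  expect_lt(s$ci_high, 100)
})

test_that("pixel correlation hits exact values for self and anti pairs", {
  set.seed(5)
  a <- matrix(runif(64 * 64, 10, 200), 64, 64)
  mask <- matrix(TRUE, 64, 64)
  self <- pixel_coloc(a, a, mask, threshold_mode = "otsu")
  expect_equal(self$pearson_r, 1, tolerance = 1e-12)
  anti <- pixel_coloc(a, 300 - a, mask, threshold_mode = "otsu")
  expect_equal(anti$pearson_r, -1, tolerance = 1e-12)
})

test_that("Pearson and Manders match brute-force summation", {
  set.seed(7)
  for (i in 1:20) {
    a <- matrix(rpois(64, 40), 8, 8)
    b <- matrix(rpois(64, 40), 8, 8)
    mask <- matrix(runif(64) < 0.6, 8, 8)
    if (sum(mask) < 3) next
    ta <- 35; tb <- 45
    res <- pixel_coloc(a, b, mask, threshold_mode = "fixed",
                       fixed_thresholds = c(ta, tb))
    av <- a[mask]; bv <- b[mask]
    r_brute <- sum((av - mean(av)) * (bv - mean(bv))) /
      sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
    expect_equal(res$pearson_r, r_brute, tolerance = 1e-12)
    expect_equal(res$manders_m1, sum(av[bv > tb]) / sum(av), tolerance = 1e-12)
    expect_equal(res$manders_m2, sum(bv[av > ta]) / sum(bv), tolerance = 1e-12)
    expect_identical(res$mask_area, sum(mask))
  }
})

test_that("disjoint supports give zero Manders overlap", {
  a <- matrix(0, 16, 16); b <- matrix(0, 16, 16)
  a[1:8, ] <- 50; b[9:16, ] <- 50
  res <- pixel_coloc(a, b, matrix(TRUE, 16, 16), threshold_mode = "fixed",
                     fixed_thresholds = c(10, 10))
  expect_identical(res$manders_m1, 0)
  expect_identical(res$manders_m2, 0)
})

test_that("Pearson is affine invariant; degenerate channels are flagged", {
  set.seed(9)
  a <- matrix(runif(400, 0, 100), 20, 20)
  b <- matrix(runif(400, 0, 100), 20, 20)
  mask <- matrix(TRUE, 20, 20)
  base <- pixel_coloc(a, b, mask, threshold_mode = "fixed",
                      fixed_thresholds = c(50, 50))
  scaled <- pixel_coloc(2.5 * a + 7, b, mask, threshold_mode = "fixed",
                        fixed_thresholds = c(50, 50))
  expect_equal(base$pearson_r, scaled$pearson_r, tolerance = 1e-12)
  flat <- pixel_coloc(matrix(5, 20, 20), b, mask, threshold_mode = "fixed",
                      fixed_thresholds = c(1, 1))
  expect_false(flat$pearson_defined)
  expect_true(is.na(flat$pearson_r))
  zero <- pixel_coloc(matrix(0, 20, 20), b, mask, threshold_mode = "fixed",
                      fixed_thresholds = c(1, 1))
  expect_false(zero$m1_defined)
})

test_that("detection-based estimator tracks the realized fraction closely", {
  errs <- vapply(1:10, function(s) {
    cfg <- simulation_config(n_vesicles = 60, coloc_fraction = 0.4,
                             image_height = 320, image_width = 320, seed = s)
    sim <- simulate_field(cfg)
    cargo <- get_frame(sim$stack, "cargo")
    rois <- detect_vesicles(get_frame(sim$stack, "marker"))
    bg <- estimate_background(cargo, rois$label_map)
    smry <- percent_positive(classify_objects(cargo, rois, bg))
    abs(smry$percent_positive - realized_percent(sim$truth))
  }, numeric(1))
  expect_lt(mean(errs), 5)
})
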