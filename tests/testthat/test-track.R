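test_that("a lone particle yields a single full-length track", {
  dets <- lapply(1:20, function(f) data.frame(row = 10 + f * 0.5, col = 30))
  tr <- link_detections(dets, max_displacement = 2)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 20L)
  expect_identical(tr$frame, 1:20)
})

test_that("empty input and impossible links are handled", {
  expect_identical(nrow(link_detections(list(), max_displacement = 5)), 0L)
  dets <- list(data.frame(row = 1, col = 1), data.frame(row = 50, col = 50))
  expect_identical(nrow(link_detections(dets, max_displacement = 5)), 0L)
})

test_that("equidistant candidates resolve by the deterministic tie rule", {
  # two track heads equidistant from one detection: the lower id claims it
  dets <- list(data.frame(row = c(10, 20), col = c(10, 10)),
               data.frame(row = 15, col = 10))
  tr <- link_detections(dets, max_displacement = 10)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(tr$row, c(10, 15))
  rerun <- link_detections(dets, max_displacement = 10)
  expect_identical(tr, rerun)
})

test_that("gap closing interpolates the missing frame and flags it", {
  dets <- list(data.frame(row = 10, col = 10),
               data.frame(row = numeric(0), col = numeric(0)),
               data.frame(row = 14, col = 10),
               data.frame(row = 16, col = 10))
  tr <- link_detections(dets, max_displacement = 5, max_gap = 1)
  expect_identical(nrow(tr), 4L)
  expect_identical(tr$interpolated, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(tr$row[2], 12)  # linear midpoint
  # with max_gap = 0 the pre-gap singleton is dropped; a fresh track starts
  tr0 <- link_detections(dets, max_displacement = 5, max_gap = 0)
  expect_identical(length(unique(tr0$track_id)), 1L)
  expect_equal(tr0$row, c(14, 16))
})

test_that("with zero gap every detection joins exactly one track", {
  cfg <- track_config(mix_diffusive, seed = 3, n = 15, n_frames = 20)
  tt <- simulate_tracks(cfg)
  dets <- lapply(split(tt, tt$frame), function(d) d[, c("row", "col")])
  tr <- link_detections(dets, max_displacement = 8, max_gap = 0)
  expect_identical(nrow(tr), 15L * 20L)
  expect_false(any(tr$interpolated))
  expect_identical(anyDuplicated(tr[, c("track_id", "frame")]), 0L)
})

test_that("well-separated particles are recovered point-for-point", {
  for (s in 1:10) {
    cfg <- simulation_config(image_height = 2000, image_width = 2000,
                             n_vesicles = 20, min_separation = 80,
                             n_frames = 50, motion_mix = mix_diffusive,
                             diffusion_coefficient = 1, seed = s)
    tt <- simulate_tracks(cfg)
    dets <- lapply(split(tt, tt$frame),
                   function(d) d[order(d$row, d$col), c("row", "col")])
    tr <- link_detections(dets, max_displacement = 8)
    expect_identical(length(unique(tr$track_id)), 20L)
    for (id in unique(tr$track_id)) {
      rec <- tr[tr$track_id == id, ]
      tid <- tt$track_id[tt$frame == 1 & tt$row == rec$row[1] &
                           tt$col == rec$col[1]]
      truth <- tt[tt$track_id == tid, ]
      expect_identical(rec$row, truth$row)
      expect_identical(rec$col, truth$col)
    }
  }
})

test_that("MSD closed forms: stationary and ballistic tracks", {
  still <- data.frame(frame = 1:10, row = 5, col = 5)
  m <- compute_msd(still)
  expect_true(all(m$msd == 0))
  v <- 2
  ball <- data.frame(frame = 1:20, row = v * (0:19), col = 0)
  mb <- compute_msd(ball)
  expect_equal(mb$msd, v^2 * mb$lag^2, tolerance = 1e-12)
  expect_identical(mb$n_pairs, 20L - seq_len(nrow(mb)))
  expect_error(compute_msd(data.frame(frame = 1:3, row = 1:3, col = 0)),
               "at least 4")
})

test_that("MSD is invariant under time reversal", {
  set.seed(11)
  tr <- data.frame(frame = 1:30, row = cumsum(rnorm(30)), col = cumsum(rnorm(30)))
  rev_tr <- data.frame(frame = 1:30, row = rev(tr$row), col = rev(tr$col))
  expect_equal(compute_msd(tr)$msd, compute_msd(rev_tr)$msd, tolerance = 1e-12)
})

test_that("ensemble diffusive MSD matches 4 D tau", {
  tt <- simulate_tracks(track_config(mix_diffusive, seed = 15, n = 500))
  sp <- split(tt, tt$track_id)
  ratios <- vapply(sp, function(t1) {
    m <- compute_msd(t1)
    mean(m$msd[1:5] / m$lag[1:5])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 4), 0.2)
})

test_that("closed-form MSD curves recover their exponents exactly", {
  tau <- 1:10
  ball <- structure(data.frame(lag = tau, msd = 4 * tau^2, n_pairs = 50 - tau),
                    frame_interval = 1, class = c("msd_profile", "data.frame"))
  est <- classify_motion(ball)
  expect_equal(est$alpha, 2, tolerance = 1e-9)
  expect_identical(est$motion_class, "directed")
  expect_equal(est$velocity, 2, tolerance = 1e-9)
  D <- 0.7
  lin <- structure(data.frame(lag = tau, msd = 4 * D * tau, n_pairs = 50 - tau),
                   frame_interval = 1, class = c("msd_profile", "data.frame"))
  est2 <- classify_motion(lin)
  expect_equal(est2$alpha, 1, tolerance = 1e-9)
  expect_identical(est2$motion_class, "diffusive")
  expect_equal(est2$diffusion_coefficient, D, tolerance = 1e-9)
})

test_that("non-positive MSD lags are dropped; too few lags is unclassifiable", {
  tau <- 1:5
  prof <- structure(data.frame(lag = tau, msd = c(0, 8, 12, 16, 20),
                               n_pairs = 10 - tau),
                    frame_interval = 1, class = c("msd_profile", "data.frame"))
  est <- classify_motion(prof)
  expect_identical(est$motion_class, "diffusive")
  flat <- structure(data.frame(lag = 1:4, msd = c(0, 0, 1, 2), n_pairs = 4:1),
                    frame_interval = 1, class = c("msd_profile", "data.frame"))
  expect_identical(classify_motion(flat)$motion_class, "unclassifiable")
})

test_that("simulated motion classes are recovered at high accuracy", {
  dirc <- simulate_tracks(track_config(mix_directed, seed = 41, n = 50))
  diff <- simulate_tracks(track_config(mix_diffusive, seed = 42, n = 50))
  acc <- mean(c(classify_truth_tracks(dirc) == "directed",
                classify_truth_tracks(diff) == "diffusive"))
  expect_gte(acc, 0.95)
})

test_that("confined motion flattens the MSD into the confined class", {
  conf <- simulate_tracks(track_config(mix_confined, seed = 43, n = 50,
                                       n_frames = 100))
  cls <- classify_truth_tracks(conf)
  expect_gte(mean(cls == "confined"), 0.9)
})

test_that("co-transport fraction hits its degenerate endpoints", {
  cfg <- simulation_config(n_vesicles = 8, coloc_fraction = 1, seed = 51)
  sim <- simulate_field(cfg)
  rois <- rois_from_truth(sim$truth, dim(get_frame(sim$stack, "cargo")),
                          cfg$ring_thickness)
  none <- data.frame(row = numeric(0), col = numeric(0),
                     peak_intensity = numeric(0))
  nf <- 5
  rois_pf <- rep(list(rois), nf)
  # no puncta anywhere -> 0 %
  r0 <- cotransport_fraction(rois_pf, rep(list(none), nf))
  expect_identical(r0$summary$percent_positive, 0)
  # a punctum at every centroid in every frame -> 100 %
  at_ctr <- data.frame(row = rois$table$row, col = rois$table$col,
                       peak_intensity = 1)
  r1 <- cotransport_fraction(rois_pf, rep(list(at_ctr), nf))
  expect_identical(r1$summary$percent_positive, 100)
  expect_identical(r1$summary$n_objects, 8L)
  # empty ROI input -> undefined percentage, not zero
  empty <- cotransport_fraction(list(), list())
  expect_true(empty$summary$undefined)
})

test_that("co-transport recovers the realized attached fraction", {
  cfg <- simulation_config(image_height = 320, image_width = 320,
                           n_vesicles = 30, coloc_fraction = 1,
                           punctum_attach_fraction = 0.5, n_frames = 6,
                           motion_mix = mix_diffusive, seed = 53)
  sim <- simulate_timelapse(cfg)
  nf <- n_frames(sim$stack)
  rois_pf <- lapply(seq_len(nf), function(f)
    detect_vesicles(get_frame(sim$stack, "cargo", f)))
  puncta_pf <- lapply(seq_len(nf), function(f)
    detect_puncta(get_frame(sim$stack, "punctum", f)))
  res <- cotransport_fraction(rois_pf, puncta_pf, max_distance = 5)
  realized <- 100 * mean(sim$truth$vesicles$has_punctum)
  expect_false(res$summary$undefined)
  expect_lt(abs(res$summary$percent_positive - realized), 5)
})
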