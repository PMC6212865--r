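# Shared fixtures built in code; nothing is read from disk.

# Config for track-level simulations: huge sparse field so trajectories are
# effectively unbounded and per-track statistics are clean.
track_config <- function(mix, seed, n = 100, n_frames = 50, D = 1, v = 2,
                         pos_noise = 0.5) {
  simulation_config(image_height = 4000, image_width = 4000, n_vesicles = n,
                    min_separation = 2, n_frames = n_frames,
                    motion_mix = mix, speed = v, diffusion_coefficient = D,
                    position_noise_sigma = pos_noise, seed = seed)
}

mix_directed <- c(directed = 1, diffusive = 0, confined = 0)
mix_diffusive <- c(directed = 0, diffusive = 1, confined = 0)
mix_confined <- c(directed = 0, diffusive = 0, confined = 1)

# Classify every track in a truth table; returns character vector of classes.
classify_truth_tracks <- function(tracks, ...) {
  vapply(unique(tracks$track_id), function(id) {
    classify_motion(compute_msd(tracks[tracks$track_id == id, ]), ...)$motion_class
  }, character(1))
}

# Realized cargo-positive percentage computed the same way percent_positive
# computes it (100 * count / n), so exact comparisons are meaningful.
realized_percent <- function(truth) {
  100 * sum(truth$vesicles$is_cargo_positive) / nrow(truth$vesicles)
}

# A single noiseless rendered ring on flat background (uses internal renderer).
render_single_ring <- function(center = c(50, 50), radius = 6, thickness = 2,
                               size = 101, amplitude = 100, psf_sigma = 1,
                               background = 10) {
  img <- matrix(0, size, size)
  img <- vesiquant:::add_annulus(img, center[1], center[2], radius,
                                 radius - thickness, amplitude)
  vesiquant:::blur_psf(img, psf_sigma) + background
}
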