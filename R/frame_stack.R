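#' Multi-channel image stack container
#'
#' A `frame_stack` holds a time-ordered sequence of multi-channel intensity
#' grids together with its calibration metadata. Internally the data live in
#' a 4-D numeric array indexed `[row, col, channel, frame]`; intensities are
#' photons (or camera ADU) per pixel and must be non-negative.
#'
#' @param data numeric 4-D array `[row, col, channel, frame]`, or a matrix /
#'   3-D array which is promoted (a matrix becomes one channel, one frame).
#' @param channels character vector naming the channels, e.g.
#'   `c("marker", "cargo")`. Length must match `dim(data)[3]`.
#' @param frame_interval seconds between consecutive frames.
#' @param pixel_size microns per pixel, or `NA` when uncalibrated.
#'
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(data, channels, frame_interval = 1, pixel_size = NA_real_) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L) {
    stop("`data` must be a matrix or a 3-/4-D array", call. = FALSE)
  }
  if (length(channels) != dim(data)[3]) {
    stop("length(channels) must equal the channel dimension of `data`",
         call. = FALSE)
  }
  if (anyDuplicated(channels)) stop("channel names must be distinct", call. = FALSE)
  if (any(!is.finite(data))) stop("intensities must be finite", call. = FALSE)
  if (any(data < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("`frame_interval` must be a positive number of seconds", call. = FALSE)
  }
  structure(
    list(data = data, channels = as.character(channels),
         frame_interval = frame_interval, pixel_size = pixel_size),
    class = "frame_stack"
  )
}

#' Extract one channel of one frame as a plain matrix
#'
#' @param stack a [frame_stack].
#' @param channel channel name or index.
#' @param frame frame index (1-based).
#' @return A numeric matrix `[row, col]`.
#' @export
get_frame <- function(stack, channel, frame = 1L) {
  stopifnot(inherits(stack, "frame_stack"))
  if (is.character(channel)) {
    ci <- match(channel, stack$channels)
    if (is.na(ci)) {
      stop(sprintf("channel '%s' not present (have: %s)", channel,
                   paste(stack$channels, collapse = ", ")), call. = FALSE)
    }
  } else ci <- as.integer(channel)
  nf <- dim(stack$data)[4]
  if (frame < 1 || frame > nf) {
    stop(sprintf("frame %d out of range 1..%d", frame, nf), call. = FALSE)
  }
  stack$data[, , ci, frame]
}

#' @export
n_frames <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  dim(stack$data)[4]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d x %d px, %d channel(s) [%s], %d frame(s), dt = %g s\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ","), d[4],
              x$frame_interval))
  invisible(x)
}
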