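#' Grayscale image sequence with calibration
#'
#' Ordered grayscale frames (numeric matrices in [0, 1], equal shape) plus
#' spatial calibration in mm per pixel and the frame interval in seconds.
#' One cardiac cycle in echocardiography is typically 9 to 13 frames at the
#' acquisition rates this workflow targets.
#'
#' @param frames list of numeric matrices of equal shape.
#' @param mm_per_px spatial calibration, millimetres per pixel.
#' @param frame_interval time between frames, seconds.
#' @return an object of class `image_sequence`.
#' @export
image_sequence <- function(frames, mm_per_px = 1, frame_interval = 0.02) {
  stopifnot(is.list(frames), length(frames) >= 1)
  d <- dim(frames[[1]])
  ok <- vapply(frames, function(f) is.matrix(f) && all(dim(f) == d), logical(1))
  if (!all(ok)) stop("image_sequence: frames must be matrices of equal shape")
  if (mm_per_px <= 0) stop("image_sequence: mm_per_px must be positive")
  structure(list(frames = frames, mm_per_px = mm_per_px,
                 frame_interval = frame_interval),
            class = "image_sequence")
}

#' @export
print.image_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("image_sequence: %d frames of %d x %d px, %.3g mm/px, %.3g s/frame\n",
              length(x$frames), d[1], d[2], x$mm_per_px, x$frame_interval))
  invisible(x)
}

#' @export
length.image_sequence <- function(x) length(x$frames)
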