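#' A single transmission frame
#'
#' @param pixels Matrix of counts, x (horizontal) in rows, y (vertical) in
#'   columns.
#' @param angle Rotation angle theta in degrees, in [0, 360).
#' @param focal_z Focal-plane position in um relative to the volume centre.
#' @param index 0-based acquisition index; theta = (index * step) mod 360.
#' @return An object of class `tomo_frame`.
#' @export
tomo_frame <- function(pixels, angle, focal_z, index) {
  stopifnot(is.matrix(pixels))
  if (any(pixels < 0)) stop("frame pixel values must be non-negative")
  structure(list(pixels = pixels, angle = angle %% 360,
                 focal_z = focal_z, index = as.integer(index)),
            class = "tomo_frame")
}

#' @export
print.tomo_frame <- function(x, ...) {
  cat(sprintf("Frame %d: %d x %d px, theta = %g deg, focal z = %g um\n",
              x$index, nrow(x$pixels), ncol(x$pixels), x$angle, x$focal_z))
  invisible(x)
}

#' Lazy stream of frames
#'
#' A `frame_stream` produces frames one at a time via `$next_frame()`
#' (returning `NULL` when exhausted) and can be rewound with `$reset()`, so
#' full spiral acquisitions never need to be held in memory at once.
#'
#' @param next_frame Function of no arguments yielding the next `tomo_frame`
#'   or `NULL`.
#' @param reset Function rewinding the stream to its first frame.
#' @param n_frames Total number of frames.
#' @param spiral,optics Acquisition metadata, if known.
#' @return An object of class `frame_stream`.
#' @export
frame_stream <- function(next_frame, reset, n_frames,
                         spiral = NULL, optics = NULL) {
  structure(list(next_frame = next_frame, reset = reset,
                 n_frames = as.integer(n_frames),
                 spiral = spiral, optics = optics),
            class = "frame_stream")
}

#' @export
print.frame_stream <- function(x, ...) {
  cat("Frame stream of", x$n_frames, "frames\n")
  if (!is.null(x$spiral)) print(x$spiral)
  invisible(x)
}

#' Wrap a list of frames as a stream
#'
#' @param frames List of [tomo_frame()] objects.
#' @param spiral,optics Optional acquisition metadata.
#' @export
as_frame_stream <- function(frames, spiral = NULL, optics = NULL) {
  if (inherits(frames, "frame_stream")) return(frames)
  stopifnot(is.list(frames))
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  frame_stream(
    next_frame = function() {
      if (env$i >= length(frames)) return(NULL)
      env$i <- env$i + 1L
      frames[[env$i]]
    },
    reset = function() env$i <- 0L,
    n_frames = length(frames), spiral = spiral, optics = optics)
}

#' Materialize a frame stream as a list
#'
#' @param stream A [frame_stream()] or a list of frames.
#' @param n Maximum number of frames to collect.
#' @return List of `tomo_frame` objects.
#' @export
collect_frames <- function(stream, n = Inf) {
  if (is.list(stream) && !inherits(stream, "frame_stream")) return(stream)
  stream$reset()
  out <- vector("list", min(n, stream$n_frames))
  i <- 0L
  while (i < n) {
    f <- stream$next_frame()
    if (is.null(f)) break
    i <- i + 1L
    out[[i]] <- f
  }
  out[seq_len(i)]
}
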