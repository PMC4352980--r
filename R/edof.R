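#' Per-angle group of through-focus frames
#'
#' @param angle Angle in degrees shared by all frames.
#' @param frames List of [tomo_frame()]s ordered by strictly increasing
#'   focal_z.
#' @export
angle_group <- function(angle, frames) {
  stopifnot(length(frames) >= 1)
  fz <- vapply(frames, `[[`, numeric(1), "focal_z")
  if (is.unsorted(fz, strictly = length(frames) > 1))
    frames <- frames[order(fz)]
  structure(list(angle = angle %% 360, frames = frames),
            class = "angle_group")
}

#' Group a frame stream by rotation angle
#'
#' Frames are binned by `round(theta / angular_step) mod frames_per_rotation`
#' and ordered by focal position within each bin, so every group holds one
#' frame per rotation. Grouping is invariant to the order of the incoming
#' stream; completeness is checked through the acquisition indices.
#'
#' @param frames A [frame_stream()] or list of frames.
#' @param spiral The [spiral_params()] of the acquisition.
#' @return List of [angle_group()]s, ascending in angle.
#' @export
group_by_angle <- function(frames, spiral) {
  stopifnot(inherits(spiral, "spiral_params"))
  frames <- collect_frames(frames)
  n <- spiral$total_frames
  if (length(frames) != n)
    stop(sprintf("expected %d frames, got %d", n, length(frames)))
  idx <- vapply(frames, `[[`, integer(1), "index")
  missing <- setdiff(0:(n - 1), idx)
  if (length(missing))
    stop("missing frame index ", missing[1])
  if (anyDuplicated(idx))
    stop("duplicate frame index ", idx[anyDuplicated(idx)])
  fpr <- spiral$frames_per_rotation
  key <- vapply(frames, function(f)
    as.integer(round(f$angle / spiral$angular_step)) %% fpr, integer(1))
  lapply(0:(fpr - 1), function(a) {
    angle_group(a * spiral$angular_step, frames[key == a])
  })
}

#' Focus measure of an image
#'
#' Squared response of a difference-of-Gaussian high-pass filter (the image
#' minus its Gaussian blur at `hp_sigma`), smoothed with a Gaussian at
#' `smooth_sigma`. Constant images score zero everywhere; adding an offset to
#' the image leaves the map unchanged.
#'
#' @param image Numeric matrix.
#' @param hp_sigma High-pass scale in pixels.
#' @param smooth_sigma Smoothing scale in pixels.
#' @return Non-negative weight matrix of the same size.
#' @export
focus_weight <- function(image, hp_sigma = 2, smooth_sigma = 4) {
  stopifnot(is.matrix(image), hp_sigma > 0, smooth_sigma > 0)
  cpp_focus_weight(image, hp_sigma, smooth_sigma)
}

# shared accumulator core so that the batch and streaming paths are
# bit-identical: fused = (sum w*x + eps * sum x) / (sum w + n * eps),
# eps = 1e-3 * mean focus response over the whole group (1 if that is zero).
new_fuse_acc <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L; e$swx <- NULL; e$sw <- NULL; e$sx <- NULL; e$swmean <- 0
  e
}

fuse_acc_add <- function(acc, img, hp_sigma, smooth_sigma) {
  w <- cpp_focus_weight(img, hp_sigma, smooth_sigma)
  if (acc$n == 0L) {
    acc$swx <- w * img; acc$sw <- w; acc$sx <- img
  } else {
    acc$swx <- acc$swx + w * img
    acc$sw <- acc$sw + w
    acc$sx <- acc$sx + img
  }
  acc$swmean <- acc$swmean + mean(w)
  acc$n <- acc$n + 1L
  invisible(acc)
}

fuse_acc_final <- function(acc, eps = NULL) {
  mean_w <- acc$swmean / acc$n
  if (is.null(eps)) eps <- if (mean_w > 0) 1e-3 * mean_w else 1
  (acc$swx + eps * acc$sx) / (acc$sw + acc$n * eps)
}

#' Fuse a through-focus group into one extended-depth-of-field image
#'
#' Per-pixel weighted average of the group's frames with weights
#' `focus_weight + eps`. The regulariser `eps` (default `1e-3` times the
#' group-mean focus response) makes fusion fall back to the plain mean where
#' no frame carries high-frequency content.
#'
#' @param group An [angle_group()] or plain list of frames/matrices.
#' @param hp_sigma,smooth_sigma Focus-measure scales, pixels.
#' @param eps Weight floor; `NULL` for the adaptive default.
#' @return Fused matrix of the frame shape.
#' @export
fuse_group <- function(group, hp_sigma = 2, smooth_sigma = 4, eps = NULL) {
  imgs <- if (inherits(group, "angle_group")) group$frames else group
  if (length(imgs) == 0) stop("cannot fuse an empty group")
  acc <- new_fuse_acc()
  for (f in imgs) {
    img <- if (inherits(f, "tomo_frame")) f$pixels else f
    fuse_acc_add(acc, img, hp_sigma, smooth_sigma)
  }
  fuse_acc_final(acc, eps)
}

#' Set of per-angle projections
#'
#' @param projections 3D array (x, y, angle), ascending angle.
#' @param angular_step Degrees between consecutive projections.
#' @param pixel_size Pixel pitch in um.
#' @param domain One of "counts", "transmittance", "optical_depth".
#' @param reduction_factor Achieved input-frames / output-projections ratio.
#' @param fusion Parameter list used during fusion (metadata).
#' @export
projection_set <- function(projections, angular_step, pixel_size,
                           domain = c("counts", "transmittance",
                                      "optical_depth"),
                           reduction_factor = NA_real_, fusion = list()) {
  stopifnot(is.array(projections), length(dim(projections)) == 3)
  domain <- match.arg(domain)
  na <- dim(projections)[3]
  if (abs(na * angular_step - 360) > 1e-6)
    stop("projections must cover 360 degrees: n_angles * angular_step == 360")
  structure(list(projections = projections, angular_step = angular_step,
                 angles = (seq_len(na) - 1) * angular_step,
                 pixel_size = pixel_size, domain = domain,
                 reduction_factor = reduction_factor, fusion = fusion),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf("Projection set: %d angles (step %g deg), %d x %d px, %s\n",
              d[3], x$angular_step, d[1], d[2], x$domain))
  if (is.finite(x$reduction_factor))
    cat(sprintf("  data reduction factor %g\n", x$reduction_factor))
  invisible(x)
}

#' Stream a spiral acquisition into fused projections
#'
#' Consumes a frame stream, groups frames by angle and fuses each group,
#' keeping only per-angle accumulation buffers in memory (for an angle-major
#' stream, a single group at a time). If correction frames are supplied the
#' fusion operates on corrected transmittance, otherwise on raw counts.
#' The achieved data-reduction factor (input frames / output projections) is
#' recorded on the result.
#'
#' @param frames A [frame_stream()] or list of frames.
#' @param spiral The acquisition's [spiral_params()].
#' @param hp_sigma,smooth_sigma,eps Fusion parameters, see [fuse_group()].
#' @param corr Optional [correction_frames()].
#' @return A [projection_set()], bit-identical to grouping then fusing.
#' @export
stream_fuse <- function(frames, spiral, hp_sigma = 2, smooth_sigma = 4,
                        eps = NULL, corr = NULL) {
  stopifnot(inherits(spiral, "spiral_params"))
  stream <- as_frame_stream(frames)
  stream$reset()
  fpr <- spiral$frames_per_rotation
  nrot <- spiral$n_rotations
  accs <- vector("list", fpr)
  out <- NULL
  n_in <- 0L
  pixel_size <- if (!is.null(stream$optics)) stream$optics$pixel_size_sample
                else NA_real_
  repeat {
    f <- stream$next_frame()
    if (is.null(f)) break
    n_in <- n_in + 1L
    if (n_in > spiral$total_frames)
      stop(sprintf("expected %d frames, got more", spiral$total_frames))
    a <- as.integer(round(f$angle / spiral$angular_step)) %% fpr
    if (identical(accs[[a + 1]], "done"))
      stop(sprintf("more than %d frames for angle %g (duplicate index %d?)",
                   nrot, f$angle, f$index))
    img <- f$pixels
    if (!is.null(corr)) img <- correct_projection(img, corr)
    if (is.null(accs[[a + 1]])) accs[[a + 1]] <- new_fuse_acc()
    fuse_acc_add(accs[[a + 1]], img, hp_sigma, smooth_sigma)
    if (accs[[a + 1]]$n == nrot) {  # group complete: finalize and free
      fused <- fuse_acc_final(accs[[a + 1]], eps)
      if (is.null(out)) out <- array(0, c(dim(fused), fpr))
      out[, , a + 1] <- fused
      accs[[a + 1]] <- "done"
    }
  }
  if (n_in != spiral$total_frames)
    stop(sprintf("expected %d frames, got %d", spiral$total_frames, n_in))
  projection_set(out, spiral$angular_step, pixel_size,
                 domain = if (is.null(corr)) "counts" else "transmittance",
                 reduction_factor = n_in / fpr,
                 fusion = list(hp_sigma = hp_sigma,
                               smooth_sigma = smooth_sigma, eps = eps))
}
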