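#' Background-division and dark-subtraction correction
#'
#' Converts raw counts to transmittance via
#' `(raw - dark) / (background - dark)`, clipped to a tiny positive floor so
#' the subsequent log stays finite. Corrects both non-uniform illumination
#' and camera dark noise.
#'
#' @param raw Matrix of raw counts.
#' @param corr A [correction_frames()] object of matching shape.
#' @param floor_value Lower clip for the transmittance.
#' @return Transmittance matrix in (0, Inf).
#' @export
correct_projection <- function(raw, corr, floor_value = 1e-6) {
  stopifnot(inherits(corr, "correction_frames"))
  if (!identical(dim(raw), dim(corr$background)))
    stop("raw frame and correction frames have different shapes")
  tr <- (raw - corr$dark) / (corr$background - corr$dark)
  tr[tr < floor_value] <- floor_value
  tr
}

#' Transmittance to optical depth
#'
#' @param transmittance Matrix of strictly positive transmittance values.
#' @return `-log(transmittance)`, the line integral of attenuation.
#' @export
to_optical_depth <- function(transmittance) {
  if (any(transmittance <= 0))
    stop("non-positive transmittance: apply correct_projection() first")
  -log(transmittance)
}

#' One-row sinogram
#'
#' @param values Matrix (n_angles x width) of optical depth.
#' @param angles Angles in degrees, ascending, uniformly covering [0, 360).
#' @param y_row 1-based image row the sinogram was taken from.
#' @param pixel_size Detector pixel pitch in um.
#' @export
sinogram <- function(values, angles, y_row = NA_integer_, pixel_size = 1) {
  stopifnot(is.matrix(values), nrow(values) == length(angles))
  if (!all(is.finite(values))) stop("sinogram values must be finite")
  structure(list(values = values, angles = angles,
                 y_row = as.integer(y_row), pixel_size = pixel_size),
            class = "sinogram")
}

#' Reorganize projections into per-row sinograms
#'
#' @param projections A [projection_set()] in the optical-depth domain (other
#'   domains are accepted; values are passed through unchanged).
#' @param rows 1-based row indices; default all rows.
#' @return List of [sinogram()]s, one per requested row.
#' @export
build_sinograms <- function(projections, rows = NULL) {
  stopifnot(inherits(projections, "projection_set"))
  d <- dim(projections$projections)
  if (is.null(rows)) rows <- seq_len(d[2])
  lapply(rows, function(y)
    sinogram(t(projections$projections[, y, ]), projections$angles, y,
             projections$pixel_size))
}

# frequency response of the discrete ramp (Ram-Lak) kernel, optionally
# windowed; pad is the FFT length
ramp_response <- function(pad, filter = c("ramp", "shepp-logan", "hamming")) {
  filter <- match.arg(filter)
  h <- numeric(pad)
  h[1] <- 0.25
  kk <- seq(1, pad / 2, by = 2)           # odd lags of the spatial kernel
  h[1 + kk] <- -1 / (pi * kk)^2
  h[pad + 1 - kk] <- -1 / (pi * kk)^2
  H <- Re(stats::fft(h))
  u <- pmin(seq(0, pad - 1), pad - seq(0, pad - 1)) / (pad / 2)  # |f|/f_N
  w <- switch(filter,
              "ramp" = rep(1, pad),
              "shepp-logan" = ifelse(u == 0, 1, sin(pi * u / 2) / (pi * u / 2)),
              "hamming" = 0.54 + 0.46 * cos(pi * u))
  H * w
}

# ramp-filter every projection of a sinogram; returns width x n_angles matrix
filter_sinogram <- function(values, filter = "ramp") {
  na <- nrow(values); W <- ncol(values)
  pad <- 2^ceiling(log2(max(2 * W, 8)))
  H <- ramp_response(pad, filter)
  P <- matrix(0, pad, na)
  P[seq_len(W), ] <- t(values)
  Q <- Re(stats::mvfft(stats::mvfft(P) * H, inverse = TRUE)) / pad
  Q[seq_len(W), , drop = FALSE]
}

#' Filtered back-projection of one sinogram
#'
#' Ramp-filters every projection (zero-padded FFT, optional Shepp-Logan or
#' Hamming window) and back-projects with linear interpolation. The rotation
#' axis is assumed at detector coordinate `(width-1)/2 + offset_x`; the
#' returned transverse slice is width x width with the axis at its centre,
#' in 1/um after division by the pixel size.
#'
#' @param sino A [sinogram()] whose angles uniformly cover [0, 360).
#' @param offset_x Axis offset in pixels (sub-pixel allowed).
#' @param filter "ramp", "shepp-logan" or "hamming".
#' @return Matrix (x, z) of attenuation coefficients, 1/um.
#' @export
fbp_slice <- function(sino, offset_x = 0, filter = "ramp") {
  stopifnot(inherits(sino, "sinogram"))
  check_uniform_angles(sino$angles)
  W <- ncol(sino$values)
  q <- filter_sinogram(sino$values, filter)
  bp <- cpp_backproject(q, sino$angles, (W - 1) / 2 + offset_x, W)
  bp * pi / length(sino$angles) / sino$pixel_size
}

check_uniform_angles <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least two projection angles")
  steps <- diff(angles)
  if (max(abs(steps - steps[1])) > 1e-6)
    stop("angles must be uniformly spaced")
  span <- n * steps[1]
  if (abs(span - 360) > 1e-6 && abs(span - 180) > 1e-6)
    stop("angles must uniformly cover [0, 360) or a 180-degree half-turn")
  invisible(steps[1])
}

#' Rotation-axis estimate
#'
#' @param offset_x Sub-pixel axis offset in pixels.
#' @param metric_curve Data frame of candidate offsets and mean reconstruction
#'   variance.
#' @param rows_used Image rows used for the search.
#' @export
axis_estimate <- function(offset_x, metric_curve, rows_used) {
  structure(list(offset_x = offset_x, metric_curve = metric_curve,
                 rows_used = rows_used),
            class = "axis_estimate")
}

#' @export
print.axis_estimate <- function(x, ...) {
  cat(sprintf("Rotation axis offset: %.3f px (searched %g..%g px, %d row%s)\n",
              x$offset_x, min(x$metric_curve$offset),
              max(x$metric_curve$offset), length(x$rows_used),
              if (length(x$rows_used) > 1) "s" else ""))
  invisible(x)
}

#' Find the rotation axis by reconstruction-variance maximization
#'
#' A series of slices is reconstructed with differently assumed x positions
#' of the rotation axis; the reconstruction with the maximum image variance
#' is the least blurred, so its assumed position is taken as the axis. The
#' discrete maximum is refined to sub-pixel precision by parabolic
#' interpolation through its two neighbours.
#'
#' @param sinos List of [sinogram()]s (a small sample of rows suffices).
#' @param search_range Half-width of the scanned offset interval, pixels.
#' @param search_step Scan step, pixels.
#' @param filter Reconstruction filter, see [fbp_slice()].
#' @return An [axis_estimate()].
#' @export
estimate_axis <- function(sinos, search_range = 20, search_step = 1,
                          filter = "ramp") {
  if (inherits(sinos, "sinogram")) sinos <- list(sinos)
  stopifnot(length(sinos) >= 1)
  offsets <- seq(-search_range, search_range, by = search_step)
  W <- ncol(sinos[[1]]$values)
  filtered <- lapply(sinos, function(s) {
    check_uniform_angles(s$angles)
    filter_sinogram(s$values, filter)
  })
  angles <- sinos[[1]]$angles
  metric <- vapply(offsets, function(off) {
    v <- vapply(seq_along(filtered), function(i) {
      bp <- cpp_backproject(filtered[[i]], angles, (W - 1) / 2 + off, W)
      var(as.vector(bp))
    }, numeric(1))
    mean(v)
  }, numeric(1))
  imax <- which.max(metric)
  if (imax == 1L || imax == length(offsets))
    stop("variance maximum on the boundary of the search range; ",
         "widen search_range")
  # parabolic sub-pixel refinement
  y1 <- metric[imax - 1]; y2 <- metric[imax]; y3 <- metric[imax + 1]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > 0) 0.5 * (y1 - y3) / denom else 0
  delta <- max(-1, min(1, delta))
  axis_estimate(offsets[imax] + delta * search_step,
                data.frame(offset = offsets, variance = metric),
                vapply(sinos, `[[`, integer(1), "y_row"))
}

# pick content-bearing rows for the axis search: evenly spaced among rows
# whose projections carry signal
axis_sample_rows <- function(od, n_rows = 5) {
  ny <- dim(od)[2]
  energy <- apply(abs(od), 2, max)
  good <- which(energy > 0.05 * max(energy))
  if (!length(good)) good <- seq_len(ny)
  good[unique(pmax(1, round(seq(1, length(good), length.out = n_rows))))]
}

#' Reconstruct a 3D volume from projections
#'
#' Full tomographic inversion: optional flat-field correction, log
#' conversion to optical depth, per-row sinogram assembly, automatic
#' rotation-axis estimation and slice-by-slice filtered back-projection.
#' The result has isotropic voxels of the projection pixel size.
#'
#' @param projections A [projection_set()] (counts, transmittance or optical
#'   depth; earlier stages are applied as needed).
#' @param corr [correction_frames()], required when the projections are raw
#'   counts.
#' @param axis "auto" for variance-based estimation, a number (pixels), or an
#'   [axis_estimate()].
#' @param filter Reconstruction filter, see [fbp_slice()].
#' @param log_transform If `FALSE`, reconstruct corrected intensity directly
#'   instead of optical depth (comparison mode).
#' @param axis_rows Number of rows sampled by the automatic axis search.
#' @param search_range Axis search half-range in pixels.
#' @return A [tomo_volume()] (x, y, z) in 1/um, with the axis estimate
#'   attached as attribute `"axis_estimate"`.
#' @export
reconstruct_volume <- function(projections, corr = NULL, axis = "auto",
                               filter = "ramp", log_transform = TRUE,
                               axis_rows = 5, search_range = 20) {
  stopifnot(inherits(projections, "projection_set"))
  proj <- projections$projections
  domain <- projections$domain
  if (domain == "counts") {
    if (is.null(corr))
      stop("projections are raw counts: correction frames are required")
    for (k in seq_len(dim(proj)[3]))
      proj[, , k] <- correct_projection(proj[, , k], corr)
    domain <- "transmittance"
  }
  if (domain == "transmittance") {
    proj <- if (log_transform) -log(pmax(proj, 1e-6)) else proj
  }
  d <- dim(proj)
  W <- d[1]; ny <- d[2]
  ps <- projection_set(proj, projections$angular_step,
                       projections$pixel_size, domain = "optical_depth")
  est <- NULL
  if (identical(axis, "auto")) {
    rows <- axis_sample_rows(proj, axis_rows)
    est <- estimate_axis(build_sinograms(ps, rows),
                         search_range = search_range, filter = filter)
    offset <- est$offset_x
  } else if (inherits(axis, "axis_estimate")) {
    est <- axis
    offset <- axis$offset_x
  } else {
    offset <- as.numeric(axis)
  }
  vox <- array(0, c(W, ny, W))
  for (y in seq_len(ny)) {
    row <- t(proj[, y, ])
    if (max(abs(row)) == 0) next
    sl <- fbp_slice(sinogram(row, ps$angles, y, ps$pixel_size),
                    offset_x = offset, filter = filter)
    vox[, y, ] <- sl
  }
  out <- tomo_volume(vox, projections$pixel_size,
                     if (log_transform) "1/um" else "intensity")
  attr(out, "axis_estimate") <- est
  out
}
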