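#' 3D scalar volume with isotropic voxels
#'
#' Thin container for a 3D array of attenuation (1/um) or fluorescence (a.u.)
#' values. Axes follow the camera convention: x = horizontal, y = vertical
#' (the rotation axis), z = detection axis; transverse slices are (x,z)
#' planes at fixed y. Voxel i (0-based) is centred at
#' (i - (n-1)/2) * voxel_size um from the volume centre.
#'
#' @param voxels 3D numeric array.
#' @param voxel_size Isotropic voxel pitch in um.
#' @param unit Free-text value unit (e.g. "1/um").
#' @return An object of class `tomo_volume`.
#' @export
tomo_volume <- function(voxels, voxel_size, unit = "") {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3, voxel_size > 0)
  if (!all(is.finite(voxels))) stop("volume values must be finite")
  structure(list(voxels = voxels, voxel_size = voxel_size, unit = unit),
            class = "tomo_volume")
}

#' @export
dim.tomo_volume <- function(x) dim(x$voxels)

#' @export
print.tomo_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("Volume %d x %d x %d voxels at %g um (%s)\n",
              d[1], d[2], d[3], x$voxel_size,
              if (nzchar(x$unit)) x$unit else "unitless"))
  cat(sprintf("  range [%.4g, %.4g], extent %g x %g x %g um\n",
              min(x$voxels), max(x$voxels),
              d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size))
  invisible(x)
}

#' Display a section of a volume
#'
#' @param x A [tomo_volume()].
#' @param y Row index (1-based) of the transverse (x,z) section; defaults to
#'   the middle row.
#' @param ... Passed to [graphics::image()].
#' @export
plot.tomo_volume <- function(x, y = NULL, ...) {
  d <- dim(x$voxels)
  if (is.null(y)) y <- ceiling(d[2] / 2)
  sl <- x$voxels[, y, ]
  graphics::image(seq_len(d[1]) * x$voxel_size, seq_len(d[3]) * x$voxel_size,
                  sl, xlab = "x [um]", ylab = "z [um]", useRaster = TRUE,
                  col = grDevices::gray.colors(256, 0, 1),
                  main = sprintf("transverse section y = %d", y), ...)
  invisible(x)
}

# um coordinates (relative to the volume centre) of voxel centres along one axis
axis_coords <- function(n, voxel_size) (seq_len(n) - 1 - (n - 1) / 2) * voxel_size

#' Voxelize a phantom into attenuation and fluorescence volumes
#'
#' Each voxel takes the sum over primitives covering its centre; overlapping
#' primitives add. Both returned volumes share the grid.
#'
#' @param spec A [phantom_spec()].
#' @param voxel_size Voxel pitch in um.
#' @return List with `tomo_volume` elements `attenuation` and `fluorescence`.
#' @export
make_phantom <- function(spec, voxel_size) {
  stopifnot(inherits(spec, "phantom_spec"), voxel_size > 0)
  n <- pmax(1L, as.integer(round(spec$extent / voxel_size)))
  att <- array(0, n)
  fluo <- array(0, n)
  # voxel centres in extent coordinates: (i + 0.5) * voxel_size, i 0-based
  cx <- (seq_len(n[1]) - 0.5) * voxel_size
  cy <- (seq_len(n[2]) - 0.5) * voxel_size
  cz <- (seq_len(n[3]) - 0.5) * voxel_size
  for (p in spec$primitives) {
    ix <- which(abs(cx - p$center[1]) <= p$semi_axes[1])
    iy <- which(abs(cy - p$center[2]) <= p$semi_axes[2])
    iz <- which(abs(cz - p$center[3]) <= p$semi_axes[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    ux <- ((cx[ix] - p$center[1]) / p$semi_axes[1])^2
    uy <- ((cy[iy] - p$center[2]) / p$semi_axes[2])^2
    uz <- ((cz[iz] - p$center[3]) / p$semi_axes[3])^2
    inside <- outer(outer(ux, uy, `+`), uz, `+`) <= 1
    if (p$attenuation > 0)
      att[ix, iy, iz] <- att[ix, iy, iz] + p$attenuation * inside
    if (p$fluorescence > 0)
      fluo[ix, iy, iz] <- fluo[ix, iy, iz] + p$fluorescence * inside
  }
  list(attenuation = tomo_volume(att, voxel_size, "1/um"),
       fluorescence = tomo_volume(fluo, voxel_size, "a.u."))
}
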