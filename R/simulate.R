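#' Parallel-beam projection of an attenuation volume
#'
#' Rotates the volume by `theta` about the y axis through the (possibly
#' offset) rotation axis and integrates along the detection axis z. The
#' result is the dimensionless optical depth seen by each camera pixel under
#' ideal all-in-focus optics.
#'
#' @param attenuation A [tomo_volume()] of attenuation coefficients (1/um).
#' @param theta Rotation angle in degrees (counter-clockwise viewed from
#'   above, i.e. from +y).
#' @param axis_offset_x Rotation-axis offset from the detector centre column,
#'   in pixels.
#' @return Matrix (x, y) of line integrals.
#' @export
project_attenuation <- function(attenuation, theta, axis_offset_x = 0) {
  stopifnot(inherits(attenuation, "tomo_volume"))
  d <- dim(attenuation$voxels)
  cx <- (d[1] - 1) / 2 + axis_offset_x
  cz <- (d[3] - 1) / 2
  p <- cpp_slab_project(attenuation$voxels, theta, cx, cz,
                        attenuation$voxel_size, c(0, d[3]))
  matrix(p, d[1], d[2])
}

# focal positions (um) for every frame of a spiral
spiral_focal_z <- function(spiral) {
  n <- spiral$total_frames
  if (n == 1) return(spiral$z_start)
  spiral$z_start + (0:(n - 1)) * (spiral$z_end - spiral$z_start) / (n - 1)
}

# z-slab partition of a volume for the defocus forward model
slab_partition <- function(nz, voxel_size, optics) {
  if (optics$sigma0 <= 0 || is.infinite(optics$depth_of_field)) {
    # blur is z-independent (or off): a single slab is exact by linearity
    edges <- c(0, nz)
  } else {
    t_vox <- (optics$depth_of_field / 2) / voxel_size  # Nyquist wrt blur scale
    ns <- max(1L, as.integer(ceiling(nz / t_vox)))
    edges <- (0:ns) * t_vox
  }
  centers_vox <- (edges[-length(edges)] + pmin(edges[-1], nz)) / 2
  list(edges = edges, centers_um = (centers_vox - (nz - 1) / 2) * voxel_size)
}

#' Simulate a spiral bright-field acquisition
#'
#' Emits `n_rotations * frames_per_rotation` frames; frame i carries
#' `theta = (i * angular_step) mod 360` and a focal position interpolated
#' linearly between `z_start` and `z_end`. Images are formed by slicing the
#' rotated volume into z slabs of thickness `depth_of_field / 2`, projecting
#' each slab, blurring it with an isotropic Gaussian of width
#' `sigma0 * max(1, |d| / depth_of_field)` pixels (d = slab distance from
#' focus), summing the blurred optical depths, and converting to counts via
#' Beer-Lambert plus Gaussian read noise.
#'
#' Frames are generated lazily in angle-major order (all rotations of angle
#' 0, then angle 1, ...) so only one angle group is in memory; the
#' acquisition index stored with each frame preserves the true spiral order.
#'
#' @param attenuation A [tomo_volume()] in 1/um.
#' @param optics An [optics_params()].
#' @param spiral A [spiral_params()].
#' @param seed Integer seed for the read noise (frame content is
#'   deterministic given the seed).
#' @param vignette_field Optional matrix (same size as a frame) multiplying
#'   the illumination, to emulate non-uniform backlight.
#' @return A [frame_stream()]; use [collect_frames()] to materialize small
#'   acquisitions.
#' @export
simulate_spiral <- function(attenuation, optics, spiral, seed = 1,
                            vignette_field = NULL) {
  stopifnot(inherits(attenuation, "tomo_volume"),
            inherits(optics, "optics_params"),
            inherits(spiral, "spiral_params"))
  d <- dim(attenuation$voxels)
  vs <- attenuation$voxel_size
  half_z <- d[3] * vs / 2
  if (max(spiral$z_start, spiral$z_end) < -half_z ||
      min(spiral$z_start, spiral$z_end) > half_z)
    warning("focal z-range does not cover any part of the volume")
  if (!is.null(vignette_field))
    stopifnot(identical(dim(vignette_field), d[1:2]))

  cx <- (d[1] - 1) / 2 + spiral$axis_offset_x
  cz <- (d[3] - 1) / 2
  # radial bound of non-zero content about the axis lets the projector skip
  # provably empty pixels (exact, see cpp_slab_project)
  nzmask <- attenuation$voxels != 0
  nzx <- which(apply(nzmask, 1, any)) - 1
  nzz <- which(apply(nzmask, 3, any)) - 1
  rm(nzmask)
  r_max <- if (!length(nzx)) 1e-6 else
    sqrt(max(outer((range(nzx) - cx)^2, (range(nzz) - cz)^2, `+`))) + 2
  slabs <- slab_partition(d[3], vs, optics)
  focal <- spiral_focal_z(spiral)
  fpr <- spiral$frames_per_rotation
  nrot <- spiral$n_rotations

  # independent per-angle noise substreams, drawn once so that the stream is
  # reproducible regardless of how it is consumed
  angle_seeds <- with_preserved_rng(seed, sample.int(2147483646L, fpr))

  env <- new.env(parent = emptyenv())
  env$a <- 0L      # next angle index to generate
  env$buf <- NULL  # counts for current angle, (nx, ny, nrot)
  env$r <- 0L

  span <- optics$background_level - optics$dark_level
  gain <- if (is.null(vignette_field)) 1 else as.vector(vignette_field)

  gen_angle <- function(a) {
    theta <- a * spiral$angular_step
    idx <- a + fpr * (0:(nrot - 1))
    sp <- cpp_slab_project(attenuation$voxels, theta, cx, cz, vs,
                           slabs$edges, r_max)
    od <- cpp_form_frames(sp, slabs$centers_um, focal[idx + 1],
                          optics$sigma0, optics$depth_of_field)
    counts <- optics$dark_level + span * gain * exp(-od)
    if (optics$noise_sd > 0) {
      noise <- with_preserved_rng(angle_seeds[a + 1],
                                  rnorm(length(counts), 0, optics$noise_sd))
      counts <- counts + noise
    }
    counts[counts < 0] <- 0
    array(counts, dim(od))
  }

  nxt <- function() {
    if (env$r == 0L) {
      if (env$a >= fpr) return(NULL)
      env$buf <- gen_angle(env$a)
      env$a <- env$a + 1L
      env$r <- 1L
    }
    a <- env$a - 1L
    r <- env$r - 1L
    i <- a + fpr * r
    f <- tomo_frame(env$buf[, , env$r, drop = TRUE],
                    angle = a * spiral$angular_step,
                    focal_z = focal[i + 1], index = i)
    env$r <- if (env$r >= nrot) 0L else env$r + 1L
    f
  }
  frame_stream(next_frame = nxt,
               reset = function() { env$a <- 0L; env$r <- 0L; env$buf <- NULL },
               n_frames = spiral$total_frames, spiral = spiral, optics = optics)
}

# run expr under a private RNG state, restoring the caller's afterwards
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  res <- expr
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  res
}

#' Flat-field and dark correction frames
#'
#' @param background Counts with illumination on and no sample.
#' @param dark Counts with illumination off.
#' @return An object of class `correction_frames`.
#' @export
correction_frames <- function(background, dark) {
  stopifnot(is.matrix(background), is.matrix(dark),
            identical(dim(background), dim(dark)))
  if (!all(background > dark))
    stop("background must exceed dark pixelwise")
  structure(list(background = background, dark = dark),
            class = "correction_frames")
}

#' Simulate correction frames for an acquisition
#'
#' @param optics An [optics_params()].
#' @param dims Frame dimensions c(nx, ny).
#' @param vignette_field Optional illumination field, as in
#'   [simulate_spiral()].
#' @param seed Seed for the read noise; `NULL` for noise-free frames.
#' @return A [correction_frames()] object.
#' @export
simulate_correction_frames <- function(optics, dims, vignette_field = NULL,
                                       seed = NULL) {
  span <- optics$background_level - optics$dark_level
  gain <- if (is.null(vignette_field)) 1 else vignette_field
  bg <- matrix(optics$dark_level + span * gain, dims[1], dims[2])
  dk <- matrix(optics$dark_level, dims[1], dims[2])
  if (!is.null(seed) && optics$noise_sd > 0) {
    nse <- with_preserved_rng(seed, rnorm(2 * prod(dims), 0, optics$noise_sd))
    bg <- bg + matrix(nse[seq_len(prod(dims))], dims[1], dims[2])
    dk <- dk + matrix(nse[-seq_len(prod(dims))], dims[1], dims[2])
    # keep the pixelwise invariant intact under noise
    bad <- bg <= dk
    bg[bad] <- dk[bad] + 1e-6
  }
  correction_frames(bg, dk)
}

#' Fluorescence SPIM stack container
#'
#' @param slices 3D array (x, y, slice index along the stack z).
#' @param z_spacing Slice spacing in um.
#' @param angle View angle in degrees.
#' @param pixel_size Lateral pixel pitch in um.
#' @export
spim_stack <- function(slices, z_spacing, angle, pixel_size) {
  stopifnot(is.array(slices), length(dim(slices)) == 3, z_spacing > 0,
            pixel_size > 0)
  structure(list(slices = slices, z_spacing = z_spacing,
                 angle = angle %% 360, pixel_size = pixel_size),
            class = "spim_stack")
}

#' @export
print.spim_stack <- function(x, ...) {
  d <- dim(x$slices)
  cat(sprintf("SPIM stack %d x %d px x %d slices at %g um, view %g deg\n",
              d[1], d[2], d[3], x$z_spacing, x$angle))
  invisible(x)
}

#' Simulate a fluorescence SPIM stack of a rotated specimen
#'
#' Optical sections of the fluorescence volume rotated to the given view,
#' boxcar-integrated axially over the slice thickness and blurred laterally
#' with `sigma0` pixels. The rotation axis sits at stack coordinate
#' `(n_slices-1)/2 + axis_z_offset / z_spacing`: `axis_z_offset` is the
#' unknown that multimodal registration must recover.
#'
#' @param fluorescence A [tomo_volume()] of fluorophore density.
#' @param theta View angle in degrees.
#' @param z_spacing Slice spacing in um (typically 2).
#' @param axis_z_offset Offset of the stack origin from the rotation axis, um.
#' @param sigma0 Lateral blur in pixels.
#' @param n_slices Number of slices; defaults to covering the volume.
#' @return A [spim_stack()].
#' @export
simulate_spim_stack <- function(fluorescence, theta, z_spacing = 2,
                                axis_z_offset = 0, sigma0 = 1,
                                n_slices = NULL) {
  stopifnot(inherits(fluorescence, "tomo_volume"), z_spacing > 0)
  d <- dim(fluorescence$voxels)
  vs <- fluorescence$voxel_size
  rot <- cpp_rotate_y(fluorescence$voxels, theta,
                      (d[1] - 1) / 2, (d[3] - 1) / 2)
  rot <- array(rot, d)
  if (is.null(n_slices))
    n_slices <- as.integer(ceiling(d[3] * vs / z_spacing)) + 1L
  m <- max(1L, as.integer(round(z_spacing / vs)))  # axial boxcar sub-samples
  sub <- ((seq_len(m)) - (m + 1) / 2) / m * z_spacing
  slices <- array(0, c(d[1], d[2], n_slices))
  for (k in seq_len(n_slices)) {
    z_phys <- ((k - 1) - (n_slices - 1) / 2) * z_spacing - axis_z_offset
    acc <- matrix(0, d[1], d[2])
    for (s in sub) {
      zi <- (z_phys + s) / vs + (d[3] - 1) / 2
      z0 <- floor(zi)
      fz <- zi - z0
      if (z0 >= 0 && z0 <= d[3] - 1) acc <- acc + (1 - fz) * rot[, , z0 + 1]
      if (z0 + 1 >= 0 && z0 + 1 <= d[3] - 1) acc <- acc + fz * rot[, , z0 + 2]
    }
    acc <- acc / m
    if (sigma0 > 0) acc <- cpp_gauss_blur2d(acc, sigma0)
    slices[, , k] <- acc
  }
  spim_stack(slices, z_spacing, theta, vs)
}
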