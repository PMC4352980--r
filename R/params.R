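#' Detection optics and camera parameters
#'
#' Bundles the optical and camera constants of the bright-field detection
#' path. Defaults describe a 10x/0.3 water-dipping detection lens with a red
#' LED backlight and an sCMOS camera: depth of field about 15 um, sample-side
#' pixel pitch of a few um.
#'
#' @param numerical_aperture Detection NA, in (0, 1].
#' @param wavelength Illumination wavelength in um.
#' @param refractive_index Immersion medium index (water by default).
#' @param depth_of_field Depth of field delta-z in um. Blur grows linearly
#'   once a structure is further than this from the focal plane.
#' @param pixel_size_sample Sample-side pixel pitch in um/pixel (camera pixel
#'   divided by magnification).
#' @param background_level Full-illumination counts (no sample).
#' @param dark_level Camera counts with illumination off.
#' @param noise_sd Additive Gaussian read-noise sigma in counts.
#' @param sigma0 In-focus blur sigma in pixels; 0 disables blur entirely
#'   (ideal all-in-focus optics).
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(numerical_aperture = 0.3,
                          wavelength = 0.63,
                          refractive_index = 1.33,
                          depth_of_field = 15,
                          pixel_size_sample = 2.5,
                          background_level = 3000,
                          dark_level = 100,
                          noise_sd = 20,
                          sigma0 = 1) {
  stopifnot(numerical_aperture > 0, numerical_aperture <= 1,
            wavelength > 0, refractive_index >= 1,
            depth_of_field > 0, pixel_size_sample > 0,
            noise_sd >= 0, sigma0 >= 0)
  if (!(background_level > dark_level) || dark_level < 0)
    stop("optics require background_level > dark_level >= 0")
  structure(list(numerical_aperture = numerical_aperture,
                 wavelength = wavelength,
                 refractive_index = refractive_index,
                 depth_of_field = depth_of_field,
                 pixel_size_sample = pixel_size_sample,
                 background_level = background_level,
                 dark_level = dark_level,
                 noise_sd = noise_sd,
                 sigma0 = sigma0),
            class = "optics_params")
}

#' @export
print.optics_params <- function(x, ...) {
  cat("Detection optics: NA", x$numerical_aperture,
      " depth of field", x$depth_of_field, "um\n")
  cat("  pixel", x$pixel_size_sample, "um/px; counts bg/dark",
      x$background_level, "/", x$dark_level,
      "; noise sd", x$noise_sd, "; sigma0", x$sigma0, "px\n")
  invisible(x)
}

#' Spiral acquisition trajectory parameters
#'
#' The sample rotates continuously while being translated through the focal
#' plane, so each angle is revisited once per rotation at a different focal
#' depth. The default trajectory is 20 rotations at 1 degree per frame while
#' the focus travels 500 um, i.e. 7200 frames.
#'
#' @param n_rotations Number of complete rotations.
#' @param angular_step Angle between consecutive frames, degrees; must divide
#'   360 evenly.
#' @param z_start,z_end Focal-plane travel in um, relative to the volume
#'   centre (monotone from start to end).
#' @param axis_offset_x Lateral miscentering of the rotation axis in pixels.
#' @param frame_rate Acquisition frame rate in Hz (metadata only).
#' @return An object of class `spiral_params`.
#' @export
spiral_params <- function(n_rotations = 20, angular_step = 1,
                          z_start = -250, z_end = 250,
                          axis_offset_x = 0, frame_rate = 60) {
  stopifnot(n_rotations >= 1, angular_step > 0)
  fpr <- 360 / angular_step
  if (abs(fpr - round(fpr)) > 1e-9)
    stop("angular_step must divide 360 evenly")
  fpr <- as.integer(round(fpr))
  structure(list(n_rotations = as.integer(n_rotations),
                 angular_step = angular_step,
                 frames_per_rotation = fpr,
                 total_frames = as.integer(n_rotations) * fpr,
                 z_start = z_start, z_end = z_end,
                 axis_offset_x = axis_offset_x,
                 frame_rate = frame_rate),
            class = "spiral_params")
}

#' @export
print.spiral_params <- function(x, ...) {
  cat("Spiral acquisition:", x$n_rotations, "rotations x",
      x$frames_per_rotation, "angles (step", x$angular_step, "deg) =",
      x$total_frames, "frames\n")
  cat("  focal travel", x$z_start, "->", x$z_end, "um; axis offset",
      x$axis_offset_x, "px\n")
  invisible(x)
}

#' Geometric phantom primitives
#'
#' Spheres and ellipsoids with attenuation (1/um) and fluorescence (a.u.)
#' values, combined additively into a ground-truth specimen by
#' [make_phantom()]. Centres and semi-axes are in um within the phantom
#' extent, whose origin is the lower corner.
#'
#' @param center Numeric length-3 centre (x, y, z) in um.
#' @param radius Sphere radius in um.
#' @param semi_axes Numeric length-3 ellipsoid semi-axes in um.
#' @param attenuation Attenuation coefficient in 1/um (>= 0).
#' @param fluorescence Fluorophore density in arbitrary units (>= 0).
#' @param label Free-text label.
#' @return A `phantom_primitive`.
#' @export
primitive_sphere <- function(center, radius, attenuation = 0,
                             fluorescence = 0, label = "sphere") {
  primitive_ellipsoid(center, rep(radius, 3), attenuation, fluorescence, label)
}

#' @rdname primitive_sphere
#' @export
primitive_ellipsoid <- function(center, semi_axes, attenuation = 0,
                                fluorescence = 0, label = "ellipsoid") {
  stopifnot(length(center) == 3, length(semi_axes) == 3,
            all(semi_axes > 0), attenuation >= 0, fluorescence >= 0)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 attenuation = attenuation, fluorescence = fluorescence,
                 label = label),
            class = "phantom_primitive")
}

#' Specimen description for the simulator
#'
#' @param primitives List of [primitive_sphere()] / [primitive_ellipsoid()]
#'   objects. Overlapping primitives add.
#' @param extent Length-3 phantom extent (x, y, z) in um.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(primitives, extent) {
  stopifnot(length(extent) == 3, all(extent > 0))
  if (!is.list(primitives)) stop("primitives must be a list")
  for (p in primitives) {
    if (!inherits(p, "phantom_primitive"))
      stop("all primitives must be phantom_primitive objects")
    if (any(p$center - p$semi_axes < 0) || any(p$center + p$semi_axes > extent))
      stop(sprintf("primitive '%s' does not fit inside the extent", p$label))
  }
  structure(list(primitives = primitives, extent = as.numeric(extent)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom:", length(x$primitives), "primitive(s) in extent",
      paste(x$extent, collapse = " x "), "um\n")
  for (p in x$primitives)
    cat(sprintf("  %-12s centre (%s) um, semi-axes (%s) um, mu=%g/um, fluo=%g\n",
                p$label, paste(p$center, collapse = ", "),
                paste(p$semi_axes, collapse = ", "),
                p$attenuation, p$fluorescence))
  invisible(x)
}

#' A two-sphere "eyes plus body" demonstration phantom
#'
#' Two strongly attenuating spheres (eye-lens-like landmarks, also
#' fluorescent) inside a weakly attenuating body ellipsoid whose centroid is
#' offset dorsally from the eye midpoint, mimicking the head of a translucent
#' embryo at desk scale.
#'
#' @param extent Length-3 extent in um.
#' @return A [phantom_spec()].
#' @export
example_phantom <- function(extent = c(400, 400, 400)) {
  e <- extent
  mid <- e / 2
  eye_dx <- 0.16 * e[1]
  eye_y <- mid[2] - 0.08 * e[2]
  phantom_spec(list(
    primitive_ellipsoid(c(mid[1], mid[2] + 0.05 * e[2], mid[3]),
                        c(0.30 * e[1], 0.36 * e[2], 0.26 * e[3]),
                        attenuation = 0.003, label = "body"),
    primitive_sphere(c(mid[1] - eye_dx, eye_y, mid[3]), 0.09 * e[1],
                     attenuation = 0.012, fluorescence = 1, label = "eye_left"),
    primitive_sphere(c(mid[1] + eye_dx, eye_y, mid[3]), 0.09 * e[1],
                     attenuation = 0.012, fluorescence = 1, label = "eye_right"),
    primitive_ellipsoid(c(mid[1], mid[2] + 0.12 * e[2], mid[3]),
                        c(0.10 * e[1], 0.16 * e[2], 0.08 * e[3]),
                        attenuation = 0.002, fluorescence = 2,
                        label = "vessel")),
    extent = e)
}
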