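# Shared fixtures: all phantoms and acquisitions are generated in code.

# ideal optics: no read noise, no blur -- makes the simulator an exact
# Beer-Lambert line-integral camera
ideal_optics <- function(pixel_size = 2, ...) {
  optics_params(noise_sd = 0, sigma0 = 0, depth_of_field = Inf,
                pixel_size_sample = pixel_size, ...)
}

# single-turn trajectory at fixed focus (no spiral travel)
flat_spiral <- function(angular_step = 3, ...) {
  spiral_params(n_rotations = 1, angular_step = angular_step,
                z_start = 0, z_end = 0, ...)
}

two_sphere_phantom <- function(extent = c(200, 200, 200)) {
  phantom_spec(list(
    primitive_sphere(c(0.35, 0.5, 0.5) * extent, 0.125 * extent[1],
                     attenuation = 0.01, fluorescence = 1, label = "a"),
    primitive_sphere(c(0.675, 0.45, 0.6) * extent, 0.09 * extent[1],
                     attenuation = 0.015, fluorescence = 2, label = "b")),
    extent = extent)
}

# counts -> optical depth for a whole projection set (ideal correction)
od_projection_set <- function(ps, optics) {
  od <- -log(pmax((ps$projections - optics$dark_level) /
                    (optics$background_level - optics$dark_level), 1e-9))
  projection_set(od, ps$angular_step, optics$pixel_size_sample,
                 domain = "optical_depth")
}

# simulate an ideal acquisition and return optical-depth projections
simulate_od_projections <- function(attenuation, spiral, optics, seed = 1) {
  st <- simulate_spiral(attenuation, optics, spiral, seed = seed)
  od_projection_set(stream_fuse(collect_frames(st), spiral), optics)
}

# analytic chord-length sinogram of a centred uniform disk
disk_sinogram <- function(width, radius, mu, angles, pixel_size = 1,
                          center_offset = 0) {
  xs <- (0:(width - 1)) - (width - 1) / 2 - center_offset
  t(vapply(angles, function(a)
    2 * mu * sqrt(pmax(radius^2 - xs^2, 0)), numeric(width)))
}

sidecar_path_for_test <- function(p) sub("\\.tif$", ".json", p)

# intensity centroid of an array, 1-based voxel coordinates
array_centroid <- function(a) {
  d <- dim(a)
  w <- a / sum(a)
  c(sum(apply(w, 1, sum) * seq_len(d[1])),
    sum(apply(w, 2, sum) * seq_len(d[2])),
    sum(apply(w, 3, sum) * seq_len(d[3])))
}
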