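test_that("flat-field correction inverts the camera model", {
  bg <- matrix(3000, 16, 16)
  dk <- matrix(100, 16, 16)
  corr <- correction_frames(bg, dk)
  expect_equal(correct_projection(bg, corr), matrix(1, 16, 16))
  # fully opaque pixels clip to a tiny positive transmittance
  tr <- correct_projection(dk, corr)
  expect_true(all(tr > 0) && all(tr <= 1e-6))
  expect_error(correct_projection(matrix(0, 8, 8), corr), "shapes")
  # a vignetted acquisition flattens out after correction
  ph <- make_phantom(two_sphere_phantom(c(64, 64, 64)), 2)
  opt <- ideal_optics()
  vg <- outer(seq(0.6, 1, length.out = 32), seq(0.7, 1, length.out = 32))
  fr <- collect_frames(simulate_spiral(ph$attenuation, opt,
                                       flat_spiral(angular_step = 180),
                                       seed = 1, vignette_field = vg))
  cf <- simulate_correction_frames(opt, c(32, 32), vignette_field = vg)
  od <- to_optical_depth(correct_projection(fr[[1]]$pixels, cf))
  expect_lt(max(abs(od - project_attenuation(ph$attenuation, 0))), 1e-6)
})

test_that("optical depth conversion is the negative log", {
  expect_equal(to_optical_depth(matrix(1, 2, 2)), matrix(0, 2, 2))
  expect_equal(to_optical_depth(matrix(exp(-1), 2, 2)), matrix(1, 2, 2))
  expect_error(to_optical_depth(matrix(c(1, 0), 1, 2)), "non-positive")
})

test_that("sinograms encode the circular trajectory of features", {
  opt <- ideal_optics()
  # a centred feature gives a constant sinogram column
  spec <- phantom_spec(list(primitive_sphere(c(64, 64, 64), 8,
                                             attenuation = 0.02)),
                       extent = c(128, 128, 128))
  ph <- make_phantom(spec, 2)
  ps <- simulate_od_projections(ph$attenuation, flat_spiral(15), opt)
  sinos <- build_sinograms(ps)
  expect_length(sinos, 64)
  expect_equal(dim(sinos[[32]]$values), c(24, 64))
  s <- sinos[[32]]$values
  com <- apply(s, 1, function(v) sum(v * seq_along(v)) / sum(v))
  expect_lt(max(com) - min(com), 0.05)
  # an off-axis feature traces a sinusoid with amplitude = its radius
  spec2 <- phantom_spec(list(primitive_sphere(c(94, 64, 64), 8,
                                              attenuation = 0.02)),
                        extent = c(128, 128, 128))
  ph2 <- make_phantom(spec2, 2)
  ps2 <- simulate_od_projections(ph2$attenuation, flat_spiral(15), opt)
  s2 <- build_sinograms(ps2, 32)[[1]]
  com2 <- apply(s2$values, 1, function(v) sum(v * (seq_along(v) - 1)) /
                                sum(v))
  th <- s2$angles * pi / 180
  fit <- stats::lm(com2 ~ cos(th) + sin(th))
  expect_lt(abs(sqrt(sum(coef(fit)[2:3]^2)) - 15), 0.2)  # 30 um = 15 px
})

test_that("filtered back-projection recovers a uniform disk", {
  expect_true(all(fbp_slice(sinogram(matrix(0, 12, 16),
                                     seq(0, 330, 30))) == 0))
  W <- 128; mu <- 0.01; r <- 40
  angles <- seq(0, 359)
  sino <- sinogram(disk_sinogram(W, r, mu, angles), angles, 1, 1)
  sl <- fbp_slice(sino)
  xs <- (0:(W - 1)) - (W - 1) / 2
  rad <- sqrt(outer(xs^2, xs^2, `+`))
  inside <- rad < 0.9 * r
  expect_lt(abs(mean(sl[inside]) / mu - 1), 0.03)
  expect_lt(sqrt(mean((sl[inside] - mu)^2)) / mu, 0.05)
  # windowed filters stay close to the ramp on a smooth object
  for (f in c("shepp-logan", "hamming"))
    expect_lt(abs(mean(fbp_slice(sino, filter = f)[inside]) / mu - 1), 0.05)
})

test_that("a full turn equals the average of its two half-turn subsets", {
  W <- 64
  angles <- seq(0, 359, 1)
  set.seed(8)
  base <- disk_sinogram(W, 20, 0.01, angles, center_offset = 6)
  full <- fbp_slice(sinogram(base, angles, 1, 1))
  h1 <- fbp_slice(sinogram(base[1:180, ], angles[1:180], 1, 1))
  h2 <- fbp_slice(sinogram(base[181:360, ], angles[181:360], 1, 1))
  expect_lt(max(abs(full - (h1 + h2) / 2)), 1e-6)
})

test_that("back-projection is linear in the sinogram", {
  W <- 48
  angles <- seq(0, 345, 15)
  set.seed(4)
  s1 <- matrix(abs(rnorm(length(angles) * W)), length(angles), W)
  s2 <- matrix(abs(rnorm(length(angles) * W)), length(angles), W)
  f <- function(s) fbp_slice(sinogram(s, angles, 1, 1))
  expect_lt(max(abs(f(2 * s1 + 0.5 * s2) - (2 * f(s1) + 0.5 * f(s2)))),
            1e-6)
})

test_that("per-angle sinogram mass is conserved for noiseless data", {
  ph <- make_phantom(two_sphere_phantom(), 2)
  ps <- simulate_od_projections(ph$attenuation, flat_spiral(10),
                                ideal_optics())
  s <- build_sinograms(ps, 50)[[1]]$values
  sums <- rowSums(s)
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.01)
})

test_that("variance maximization finds the rotation axis", {
  opt <- ideal_optics()
  ph <- make_phantom(two_sphere_phantom(c(160, 160, 160)), 2)
  run <- function(off) {
    sp <- flat_spiral(angular_step = 3, axis_offset_x = off)
    ps <- simulate_od_projections(ph$attenuation, sp, opt)
    estimate_axis(build_sinograms(ps, seq(30, 50, 5)), search_range = 10)
  }
  e0 <- run(0)
  expect_lt(abs(e0$offset_x), 0.25)
  e5 <- run(5)
  expect_lt(abs(e5$offset_x - 5), 0.5)
  # the metric peaks at the true offset and is unimodal around it
  mc <- e5$metric_curve
  imax <- which.max(mc$variance)
  expect_equal(mc$offset[imax], 5)
  near <- which(abs(mc$offset - 5) <= 4)
  v <- mc$variance[near]
  i0 <- which.max(v)
  expect_true(all(diff(v[seq_len(i0)]) > 0))
  expect_true(all(diff(v[i0:length(v)]) < 0))
  # a maximum on the scan boundary is refused
  sp_far <- flat_spiral(angular_step = 3, axis_offset_x = 5)
  ps_far <- simulate_od_projections(ph$attenuation, sp_far, opt)
  expect_error(estimate_axis(build_sinograms(ps_far, seq(30, 50, 5)),
                             search_range = 4),
               "widen")
})

test_that("volume reconstruction is faithful and equivariant", {
  opt <- ideal_optics()
  spec <- two_sphere_phantom(c(128, 128, 128))
  ph <- make_phantom(spec, 2)
  ps <- simulate_od_projections(ph$attenuation, flat_spiral(3), opt)
  vol <- reconstruct_volume(ps, axis = 0)
  expect_equal(dim(vol$voxels), dim(ph$attenuation$voxels))
  expect_gt(cor(as.vector(vol$voxels), as.vector(ph$attenuation$voxels)),
            0.9)
  # rotating the phantom rotates the reconstruction accordingly
  rot <- tomo_volume(array(
    spiraltomo:::cpp_rotate_y(ph$attenuation$voxels, 90, 31.5, 31.5),
    dim(ph$attenuation$voxels)), 2, "1/um")
  ps_rot <- simulate_od_projections(rot, flat_spiral(3), opt)
  vol_rot <- reconstruct_volume(ps_rot, axis = 0)
  expected <- array(spiraltomo:::cpp_rotate_y(vol$voxels, 90, 31.5, 31.5),
                    dim(vol$voxels))
  keep <- expected != 0 | vol_rot$voxels != 0
  expect_gt(cor(vol_rot$voxels[keep], expected[keep]), 0.95)
})

test_that("raw-count projections demand correction frames", {
  ph <- make_phantom(two_sphere_phantom(c(64, 64, 64)), 2)
  opt <- ideal_optics()
  sp <- flat_spiral(angular_step = 10)
  ps <- stream_fuse(simulate_spiral(ph$attenuation, opt, sp, seed = 1), sp)
  expect_identical(ps$domain, "counts")
  expect_error(reconstruct_volume(ps, axis = 0), "correction frames")
  corr <- simulate_correction_frames(opt, c(32, 32))
  vol <- reconstruct_volume(ps, corr = corr, axis = 0)
  expect_gt(cor(as.vector(vol$voxels), as.vector(ph$attenuation$voxels)),
            0.8)
})
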