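test_that("projection of an empty volume is zero at any angle", {
  vol <- tomo_volume(array(0, c(20, 10, 20)), 2)
  for (th in c(0, 17, 90, 233))
    expect_true(all(project_attenuation(vol, th) == 0))
})

test_that("projection of a uniform sphere matches the analytic chord length", {
  spec <- phantom_spec(list(primitive_sphere(c(100, 100, 100), 50,
                                             attenuation = 0.01)),
                       extent = c(200, 200, 200))
  ph <- make_phantom(spec, 1)
  p <- project_attenuation(ph$attenuation, 30)
  d <- dim(ph$attenuation$voxels)
  prof <- p[, round(d[2] / 2)]
  xs <- (seq_len(d[1]) - 1 - (d[1] - 1) / 2) * 1
  chord <- 2 * 0.01 * sqrt(pmax(50^2 - xs^2, 0))
  sel <- abs(xs) < 0.8 * 50
  expect_lt(max(abs(prof[sel] - chord[sel]) / chord[sel]), 0.02)
})

test_that("total projected mass is conserved under rotation", {
  ph <- make_phantom(two_sphere_phantom(), 2)
  sums <- vapply(seq(0, 315, by = 45),
                 function(th) sum(project_attenuation(ph$attenuation, th)),
                 numeric(1))
  expect_lt((max(sums) - min(sums)) / mean(sums), 0.01)
})

test_that("spiral streams keep the frame count and angle bookkeeping", {
  ph <- make_phantom(two_sphere_phantom(c(64, 64, 64)), 2)
  opt <- ideal_optics()
  sp <- spiral_params(n_rotations = 3, angular_step = 45,
                      z_start = -20, z_end = 20)
  fr <- collect_frames(simulate_spiral(ph$attenuation, opt, sp, seed = 1))
  expect_length(fr, sp$total_frames)
  idx <- vapply(fr, `[[`, integer(1), "index")
  expect_setequal(idx, 0:(sp$total_frames - 1))
  ang <- vapply(fr, `[[`, numeric(1), "angle")
  expect_equal(ang[order(idx)], (0:(sp$total_frames - 1) * 45) %% 360)
  # every angle appears exactly n_rotations times
  expect_true(all(table(ang) == sp$n_rotations))
  # focal positions are linear in the acquisition index
  fz <- vapply(fr, `[[`, numeric(1), "focal_z")[order(idx)]
  expect_equal(fz, seq(-20, 20, length.out = sp$total_frames))
})

test_that("zero attenuation with no noise gives uniform background frames", {
  vol <- tomo_volume(array(0, c(16, 16, 16)), 2)
  opt <- optics_params(noise_sd = 0, pixel_size_sample = 2)
  sp <- flat_spiral(angular_step = 90)
  fr <- collect_frames(simulate_spiral(vol, opt, sp, seed = 1))
  for (f in fr)
    expect_true(all(f$pixels == opt$background_level))
})

test_that("Beer-Lambert round trip is exact for all-in-focus optics", {
  ph <- make_phantom(two_sphere_phantom(), 2)
  opt <- ideal_optics(pixel_size = 2)
  sp <- flat_spiral(angular_step = 45)
  fr <- collect_frames(simulate_spiral(ph$attenuation, opt, sp, seed = 1))
  for (f in fr[c(1, 3, 6)]) {
    od <- -log((f$pixels - opt$dark_level) /
                 (opt$background_level - opt$dark_level))
    expect_lt(max(abs(od - project_attenuation(ph$attenuation, f$angle))),
              1e-6)
  }
})

test_that("the simulator is deterministic under a fixed seed", {
  ph <- make_phantom(two_sphere_phantom(c(64, 64, 64)), 2)
  opt <- optics_params(pixel_size_sample = 2, noise_sd = 15)
  sp <- spiral_params(n_rotations = 2, angular_step = 60,
                      z_start = -10, z_end = 10)
  f1 <- collect_frames(simulate_spiral(ph$attenuation, opt, sp, seed = 9))
  f2 <- collect_frames(simulate_spiral(ph$attenuation, opt, sp, seed = 9))
  expect_identical(f1, f2)
  # a different seed changes only the noise
  f3 <- collect_frames(simulate_spiral(ph$attenuation, opt, sp, seed = 10))
  expect_false(identical(f1[[1]]$pixels, f3[[1]]$pixels))
  opt0 <- optics_params(pixel_size_sample = 2, noise_sd = 0)
  g1 <- collect_frames(simulate_spiral(ph$attenuation, opt0, sp, seed = 9))
  g2 <- collect_frames(simulate_spiral(ph$attenuation, opt0, sp, seed = 10))
  expect_identical(g1, g2)
})

test_that("a focal range outside the volume warns but still yields frames", {
  ph <- make_phantom(two_sphere_phantom(c(64, 64, 64)), 2)
  sp <- spiral_params(n_rotations = 1, angular_step = 90,
                      z_start = 500, z_end = 600)
  expect_warning(st <- simulate_spiral(ph$attenuation, ideal_optics(),
                                       sp, seed = 1),
                 "does not cover")
  expect_length(collect_frames(st), 4)
})

test_that("SPIM stacks section the rotated fluorescence volume", {
  # zero volume -> zero stack
  z <- tomo_volume(array(0, c(32, 32, 32)), 2)
  expect_true(all(simulate_spim_stack(z, 0, 2)$slices == 0))
  # the brightest slice locates a single sphere's z within one slice
  spec <- phantom_spec(list(primitive_sphere(c(64, 64, 80), 16,
                                             fluorescence = 1)),
                       extent = c(128, 128, 128))
  ph <- make_phantom(spec, 2)
  off <- 14
  st <- simulate_spim_stack(ph$fluorescence, 0, 2, axis_z_offset = off)
  k <- which.max(apply(st$slices, 3, sum))
  n <- dim(st$slices)[3]
  z_phys <- ((k - 1) - (n - 1) / 2) * st$z_spacing - off
  expect_lt(abs(z_phys - 16), st$z_spacing + 1e-9)  # sphere centre at +16 um
  # views 90 degrees apart carry the same total signal within 2%
  ph2 <- make_phantom(two_sphere_phantom(), 2)
  s0 <- simulate_spim_stack(ph2$fluorescence, 0, 2)
  s90 <- simulate_spim_stack(ph2$fluorescence, 90, 2)
  expect_lt(abs(sum(s0$slices) / sum(s90$slices) - 1), 0.02)
})
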