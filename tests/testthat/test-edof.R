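# small helper: a through-focus acquisition reused across fusion tests
make_defocus_stream <- function(n_rotations = 4, angular_step = 90,
                                seed = 3) {
  ph <- make_phantom(two_sphere_phantom(c(96, 96, 96)), 2)
  opt <- optics_params(pixel_size_sample = 2, noise_sd = 0,
                       depth_of_field = 10, sigma0 = 1)
  sp <- spiral_params(n_rotations = n_rotations, angular_step = angular_step,
                      z_start = -40, z_end = 40)
  list(stream = simulate_spiral(ph$attenuation, opt, sp, seed = seed),
       spiral = sp, optics = opt)
}

test_that("grouping by angle yields one frame per rotation, focus-ordered", {
  x <- make_defocus_stream(n_rotations = 2, angular_step = 90)
  groups <- group_by_angle(x$stream, x$spiral)
  expect_length(groups, 4)
  for (g in groups) {
    expect_length(g$frames, 2)
    expect_true(all(vapply(g$frames, `[[`, numeric(1), "angle") == g$angle))
    fz <- vapply(g$frames, `[[`, numeric(1), "focal_z")
    expect_true(all(diff(fz) > 0))
  }
  expect_equal(vapply(groups, `[[`, numeric(1), "angle"), c(0, 90, 180, 270))
})

test_that("grouping is invariant to the order of the incoming stream", {
  x <- make_defocus_stream(n_rotations = 3, angular_step = 120)
  fr <- collect_frames(x$stream)
  g1 <- group_by_angle(fr, x$spiral)
  set.seed(11)
  g2 <- group_by_angle(fr[sample(length(fr))], x$spiral)
  expect_identical(g1, g2)
})

test_that("missing and duplicate frames are reported by index", {
  x <- make_defocus_stream(n_rotations = 2, angular_step = 180)
  fr <- collect_frames(x$stream)
  expect_error(group_by_angle(fr[-2], x$spiral), "expected 4 frames")
  bad <- fr
  bad[[3]] <- bad[[2]]
  expect_error(group_by_angle(bad, x$spiral), "index 1")
})

test_that("focus weights respond to high-frequency content only", {
  flat <- matrix(7, 32, 32)
  expect_lt(max(abs(focus_weight(flat))), 1e-20)
  # a sharp step outweighs a soft (ramped) copy of the same edge
  ramp_edge <- function(width) {
    m <- matrix(0, 32, 32)
    for (i in 1:32) m[i, ] <- 100 * min(1, max(0, (i - 16) / width + 0.5))
    m
  }
  sharp <- ramp_edge(1)
  soft <- ramp_edge(10)
  expect_gt(sum(focus_weight(sharp)), sum(focus_weight(soft)))
  # adding a constant offset leaves the weight map unchanged
  expect_equal(focus_weight(sharp + 123), focus_weight(sharp))
})

test_that("fusing identical frames returns that frame exactly", {
  img <- matrix(rnorm(32 * 32, 100, 10), 32)
  img <- abs(img)
  fr <- lapply(1:5, function(i) tomo_frame(img, 0, i, i - 1))
  expect_equal(fuse_group(angle_group(0, fr)), img)
})

test_that("fusion picks the sharp frame over flat companions", {
  sharp <- matrix(100, 48, 48)
  sharp[, 24:48] <- 200            # strong vertical edge
  flat <- matrix(150, 48, 48)
  fused <- fuse_group(list(sharp, flat, flat))
  edge <- cbind(20:28, 24)         # pixels on the edge
  expect_lt(max(abs(fused[edge] - sharp[edge]) / sharp[edge]), 0.01)
})

test_that("fused projections keep at least the sharpest frame's detail", {
  # structures at well-separated depths: no single focal plane is sharp
  # everywhere, which is the scenario extended depth of field exists for
  spec <- phantom_spec(list(
    primitive_sphere(c(30, 48, 20), 10, attenuation = 0.02),
    primitive_sphere(c(66, 48, 76), 10, attenuation = 0.02)),
    extent = c(96, 96, 96))
  ph <- make_phantom(spec, 2)
  opt <- optics_params(pixel_size_sample = 2, noise_sd = 0,
                       depth_of_field = 8, sigma0 = 1.5)
  sp <- spiral_params(n_rotations = 8, angular_step = 360,
                      z_start = -40, z_end = 40)
  st <- simulate_spiral(ph$attenuation, opt, sp, seed = 3)
  g <- group_by_angle(st, sp)[[1]]
  hf_energy <- function(m) {
    d1 <- m[-1, ] - m[-nrow(m), ]
    d2 <- m[, -1] - m[, -ncol(m)]
    sum(d1^2) + sum(d2^2)
  }
  fused <- fuse_group(g)
  per_frame <- vapply(g$frames, function(f) hf_energy(f$pixels), numeric(1))
  expect_gte(hf_energy(fused), max(per_frame) * 0.999)
})

test_that("fusion is convex and commutes with intensity scaling", {
  set.seed(5)
  for (rep in 1:5) {
    frames <- lapply(1:4, function(i) abs(matrix(rnorm(400, 50, 20), 20)))
    fused <- fuse_group(frames)
    lo <- Reduce(pmin, frames)
    hi <- Reduce(pmax, frames)
    expect_true(all(fused >= lo - 1e-12 & fused <= hi + 1e-12))
    expect_equal(fuse_group(lapply(frames, `*`, 3.7)), 3.7 * fused)
  }
})

test_that("streaming fusion equals the batch path bit for bit", {
  x <- make_defocus_stream(n_rotations = 3, angular_step = 45)
  fr <- collect_frames(x$stream)
  ps <- stream_fuse(fr, x$spiral)
  batch <- vapply(group_by_angle(fr, x$spiral), fuse_group,
                  matrix(0, 48, 48))
  expect_identical(ps$projections, batch)
  expect_equal(ps$reduction_factor, 3)
  # and is independent of the arrival order
  set.seed(2)
  ps2 <- stream_fuse(fr[sample(length(fr))], x$spiral)
  expect_equal(ps2$projections, ps$projections)
})

test_that("a single-rotation spiral passes frames through with factor 1", {
  x <- make_defocus_stream(n_rotations = 1, angular_step = 90)
  fr <- collect_frames(x$stream)
  ps <- stream_fuse(fr, x$spiral)
  expect_equal(ps$reduction_factor, 1)
  for (k in seq_along(fr)) {
    a <- as.integer(round(fr[[k]]$angle / 90)) %% 4
    expect_equal(ps$projections[, , a + 1], fr[[k]]$pixels)
  }
})
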