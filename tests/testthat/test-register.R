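test_that("rigid transforms compose, invert and stay orthonormal", {
  th <- 35 * pi / 180
  R1 <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  t1 <- rigid_transform(R1, c(3, -2, 7))
  t2 <- rigid_transform(diag(3)[, c(2, 3, 1)][c(2, 3, 1), ], c(0, 1, 0))
  comp <- compose_transforms(t2, t1)
  p <- matrix(rnorm(30), 10)
  expect_equal(apply_transform(comp, p),
               apply_transform(t2, apply_transform(t1, p)))
  inv <- invert_transform(comp)
  expect_lt(max(abs(apply_transform(inv, apply_transform(comp, p)) - p)),
            1e-9)
  expect_lt(max(abs(crossprod(comp$rotation) - diag(3))), 1e-12)
  expect_error(rigid_transform(diag(c(1, 1, -1))), "determinant")
})

test_that("the rotation-axis z position is recovered from two views", {
  ph <- make_phantom(two_sphere_phantom(c(200, 200, 200)), 2)
  mk <- function(off, th) simulate_spim_stack(ph$fluorescence, th, 2,
                                              axis_z_offset = off)
  # centred case
  al0 <- align_spim_z(mk(0, 0), mk(0, 90))
  expect_lt(abs(al0$z_offset), 2)
  # a 30 um offset comes back within 2 um
  al <- align_spim_z(mk(30, 0), mk(30, 90))
  expect_lt(abs(al$z_offset - 30), 2)
  expect_gt(al$peak, 0.9)
  # the offset is a property of the shared stage: order-independent
  al_sw <- align_spim_z(mk(30, 90), mk(30, 0))
  expect_lt(abs(al_sw$z_offset - al$z_offset), 2)
  # structure-free stacks are refused
  flat <- spim_stack(array(1, c(20, 20, 20)), 2, 0, 2)
  flat90 <- spim_stack(array(1, c(20, 20, 20)), 2, 90, 2)
  expect_error(align_spim_z(flat, flat90), "insufficient mutual structure")
})

test_that("multimodal fusion puts fluorescence onto the tomographic grid", {
  spec <- phantom_spec(list(primitive_sphere(c(80, 100, 110), 24,
                                             attenuation = 0.01,
                                             fluorescence = 1)),
                       extent = c(200, 200, 200))
  ph <- make_phantom(spec, 2)
  off <- 24
  spim <- simulate_spim_stack(ph$fluorescence, 0, 2, axis_z_offset = off)
  fused <- fuse_multimodal(ph$attenuation, spim, off)
  c_tomo <- array_centroid(fused$channels$tomography$voxels)
  c_fluo <- array_centroid(fused$channels$fluorescence$voxels)
  expect_lt(max(abs(c_tomo - c_fluo)), 1)
  # zero fluorescence passes through as a zero channel
  z <- tomo_volume(array(0, dim(ph$fluorescence$voxels)), 2)
  zs <- simulate_spim_stack(z, 0, 2)
  f0 <- fuse_multimodal(ph$attenuation, zs, 0)
  expect_identical(f0$channels$tomography$voxels, ph$attenuation$voxels)
  expect_true(all(f0$channels$fluorescence$voxels == 0))
  # shifting by a then b equals shifting once by a + b
  fa <- fuse_multimodal(ph$attenuation, spim, 10)
  sa <- spim_stack(fa$channels$fluorescence$voxels, 2, 0, 2)
  fab <- fuse_multimodal(ph$attenuation, sa, 14)
  fboth <- fuse_multimodal(ph$attenuation, spim, 24)
  keep <- fboth$channels$fluorescence$voxels > 0.1
  expect_gt(cor(fab$channels$fluorescence$voxels[keep],
                fboth$channels$fluorescence$voxels[keep]), 0.98)
})

test_that("spherical landmarks are detected to voxel precision", {
  spec <- phantom_spec(list(primitive_sphere(c(100, 100, 100), 20,
                                             attenuation = 0.01)),
                       extent = c(200, 200, 200))
  ph <- make_phantom(spec, 2)
  det <- detect_spheres(ph$attenuation, 5, 15, n_best = 3)
  expect_equal(nrow(det), 1)
  expect_lt(max(abs(unlist(det[1, c("x", "y", "z")]) - c(50.5, 50.5, 50.5))),
            1)
  expect_lt(abs(det$radius - 10), 1)
  # two eye-lens-like spheres 60 voxels apart are both found
  spec2 <- phantom_spec(list(
    primitive_sphere(c(60, 100, 100), 20, attenuation = 0.01),
    primitive_sphere(c(180, 100, 100), 20, attenuation = 0.01)),
    extent = c(240, 240, 240))
  det2 <- detect_spheres(make_phantom(spec2, 2)$attenuation, 5, 15,
                         n_best = 2)
  expect_equal(nrow(det2), 2)
  xs <- sort(det2$x)
  expect_lt(abs(xs[1] - 30.5), 1)
  expect_lt(abs(xs[2] - 90.5), 1)
  # featureless volumes yield no detections
  expect_equal(nrow(detect_spheres(array(3, c(20, 20, 20)), 3, 6)), 0)
})

test_that("sphere detection is reliable across random phantoms", {
  set.seed(123)
  hits <- 0L
  trials <- 10L
  for (i in seq_len(trials)) {
    k <- 2L
    centers <- matrix(runif(3 * k, 60, 140), k)
    while (k > 1 && dist(centers) < 50)
      centers <- matrix(runif(3 * k, 60, 140), k)
    radius <- runif(k, 14, 24)
    prims <- lapply(seq_len(k), function(j)
      primitive_sphere(centers[j, ], radius[j], attenuation = 0.01))
    ph <- make_phantom(phantom_spec(prims, c(200, 200, 200)), 2)
    det <- detect_spheres(ph$attenuation, 5, 14, n_best = k)
    if (nrow(det) < k) next
    err <- vapply(seq_len(k), function(j) {
      gt <- centers[j, ] / 2 + 0.5
      min(sqrt(rowSums((as.matrix(det[, c("x", "y", "z")]) -
                          matrix(gt, nrow(det), 3, byrow = TRUE))^2)))
    }, numeric(1))
    if (all(err <= 1)) hits <- hits + 1L
  }
  expect_gte(hits / trials, 0.9)
})

test_that("eye landmarks define a rigid anatomical transform", {
  eyes <- rbind(c(-30, 5, 0), c(30, 5, 0))
  # identical landmarks give the identity
  tf0 <- eye_landmark_transform(eyes, eyes)
  expect_equal(tf0$rotation, diag(3))
  expect_equal(tf0$translation, c(0, 0, 0))
  # a known 20-degree rotation plus translation is recovered exactly
  th <- 20 * pi / 180
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(4, -7, 2)
  eyes_t <- eyes %*% t(Rz) + rep(shift, each = 2)
  tf <- eye_landmark_transform(eyes_t, eyes, as.numeric(Rz %*% c(0, 1, 0)),
                               c(0, 1, 0))
  expect_lt(max(abs(apply_transform(tf, eyes_t) - eyes)), 1e-6)
  expect_lt(max(abs(tf$rotation %*% Rz - diag(3))), 1e-6)
  # eye growth keeps the fit rigid; residual is half the distance change
  eyes_grown <- rbind(c(-35, 5, 0), c(35, 5, 0))
  tfg <- eye_landmark_transform(eyes_grown, eyes)
  expect_equal(unname(attr(tfg, "residual")), c(5, 5))
  expect_lt(max(abs(crossprod(tfg$rotation) - diag(3))), 1e-9)
  expect_error(eye_landmark_transform(rbind(eyes[1, ], eyes[1, ]), eyes),
               "degenerate|coincident")
})

jittered_head_spec <- function(shift, ang, extent = c(200, 200, 200)) {
  c0 <- extent / 2
  mv <- function(p) {
    th <- ang * pi / 180
    c(cos(th) * (p[1] - c0[1]) - sin(th) * (p[3] - c0[3]) + c0[1] + shift[1],
      p[2] + shift[2],
      sin(th) * (p[1] - c0[1]) + cos(th) * (p[3] - c0[3]) + c0[3] + shift[3])
  }
  phantom_spec(list(
    primitive_sphere(mv(c(60, 90, 100)), 16, attenuation = 0.012),
    primitive_sphere(mv(c(140, 90, 100)), 16, attenuation = 0.012),
    primitive_ellipsoid(mv(c(100, 120, 100)), c(50, 60, 40),
                        attenuation = 0.004)),
    extent = extent)
}

test_that("time-lapse volumes align onto the reference anatomy", {
  vols <- list(
    make_phantom(jittered_head_spec(c(0, 0, 0), 0), 2)$attenuation,
    make_phantom(jittered_head_spec(c(6, -4, 8), 8), 2)$attenuation,
    make_phantom(jittered_head_spec(c(-8, 5, -5), -10), 2)$attenuation)
  reg <- register_timelapse(vols, r_min = 5, r_max = 12)
  expect_false(any(reg$flagged))
  expect_equal(reg$transforms[[1]]$rotation, diag(3))
  for (i in 2:3)
    expect_gt(cor(as.vector(reg$volumes[[1]]$voxels),
                  as.vector(reg$volumes[[i]]$voxels)), 0.95)
  # a single time point registers to itself
  reg1 <- register_timelapse(vols[1], r_min = 5, r_max = 12)
  expect_identical(reg1$volumes[[1]]$voxels, vols[[1]]$voxels)
  # growth: eye spacing +10 % still aligns the midpoints
  grown <- jittered_head_spec(c(0, 0, 0), 0)
  grown$primitives[[1]]$center <- c(56, 90, 100)
  grown$primitives[[2]]$center <- c(144, 90, 100)
  volg <- make_phantom(grown, 2)$attenuation
  regg <- register_timelapse(list(vols[[1]], volg), r_min = 5, r_max = 12)
  dg <- regg$detections
  mid <- function(d) colMeans(as.matrix(d[1:2, c("x", "y", "z")]))
  tf <- regg$transforms[[2]]
  m2 <- apply_transform(tf, (mid(dg[[2]]) - 1 - 49.5) * 2)
  expect_lt(max(abs(m2 - (mid(dg[[1]]) - 1 - 49.5) * 2)), 2)
})

test_that("gradient-bounded region growing measures organ volumes", {
  spec <- phantom_spec(list(primitive_sphere(c(100, 100, 100), 20,
                                             attenuation = 0.01)),
                       extent = c(200, 200, 200))
  ph <- make_phantom(spec, 2)
  sm <- segment_region(ph$attenuation, c(50, 50, 50),
                       gradient_threshold = 0.002)
  expect_lt(abs(sm$volume_um3 / (4 / 3 * pi * 20^3) - 1), 0.1)
  # threshold zero keeps only the seed
  sm0 <- segment_region(ph$attenuation, c(50, 50, 50),
                        gradient_threshold = 0)
  expect_equal(sm0$n_voxels, 1L)
  expect_true(sm0$mask[50, 50, 50])
  # the mask does not depend on which interior voxel seeds it
  sm2 <- segment_region(ph$attenuation, c(54, 47, 52),
                        gradient_threshold = 0.002)
  expect_identical(sm$mask, sm2$mask)
  # seeding on an edge is refused
  expect_error(segment_region(ph$attenuation, c(50, 50, 60),
                              gradient_threshold = 0.002),
               "high-gradient")
})
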