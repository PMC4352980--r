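#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation, um.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be orthonormal with determinant +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(max(-1, min(1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("Rigid transform: rotation %.2f deg, translation (%s) um\n",
              ang, paste(sprintf("%.2f", x$translation), collapse = ", ")))
  invisible(x)
}

#' Apply, compose and invert rigid transforms
#'
#' @param tf,a,b [rigid_transform()] objects.
#' @param points n x 3 matrix (or length-3 vector) of coordinates.
#' @return Transformed points / the composed or inverted transform.
#' @export
apply_transform <- function(tf, points) {
  stopifnot(inherits(tf, "rigid_transform"))
  p <- if (is.null(dim(points))) matrix(points, 1) else as.matrix(points)
  out <- p %*% t(tf$rotation) + rep(tf$translation, each = nrow(p))
  if (is.null(dim(points))) drop(out) else out
}

#' @rdname apply_transform
#' @export
compose_transforms <- function(a, b) {
  # (a o b): apply b first, then a
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation),
                  as.numeric(-t(tf$rotation) %*% tf$translation))
}

# resample a stack to isotropic voxels (linear interpolation along stack z)
spim_isotropic <- function(stack) {
  stopifnot(inherits(stack, "spim_stack"))
  d <- dim(stack$slices)
  ps <- stack$pixel_size
  if (abs(stack$z_spacing - ps) < 1e-9) return(stack$slices)
  mz <- as.integer(floor((d[3] - 1) * stack$z_spacing / ps)) + 1L
  out <- array(0, c(d[1], d[2], mz))
  for (k in seq_len(mz)) {
    zi <- (k - 1) * ps / stack$z_spacing
    z0 <- min(floor(zi), d[3] - 1)
    fz <- zi - z0
    sl <- (1 - fz) * stack$slices[, , z0 + 1]
    if (z0 + 2 <= d[3]) sl <- sl + fz * stack$slices[, , z0 + 2]
    out[, , k] <- sl
  }
  out
}

# centre-embed an array into the given dims (crop or zero-pad per axis)
center_embed <- function(arr, dims) {
  out <- array(0, dims)
  src <- dim(arr)
  n <- pmin(src, dims)
  so <- floor((src - n) / 2)
  do <- floor((dims - n) / 2)
  out[do[1] + seq_len(n[1]), do[2] + seq_len(n[2]), do[3] + seq_len(n[3])] <-
    arr[so[1] + seq_len(n[1]), so[2] + seq_len(n[2]), so[3] + seq_len(n[3])]
  out
}

#' Locate the rotation axis in z from two orthogonal SPIM views
#'
#' The two stacks (views 90 degrees apart) are resampled to isotropic
#' voxels; the rotated view is axis-permuted so that its stack-z axis maps
#' onto the reference's x axis. Normalized cross-correlation over a 1D shift
#' along the reference's z then yields the z position of the rotation axis,
#' refined to sub-voxel precision by a parabolic fit around the peak.
#'
#' @param ref Reference [spim_stack()] at view angle theta0.
#' @param rot [spim_stack()] at theta0 + 90 degrees.
#' @param max_shift Largest shift searched, um; default one third of the
#'   common z extent.
#' @param min_peak Minimum admissible correlation peak.
#' @return List with `z_offset` (um), `peak`, and the correlation `curve`;
#'   class `spim_alignment`.
#' @export
align_spim_z <- function(ref, rot, max_shift = NULL, min_peak = 0.2) {
  stopifnot(inherits(ref, "spim_stack"), inherits(rot, "spim_stack"))
  dang <- (rot$angle - ref$angle) %% 360
  if (min(abs(dang - 90), abs(dang - 270)) > 1e-6)
    warning("views are not 90 degrees apart; alignment assumes they are")
  plus90 <- abs(dang - 90) < abs(dang - 270)
  ps <- ref$pixel_size
  a <- spim_isotropic(ref)
  b <- spim_isotropic(rot)
  # resample the rotated view onto the reference grid: its stack-z axis maps
  # onto the reference's x axis (rotation about y), sub-voxel exact
  ca <- (dim(a) - 1) / 2
  cb <- (dim(b) - 1) / 2
  M <- if (plus90) rbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0))
       else        rbind(c(0, 0,  1), c(0, 1, 0), c(-1, 0, 0))
  b <- array(cpp_resample_affine(b, M, as.numeric(cb - M %*% ca), dim(a)),
             dim(a))
  dims <- dim(a)
  nx <- dims[1]; nz <- dims[3]
  if (is.null(max_shift)) max_shift <- min(nx, nz) * ps / 3
  smax <- max(1L, min(min(nx, nz) - 2L, as.integer(ceiling(max_shift / ps))))
  shifts <- (-smax):smax
  # one unknown: the axis offset displaces the reference along z and the
  # permuted 90-degree view along x by the same amount, so a single 1D scan
  # compensates both at once
  ncc <- vapply(shifts, function(s) {
    sb <- if (plus90) s else -s   # the -90 permutation mirrors the x shift
    ia1 <- if (sb >= 0) 1:(nx - sb) else (1 - sb):nx
    ia3 <- if (s >= 0) (1 + s):nz else 1:(nz + s)
    ib1 <- if (sb >= 0) (1 + sb):nx else 1:(nx + sb)
    ib3 <- if (s >= 0) 1:(nz - s) else (1 - s):nz
    va <- as.vector(a[ia1, , ia3]); vb <- as.vector(b[ib1, , ib3])
    if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(0)
    stats::cor(va, vb)
  }, numeric(1))
  imax <- which.max(ncc)
  if (!is.finite(ncc[imax]) || ncc[imax] < min_peak)
    stop("insufficient mutual structure: correlation peak ",
         sprintf("%.3f < %.3f", ncc[imax], min_peak))
  delta <- 0
  if (imax > 1 && imax < length(shifts)) {
    y1 <- ncc[imax - 1]; y2 <- ncc[imax]; y3 <- ncc[imax + 1]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 0) delta <- max(-1, min(1, 0.5 * (y1 - y3) / den))
  }
  structure(list(z_offset = (shifts[imax] + delta) * ps,
                 peak = ncc[imax],
                 curve = data.frame(shift_um = shifts * ps, ncc = ncc)),
            class = "spim_alignment")
}

#' @export
print.spim_alignment <- function(x, ...) {
  cat(sprintf("SPIM/tomography z-alignment: offset %.2f um (peak NCC %.3f)\n",
              x$z_offset, x$peak))
  invisible(x)
}

#' Overlay a SPIM stack onto the tomographic grid
#'
#' Resamples the fluorescence stack onto the tomography volume's isotropic
#' grid using the inherent lateral (x,y) alignment of the shared detector
#' plus the recovered z offset of the rotation axis.
#'
#' @param tomo Tomographic [tomo_volume()].
#' @param spim A [spim_stack()] acquired at the tomography reference view.
#' @param z_offset Axis z offset in um, e.g. from [align_spim_z()].
#' @return A `multichannel_volume` with congruent `tomography` and
#'   `fluorescence` channels.
#' @export
fuse_multimodal <- function(tomo, spim, z_offset = 0) {
  stopifnot(inherits(tomo, "tomo_volume"), inherits(spim, "spim_stack"))
  d <- dim(tomo$voxels)
  ds <- dim(spim$slices)
  vs <- tomo$voxel_size
  ps <- spim$pixel_size
  # tomo voxel (i,j,k) [0-based] -> spim indices
  A <- diag(c(vs / ps, vs / ps, vs / spim$z_spacing))
  t_vec <- c((ds[1] - 1) / 2 - (d[1] - 1) / 2 * vs / ps,
             (ds[2] - 1) / 2 - (d[2] - 1) / 2 * vs / ps,
             (ds[3] - 1) / 2 +
               (z_offset - (d[3] - 1) / 2 * vs) / spim$z_spacing)
  res <- cpp_resample_affine(spim$slices, A, t_vec, dim(tomo$voxels))
  res <- array(res, d)
  if (max(spim$slices) > 0 && max(res) == 0)
    stop("no overlap between the SPIM stack and the tomographic volume")
  structure(list(channels = list(tomography = tomo,
                                 fluorescence = tomo_volume(res, vs, "a.u.")),
                 voxel_size = vs),
            class = "multichannel_volume")
}

#' @export
print.multichannel_volume <- function(x, ...) {
  cat("Multichannel volume with channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

#' Detect spherical structures by gradient-direction Hough voting
#'
#' Strong-gradient voxels vote along their (inward-pointing, for bright
#' spheres) gradient direction at every candidate radius; vote peaks after
#' non-maximum suppression are returned by descending score. The score is
#' the fraction of the candidate sphere's surface supported by edge voxels.
#'
#' @param vol A [tomo_volume()] or 3D array.
#' @param r_min,r_max Radius search range, voxels.
#' @param n_best Maximum number of detections returned.
#' @param grad_threshold Gradient magnitude cut for edge voxels; default half
#'   the 98th percentile of the non-zero gradient magnitudes (after
#'   smoothing).
#' @param r_step Radius scan step, voxels.
#' @param smooth_sigma Gaussian pre-smoothing in voxels; regularises the
#'   gradient directions (crisp synthetic volumes otherwise quantise them to
#'   the 26 lattice directions and the votes no longer converge).
#' @return Data frame with sub-voxel `x,y,z` (1-based voxel coordinates),
#'   `radius` (voxels) and `score`, at most `n_best` rows.
#' @export
detect_spheres <- function(vol, r_min, r_max, n_best = 2,
                           grad_threshold = NULL, r_step = 1,
                           smooth_sigma = 1) {
  stopifnot(r_min < r_max, r_min > 0)
  arr <- if (inherits(vol, "tomo_volume")) vol$voxels else vol
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      radius = numeric(0), score = numeric(0))
  if (max(arr) == min(arr)) return(empty)
  if (smooth_sigma > 0)
    arr <- array(cpp_gauss_blur3d(arr, smooth_sigma), dim(arr))
  if (is.null(grad_threshold)) {
    gm <- cpp_grad_mag(arr)
    pos <- gm[gm > 0]
    if (!length(pos)) return(empty)
    # half the robust maximum: keeps sharp shell voxels on binary phantoms
    # and the strong edges of smooth reconstructions alike
    grad_threshold <- 0.5 * stats::quantile(pos, 0.98, names = FALSE)
  }
  cand <- cpp_sphere_hough(arr, r_min, r_max, r_step, grad_threshold)
  if (nrow(cand) == 0) return(empty)
  cand <- cand[order(-cand[, "score"]), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(keep)) {
      dmin <- min(sqrt(rowSums(
        (cand[keep, 1:3, drop = FALSE] -
           matrix(cand[i, 1:3], length(keep), 3, byrow = TRUE))^2)))
      if (dmin < r_min) next
    }
    keep <- c(keep, i)
    if (length(keep) >= n_best) break
  }
  sel <- cand[keep, , drop = FALSE]
  data.frame(x = sel[, "x"] + 1, y = sel[, "y"] + 1, z = sel[, "z"] + 1,
             radius = sel[, "r"], score = sel[, "score"])
}

unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("degenerate direction vector")
  v / n
}

# orthonormal frame from an axis and a roughly-dorsal hint
landmark_frame <- function(eye_axis, dorsal) {
  e1 <- unitize(eye_axis)
  d <- dorsal - sum(dorsal * e1) * e1
  if (sqrt(sum(d^2)) < 1e-9)
    stop("dorsal hint is parallel to the eye axis")
  e2 <- unitize(d)
  cbind(e1, e2, c(e1[2] * e2[3] - e1[3] * e2[2],
                  e1[3] * e2[1] - e1[1] * e2[3],
                  e1[1] * e2[2] - e1[2] * e2[1]))
}

#' Rigid transform from paired eye landmarks
#'
#' Maps the time point's eye midpoint onto the reference midpoint, the
#' eye-to-eye axis onto the reference eye axis, and a dorsal-direction hint
#' (the third, otherwise unconstrained, degree of freedom) onto the
#' reference dorsal direction. The transform stays rigid under eye-distance
#' changes (growth); the per-eye residual is attached as attribute
#' `"residual"`.
#'
#' @param eyes_t,eyes_ref 2 x 3 matrices of eye centres (rows) for the moving
#'   time point and the reference.
#' @param dorsal_t,dorsal_ref Length-3 dorsal hints; default +y.
#' @return A [rigid_transform()] mapping time-point into reference
#'   coordinates.
#' @export
eye_landmark_transform <- function(eyes_t, eyes_ref,
                                   dorsal_t = c(0, 1, 0),
                                   dorsal_ref = c(0, 1, 0)) {
  eyes_t <- as.matrix(eyes_t); eyes_ref <- as.matrix(eyes_ref)
  stopifnot(all(dim(eyes_t) == c(2, 3)), all(dim(eyes_ref) == c(2, 3)))
  ax_t <- eyes_t[2, ] - eyes_t[1, ]
  ax_r <- eyes_ref[2, ] - eyes_ref[1, ]
  if (sqrt(sum(ax_t^2)) < 1e-9 || sqrt(sum(ax_r^2)) < 1e-9)
    stop("coincident eye centres: landmarks are degenerate")
  Ft <- landmark_frame(ax_t, dorsal_t)
  Fr <- landmark_frame(ax_r, dorsal_ref)
  R <- Fr %*% t(Ft)
  mt <- colMeans(eyes_t); mr <- colMeans(eyes_ref)
  tf <- rigid_transform(R, mr - as.numeric(R %*% mt))
  mapped <- apply_transform(tf, eyes_t)
  attr(tf, "residual") <- sqrt(rowSums((mapped - eyes_ref)^2))
  tf
}

# voxel index (1-based) -> um relative to the volume centre
voxel_to_um <- function(idx, dims, voxel_size) {
  (as.matrix(idx) - 1 - matrix((dims - 1) / 2, nrow(as.matrix(idx)), 3,
                               byrow = TRUE)) * voxel_size
}

# dorsal hint: direction from the eye midpoint to the intensity centroid
intensity_dorsal_hint <- function(arr, midpoint_um, voxel_size) {
  d <- dim(arr)
  w <- pmax(arr, 0)
  tot <- sum(w)
  if (tot <= 0) return(c(0, 1, 0))
  xs <- axis_coords(d[1], voxel_size)
  ys <- axis_coords(d[2], voxel_size)
  zs <- axis_coords(d[3], voxel_size)
  cx <- sum(apply(w, 1, sum) * xs) / tot
  cy <- sum(apply(w, 2, sum) * ys) / tot
  cz <- sum(apply(w, 3, sum) * zs) / tot
  hint <- c(cx, cy, cz) - midpoint_um
  if (sqrt(sum(hint^2)) < 1e-9) c(0, 1, 0) else hint
}

#' Register a time-lapse series onto an anatomical reference
#'
#' Detects the two spherical eye-lens landmarks in every volume, derives a
#' rigid transform onto the reference time point (eye midpoint, eye axis and
#' a dorsal hint from the intensity centroid) and resamples each volume into
#' the reference frame, so that a fixed section index addresses homologous
#' anatomy across the whole series.
#'
#' @param volumes List of [tomo_volume()]s (one per time point).
#' @param r_min,r_max Eye-lens radius search range, voxels.
#' @param detections Optional list of precomputed [detect_spheres()] results.
#' @param reference Index of the reference time point.
#' @return List with registered `volumes`, `transforms`, `detections` and a
#'   logical `flagged` marking time points passed through untransformed
#'   because landmark detection failed; class `timelapse_registration`.
#' @export
register_timelapse <- function(volumes, r_min, r_max, detections = NULL,
                               reference = 1) {
  stopifnot(length(volumes) >= 1)
  n <- length(volumes)
  if (is.null(detections))
    detections <- lapply(volumes, detect_spheres,
                         r_min = r_min, r_max = r_max, n_best = 2)
  landmarks <- vector("list", n)
  dorsal <- vector("list", n)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    det <- detections[[i]]
    if (is.null(det) || nrow(det) < 2) { flagged[i] <- TRUE; next }
    vol <- volumes[[i]]
    d <- dim(vol$voxels)
    pts <- voxel_to_um(as.matrix(det[1:2, c("x", "y", "z")]), d,
                       vol$voxel_size)
    pts <- pts[order(pts[, 1]), , drop = FALSE]  # consistent left/right order
    landmarks[[i]] <- pts
    dorsal[[i]] <- intensity_dorsal_hint(vol$voxels, colMeans(pts),
                                         vol$voxel_size)
  }
  if (flagged[reference])
    stop("landmark detection failed on the reference time point")
  out_vols <- volumes
  transforms <- vector("list", n)
  for (i in seq_len(n)) {
    if (flagged[i]) next
    if (i == reference) { transforms[[i]] <- rigid_transform(); next }
    eyes_t <- landmarks[[i]]
    # flip pairing if the eye axis points the other way than the reference's
    if (sum((eyes_t[2, ] - eyes_t[1, ]) *
            (landmarks[[reference]][2, ] - landmarks[[reference]][1, ])) < 0)
      eyes_t <- eyes_t[2:1, , drop = FALSE]
    tf <- eye_landmark_transform(eyes_t, landmarks[[reference]],
                                 dorsal[[i]], dorsal[[reference]])
    transforms[[i]] <- tf
    vol <- volumes[[i]]
    d <- dim(vol$voxels)
    vs <- vol$voxel_size
    cvec <- (d - 1) / 2
    Rt <- t(tf$rotation)
    t_vox <- as.numeric(-Rt %*% cvec) - as.numeric(Rt %*% tf$translation) / vs +
      cvec
    res <- cpp_resample_affine(vol$voxels, Rt, t_vox, d)
    out_vols[[i]] <- tomo_volume(array(res, d), vs, vol$unit)
  }
  structure(list(volumes = out_vols, transforms = transforms,
                 detections = detections, flagged = flagged,
                 reference = reference),
            class = "timelapse_registration")
}

#' @export
print.timelapse_registration <- function(x, ...) {
  cat(sprintf("Time-lapse registration: %d time points, reference %d, %d flagged\n",
              length(x$volumes), x$reference, sum(x$flagged)))
  invisible(x)
}

#' Gradient-bounded seeded region growing
#'
#' Grows a 26-connected region from the seed, accepting voxels whose local
#' gradient magnitude stays below the threshold, i.e. the region floods
#' homogeneous tissue and stops at intensity edges. Supports quantitative
#' organ volume measurements.
#'
#' @param vol A [tomo_volume()] or 3D array.
#' @param seed Length-3 integer voxel index (1-based).
#' @param gradient_threshold Gradient magnitude bound (volume units per
#'   voxel).
#' @return List with the logical `mask`, `n_voxels` and (when the input
#'   carries a voxel size) `volume_um3`; class `region_mask`.
#' @export
segment_region <- function(vol, seed, gradient_threshold) {
  arr <- if (inherits(vol, "tomo_volume")) vol$voxels else vol
  vs <- if (inherits(vol, "tomo_volume")) vol$voxel_size else NA_real_
  d <- dim(arr)
  seed <- as.integer(round(seed))
  stopifnot(length(seed) == 3)
  if (any(seed < 1) || any(seed > d))
    stop("seed lies outside the volume")
  gm <- cpp_grad_mag(arr)
  if (gm[seed[1], seed[2], seed[3]] > gradient_threshold)
    stop("seed sits on a high-gradient voxel; choose a seed inside a ",
         "homogeneous region")
  mask <- cpp_region_grow(arr, seed - 1L, gradient_threshold)
  mask <- array(mask == 1L, d)
  mask[seed[1], seed[2], seed[3]] <- TRUE
  structure(list(mask = mask, n_voxels = sum(mask),
                 volume_um3 = if (is.na(vs)) NA_real_ else sum(mask) * vs^3,
                 seed = seed, gradient_threshold = gradient_threshold),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("Region mask: %d voxels", x$n_voxels))
  if (is.finite(x$volume_um3)) cat(sprintf(" (%.3g um^3)", x$volume_um3))
  cat("\n")
  invisible(x)
}
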