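# On-disk convention: one multi-page TIFF per dataset plus a JSON sidecar
# (same path with .json extension) carrying acquisition metadata. Sidecars
# rather than TIFF tags keep the files portable across toolchains.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
}

read_sidecar <- function(path, required = character()) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop("missing sidecar metadata file '", sp, "'; required keys: ",
         paste(required, collapse = ", "))
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stop("sidecar '", sp, "' lacks required keys: ",
         paste(miss, collapse = ", "))
  meta
}

#' Write a frame stream to disk
#'
#' Pixel data go into a 16-bit multi-page TIFF (rounded and clamped to
#' 0..65535); the spiral/optics parameters, the seed and the per-page frame
#' index, angle and focal position go into a JSON sidecar next to it.
#'
#' @param frames A [frame_stream()] or list of frames.
#' @param path Output TIFF path.
#' @param seed Seed recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_frames <- function(frames, path, seed = NULL) {
  stream <- as_frame_stream(frames)
  fr <- collect_frames(stream)
  write_tiff_stack(lapply(fr, `[[`, "pixels"), path, "uint16")
  write_sidecar(list(
    kind = "spiral_frames",
    n_frames = length(fr),
    index = vapply(fr, `[[`, integer(1), "index"),
    angle = vapply(fr, `[[`, numeric(1), "angle"),
    focal_z = vapply(fr, `[[`, numeric(1), "focal_z"),
    spiral = unclass(stream$spiral),
    optics = unclass(stream$optics),
    seed = seed), path)
  invisible(path)
}

#' Read a frame stream from disk
#'
#' Lazily reads the 16-bit TIFF written by [write_frames()]; pages are
#' fetched on demand so full spiral acquisitions never reside in memory.
#'
#' @param path TIFF path with its JSON sidecar.
#' @return A [frame_stream()].
#' @export
read_frames <- function(path) {
  meta <- read_sidecar(path, c("n_frames", "index", "angle", "focal_z"))
  idx <- tiff_index(path)
  if (length(idx) != meta$n_frames)
    stop(sprintf("'%s' has %d pages but the sidecar declares %d frames",
                 path, length(idx), meta$n_frames))
  spiral <- if (!is.null(meta$spiral)) do.call(spiral_params, meta$spiral[
    c("n_rotations", "angular_step", "z_start", "z_end", "axis_offset_x",
      "frame_rate")]) else NULL
  optics <- if (!is.null(meta$optics))
    do.call(optics_params, meta$optics) else NULL
  env <- new.env(parent = emptyenv())
  env$k <- 0L
  env$con <- NULL
  nxt <- function() {
    if (env$k >= length(idx)) {
      if (!is.null(env$con)) { close(env$con); env$con <- NULL }
      return(NULL)
    }
    if (is.null(env$con)) env$con <- file(path, "rb")
    env$k <- env$k + 1L
    k <- env$k
    tomo_frame(tiff_read_page(env$con, idx[[k]]),
               angle = meta$angle[k], focal_z = meta$focal_z[k],
               index = meta$index[k])
  }
  frame_stream(next_frame = nxt,
               reset = function() {
                 if (!is.null(env$con)) { close(env$con); env$con <- NULL }
                 env$k <- 0L
               },
               n_frames = meta$n_frames, spiral = spiral, optics = optics)
}

#' Projection set and volume file I/O
#'
#' Projections and volumes are stored as 32-bit float multi-page TIFFs with
#' JSON sidecars; volume pages are transverse (x,z) sections indexed by y.
#'
#' @param projections A [projection_set()].
#' @param vol A [tomo_volume()].
#' @param path TIFF path.
#' @return The read object, or `path` invisibly for writers.
#' @name tomo_io
NULL

#' @rdname tomo_io
#' @export
write_projections <- function(projections, path) {
  stopifnot(inherits(projections, "projection_set"))
  write_tiff_stack(projections$projections, path, "float32")
  write_sidecar(list(kind = "projections",
                     angular_step = projections$angular_step,
                     angles = projections$angles,
                     pixel_size = projections$pixel_size,
                     domain = projections$domain,
                     reduction_factor = projections$reduction_factor,
                     fusion = projections$fusion), path)
  invisible(path)
}

#' @rdname tomo_io
#' @export
read_projections <- function(path) {
  meta <- read_sidecar(path, c("angular_step", "pixel_size", "domain"))
  arr <- read_tiff_stack(path)
  if (!is.null(meta$angles) && dim(arr)[3] != length(meta$angles))
    stop(sprintf("'%s' has %d pages but the sidecar declares %d angles",
                 path, dim(arr)[3], length(meta$angles)))
  projection_set(arr, meta$angular_step, meta$pixel_size,
                 domain = meta$domain,
                 reduction_factor = meta$reduction_factor %||% NA_real_,
                 fusion = as.list(meta$fusion))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname tomo_io
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "tomo_volume"))
  d <- dim(vol$voxels)
  pages <- lapply(seq_len(d[2]), function(y) vol$voxels[, y, ])
  write_tiff_stack(pages, path, "float32")
  est <- attr(vol, "axis_estimate")
  write_sidecar(list(kind = "volume", dims = d, voxel_size = vol$voxel_size,
                     unit = vol$unit,
                     axis_offset_x = if (!is.null(est)) est$offset_x), path)
  invisible(path)
}

#' @rdname tomo_io
#' @export
read_volume <- function(path) {
  meta <- read_sidecar(path, c("dims", "voxel_size"))
  arr <- read_tiff_stack(path)  # (x, z, y-page)
  if (dim(arr)[3] != meta$dims[2])
    stop(sprintf("'%s' has %d pages but the sidecar declares %d rows",
                 path, dim(arr)[3], meta$dims[2]))
  tomo_volume(aperm(arr, c(1, 3, 2)), meta$voxel_size, meta$unit %||% "")
}

#' @rdname tomo_io
#' @export
write_spim_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spim_stack"))
  write_tiff_stack(stack$slices, path, "float32")
  write_sidecar(list(kind = "spim_stack", z_spacing = stack$z_spacing,
                     angle = stack$angle, pixel_size = stack$pixel_size),
                path)
  invisible(path)
}

#' @rdname tomo_io
#' @export
read_spim_stack <- function(path) {
  meta <- read_sidecar(path, c("z_spacing", "angle", "pixel_size"))
  spim_stack(read_tiff_stack(path), meta$z_spacing, meta$angle,
             meta$pixel_size)
}

#' Pipeline configuration
#'
#' A nested parameter list describing an end-to-end run: phantom, optics,
#' spiral trajectory, fusion, reconstruction and registration settings plus
#' the master seed. Every block is validated against its module's
#' constructors before any computation starts. The JSON on-disk form
#' round-trips through [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... Named blocks overriding the defaults (see the example config
#'   produced by `pipeline_config()` itself).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    phantom = list(type = "example", extent = c(400, 400, 400),
                   voxel_size = 2.5),
    optics = list(),
    spiral = list(n_rotations = 20, angular_step = 1,
                  z_start = -250, z_end = 250, axis_offset_x = 0),
    fusion = list(hp_sigma = 2, smooth_sigma = 4),
    reconstruction = list(filter = "ramp", axis = "auto", search_range = 20,
                          log_transform = TRUE),
    registration = list(enabled = TRUE, z_spacing = 2, axis_z_offset = 30,
                        spim_sigma0 = 1),
    io = list(save_frames = FALSE))
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config block(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]]))
      utils::modifyList(defaults[[nm]], as.list(over[[nm]])) else over[[nm]]
  }
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  do.call(optics_params, cfg$optics)
  do.call(spiral_params, cfg$spiral)
  stopifnot(cfg$phantom$voxel_size > 0, length(cfg$phantom$extent) == 3,
            cfg$registration$z_spacing > 0, cfg$seed == round(cfg$seed))
  if (!cfg$phantom$type %in% c("example", "custom"))
    stop("phantom$type must be 'example' or 'custom'")
  if (cfg$phantom$type == "custom" && is.null(cfg$phantom$primitives))
    stop("custom phantom requires a primitives list")
  invisible(cfg)
}

config_phantom_spec <- function(cfg) {
  if (cfg$phantom$type == "example") {
    example_phantom(cfg$phantom$extent)
  } else {
    prims <- lapply(cfg$phantom$primitives, function(p) {
      if (identical(p$shape, "sphere"))
        primitive_sphere(p$center, p$radius, p$attenuation %||% 0,
                         p$fluorescence %||% 0, p$label %||% "sphere")
      else
        primitive_ellipsoid(p$center, p$semi_axes, p$attenuation %||% 0,
                            p$fluorescence %||% 0, p$label %||% "ellipsoid")
    })
    phantom_spec(prims, cfg$phantom$extent)
  }
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(raw)
}
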