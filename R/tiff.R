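# Minimal classic TIFF (little-endian, uncompressed, single-sample) writer and
# reader. The installed R stack has no TIFF package, so the subset of the
# format this pipeline needs -- multi-page stacks of uint8/uint16/float32
# grayscale images -- is implemented here directly. Written files are plain
# baseline TIFF readable by Fiji/tifffile.

tiff_types <- list(
  uint8   = list(bits =  8L, fmt = 1L, bytes = 1L),
  uint16  = list(bits = 16L, fmt = 1L, bytes = 2L),
  float32 = list(bits = 32L, fmt = 3L, bytes = 4L))

w2 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
w4 <- function(con, x) writeBin(as.integer(x), con, size = 4, endian = "little")

# one 12-byte IFD entry; type 3 = SHORT, 4 = LONG
tiff_entry <- function(con, tag, type, count, value) {
  w2(con, tag); w2(con, type); w4(con, count)
  if (type == 3L) { w2(con, value); w2(con, 0L) } else w4(con, value)
}

#' Write a stack of grayscale images as a multi-page TIFF
#'
#' @param pages 3D array (x, y, page) or list of matrices (x in rows).
#' @param path Output file.
#' @param type "uint8", "uint16" or "float32". Integer types are rounded and
#'   clamped to their range.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(pages, path, type = c("float32", "uint16",
                                                   "uint8")) {
  type <- match.arg(type)
  tt <- tiff_types[[type]]
  if (is.array(pages) && length(dim(pages)) == 3)
    pages <- lapply(seq_len(dim(pages)[3]), function(k) pages[, , k])
  stopifnot(length(pages) >= 1)
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  for (p in pages) stopifnot(nrow(p) == nx, ncol(p) == ny)
  np <- length(pages)
  strip_bytes <- nx * ny * tt$bytes
  ifd_bytes <- 2L + 10L * 12L + 4L
  ifd0 <- 8 + np * strip_bytes
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); w2(con, 42L); w4(con, ifd0)
  for (p in pages) {
    v <- as.vector(p)  # column-major = TIFF rows (y) of contiguous x
    if (type == "uint8") {
      writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
    } else if (type == "uint16") {
      iv <- as.integer(pmin(pmax(round(v), 0), 65535))
      writeBin(as.raw(rbind(iv %% 256L, iv %/% 256L)), con)
    } else {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    }
  }
  for (k in seq_len(np)) {
    w2(con, 10L)
    tiff_entry(con, 256L, 4L, 1L, nx)                      # ImageWidth
    tiff_entry(con, 257L, 4L, 1L, ny)                      # ImageLength
    tiff_entry(con, 258L, 3L, 1L, tt$bits)                 # BitsPerSample
    tiff_entry(con, 259L, 3L, 1L, 1L)                      # Compression
    tiff_entry(con, 262L, 3L, 1L, 1L)                      # Photometric
    tiff_entry(con, 273L, 4L, 1L, 8 + (k - 1) * strip_bytes) # StripOffsets
    tiff_entry(con, 277L, 3L, 1L, 1L)                      # SamplesPerPixel
    tiff_entry(con, 278L, 4L, 1L, ny)                      # RowsPerStrip
    tiff_entry(con, 279L, 4L, 1L, strip_bytes)             # StripByteCounts
    tiff_entry(con, 339L, 3L, 1L, tt$fmt)                  # SampleFormat
    w4(con, if (k < np) ifd0 + k * ifd_bytes else 0L)
  }
  invisible(path)
}

r2 <- function(con, n = 1) readBin(con, integer(), n, size = 2,
                                   signed = FALSE, endian = "little")
r4 <- function(con, n = 1) readBin(con, integer(), n, size = 4,
                                   endian = "little")

# parse all IFDs; returns list of per-page descriptors
tiff_index <- function(path) {
  fsize <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, raw(), 2)
  if (!identical(rawToChar(magic), "II"))
    stop("only little-endian TIFF is supported: ", path)
  if (r2(con) != 42L) stop("not a TIFF file: ", path)
  nxt <- r4(con)
  pages <- list()
  while (nxt != 0) {
    if (nxt + 2 > fsize)
      stop(sprintf("truncated TIFF '%s': IFD for page %d beyond end of file",
                   path, length(pages) + 1))
    seek(con, nxt)
    nent <- r2(con)
    tags <- list()
    for (e in seq_len(nent)) {
      tag <- r2(con); type <- r2(con); count <- r4(con)
      here <- seek(con)
      size1 <- switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L,
                      "4" = 4L, 4L)
      vals <- if (as.numeric(count) * size1 <= 4) {
        v <- if (type == 3L) r2(con, count) else r4(con, count)
        seek(con, here + 4)
        v
      } else {
        off <- r4(con)
        at <- seek(con)
        seek(con, off)
        v <- if (type == 3L) r2(con, count) else r4(con, count)
        seek(con, at)
        v
      }
      tags[[as.character(tag)]] <- vals
    }
    nxt2 <- r4(con)
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (!identical(g(259L, 1L), 1L))
      stop("compressed TIFF is not supported: ", path)
    pages[[length(pages) + 1]] <- list(
      width = g(256L), height = g(257L), bits = g(258L, 1L),
      fmt = g(339L, 1L), offsets = g(273L), counts = g(279L))
    nxt <- nxt2
  }
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    if (any(p$offsets + p$counts > fsize))
      stop(sprintf(
        "truncated TIFF '%s': pixel data of page %d of %d beyond end of file",
        path, k, length(pages)))
  }
  pages
}

tiff_read_page <- function(con, p) {
  chunks <- lapply(seq_along(p$offsets), function(i) {
    seek(con, p$offsets[i])
    n_bytes <- p$counts[i]
    if (p$fmt == 3L && p$bits == 32L) {
      readBin(con, numeric(), n_bytes / 4, size = 4, endian = "little")
    } else if (p$bits == 16L) {
      readBin(con, integer(), n_bytes / 2, size = 2, signed = FALSE,
              endian = "little")
    } else if (p$bits == 8L) {
      as.integer(readBin(con, raw(), n_bytes))
    } else stop(sprintf("unsupported TIFF sample: %d bits, format %d",
                        p$bits, p$fmt))
  })
  matrix(as.numeric(unlist(chunks)), p$width, p$height)
}

#' Read a multi-page grayscale TIFF into a 3D array
#'
#' Supports the uncompressed little-endian uint8/uint16/float32 files this
#' package writes (and equivalents from other tools).
#'
#' @param path TIFF file.
#' @return 3D array (x, y, page).
#' @export
read_tiff_stack <- function(path) {
  idx <- tiff_index(path)
  con <- file(path, "rb")
  on.exit(close(con))
  pages <- lapply(idx, function(p) tiff_read_page(con, p))
  nx <- nrow(pages[[1]]); ny <- ncol(pages[[1]])
  array(unlist(pages), c(nx, ny, length(pages)))
}
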