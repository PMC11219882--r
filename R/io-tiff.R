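#' Minimal multi-page 16-bit TIFF reader/writer
#'
#' The package reads and writes uncompressed baseline TIFF: grayscale,
#' 8- or 16-bit, one image per IFD ("page"), any number of pages. This is
#' the subset produced by Fiji/ImageJ "Save as Tiff" for single-channel
#' stacks and by the simulator here. Compressed, tiled, planar-RGB or
#' BigTIFF inputs are rejected with an explanatory error.
#'
#' @name tiff-io
#' @keywords internal
NULL

.tif_entry <- function(con, tag, type, count, value) {
  writeBin(as.integer(tag), con, size = 2, endian = "little")
  writeBin(as.integer(type), con, size = 2, endian = "little")
  writeBin(as.integer(count), con, size = 4, endian = "little")
  if (type == 3L) { # SHORT packed into 4-byte value field
    v <- as.integer(value)
    writeBin(ifelse(v > 32767L, v - 65536L, v), con, size = 2,
             endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  } else {
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' @param frames A list of numeric/integer matrices (all the same
#'   dimensions) or a 3D array `[H, W, T]`. Values must lie in
#'   \[0, 65535\]; they are rounded to integers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(frames, path) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  for (fr in frames)
    if (nrow(fr) != H || ncol(fr) != W)
      stop("all frames must share the same dimensions")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("II", con, nchars = 2, eos = NULL)
  writeBin(42L, con, size = 2, endian = "little")
  n_tags <- 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  strip_bytes <- H * W * 2L
  offset <- 8L
  writeBin(offset, con, size = 4, endian = "little")
  for (k in seq_along(frames)) {
    data_off <- offset + ifd_size
    next_off <- if (k < length(frames)) data_off + strip_bytes else 0L
    writeBin(n_tags, con, size = 2, endian = "little")
    .tif_entry(con, 256, 4, 1, W)                 # ImageWidth
    .tif_entry(con, 257, 4, 1, H)                 # ImageLength
    .tif_entry(con, 258, 3, 1, 16)                # BitsPerSample
    .tif_entry(con, 259, 3, 1, 1)                 # Compression: none
    .tif_entry(con, 262, 3, 1, 1)                 # Photometric: min-is-black
    .tif_entry(con, 273, 4, 1, data_off)          # StripOffsets
    .tif_entry(con, 278, 4, 1, H)                 # RowsPerStrip
    .tif_entry(con, 279, 4, 1, strip_bytes)       # StripByteCounts
    .tif_entry(con, 339, 3, 1, 1)                 # SampleFormat: unsigned
    writeBin(as.integer(next_off), con, size = 4, endian = "little")
    v <- as.integer(round(t(frames[[k]])))        # scanline (row-major) order
    if (any(v < 0 | v > 65535))
      stop("pixel values outside the 16-bit range [0, 65535]")
    writeBin(ifelse(v > 32767L, v - 65536L, v), con, size = 2,
             endian = "little")
    offset <- data_off + strip_bytes
  }
  invisible(path)
}

.read_exact <- function(con, what, n, size, endian, signed = TRUE) {
  v <- readBin(con, what, n = n, size = size, endian = endian,
               signed = signed)
  if (length(v) != n) stop("truncated TIFF file")
  v
}

.tif_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

.read_ifd_values <- function(con, type, count, endian) {
  size <- .tif_type_size[[as.character(type)]]
  if (is.null(size)) stop("unsupported TIFF field type ", type)
  total <- size * count
  here <- seek(con)
  if (total > 4) {
    off <- .read_exact(con, integer(), 1, 4, endian)
    seek(con, off)
  }
  vals <- switch(as.character(size),
    `1` = .read_exact(con, integer(), count, 1, endian, signed = FALSE),
    `2` = .read_exact(con, integer(), count, 2, endian, signed = FALSE),
    `4` = .read_exact(con, integer(), count, 4, endian),
    `8` = .read_exact(con, integer(), 2 * count, 4, endian))
  seek(con, here + 4)
  vals
}

#' Read a multi-page TIFF stack
#'
#' @param path Path to an uncompressed grayscale baseline TIFF.
#' @param allow_8bit If `TRUE`, 8-bit pages are widened to the 16-bit
#'   integer range's low end (values kept, no rescaling); if `FALSE`
#'   (default) 8-bit input is rejected with a remediation hint.
#' @return A list of integer matrices (one per page).
#' @export
read_stack <- function(path, allow_8bit = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2, useBytes = TRUE)
  endian <- if (identical(magic, "II")) "little"
            else if (identical(magic, "MM")) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path)
  forty2 <- .read_exact(con, integer(), 1, 2, endian)
  if (forty2 != 42) stop("not a classic TIFF (BigTIFF is unsupported)")
  ifd_off <- .read_exact(con, integer(), 1, 4, endian)
  pages <- list()
  while (ifd_off != 0) {
    seek(con, ifd_off)
    n_tags <- .read_exact(con, integer(), 1, 2, endian)
    tags <- list()
    for (i in seq_len(n_tags)) {
      tag <- .read_exact(con, integer(), 1, 2, endian, signed = FALSE)
      type <- .read_exact(con, integer(), 1, 2, endian, signed = FALSE)
      count <- .read_exact(con, integer(), 1, 4, endian)
      tags[[as.character(tag)]] <- .read_ifd_values(con, type, count, endian)
    }
    ifd_off <- .read_exact(con, integer(), 1, 4, endian)
    W <- tags[["256"]][1]; H <- tags[["257"]][1]
    if (is.null(W) || is.null(H)) stop("TIFF page missing dimensions")
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]][1]
    if (comp != 1)
      stop("compressed TIFF unsupported; re-save uncompressed ",
           "(e.g. Fiji > Save As > Tiff)")
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]][1]
    if (!bits %in% c(8L, 16L))
      stop("only 8- or 16-bit grayscale TIFF supported (got ", bits, "-bit)")
    if (bits == 8L && !allow_8bit)
      stop("8-bit TIFF: pass allow_8bit = TRUE to accept, or convert the ",
           "stack to 16-bit")
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]][1]
    if (spp != 1) stop("multi-sample (RGB) TIFF unsupported; split channels")
    offs <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offs)) stop("TIFF page missing strip offsets")
    if (is.null(counts)) counts <- rep(H * W * bits / 8 / length(offs),
                                       length(offs))
    vals <- integer(0)
    for (s in seq_along(offs)) {
      seek(con, offs[s])
      n <- counts[s] / (bits / 8)
      vals <- c(vals, .read_exact(con, integer(), n, bits / 8, endian,
                                  signed = FALSE))
    }
    if (length(vals) != H * W) stop("truncated TIFF strip data")
    pages[[length(pages) + 1L]] <- t(matrix(vals, nrow = W, ncol = H))
  }
  pages
}

#' @rdname tiff-io
#' @param labels,path See [write_stack()]/[read_stack()]; label movies are
#'   stored as unsigned 16-bit integer TIFF.
#' @export
write_labels <- function(labels, path) write_stack(labels, path)

#' @rdname tiff-io
#' @export
read_labels <- function(path) {
  lapply(read_stack(path), function(m) {
    storage.mode(m) <- "integer"
    m
  })
}
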