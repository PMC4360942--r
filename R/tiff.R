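## Minimal baseline TIFF codec: uncompressed greyscale, 8/16-bit unsigned
## or 32-bit float, single- or multi-page, strip-organized.  Written by hand
## because the pre-installed R stack carries no TIFF package; read support
## covers both byte orders and the strip layouts mainstream writers
## (ImageJ, tifffile) produce for such images.

TIFF_TYPE_BYTES <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L)

## ---- writing -------------------------------------------------------------

w_int <- function(con, x, size) {
  x <- as.numeric(x)
  half <- 2^(8 * size - 1)
  x <- ifelse(x >= half, x - 2 * half, x)   # two's complement for u16/u32
  writeBin(as.integer(x), con, size = size, endian = "little")
}

#' Write a greyscale TIFF
#'
#' Writes one matrix (or a list of matrices as a multi-page stack) as an
#' uncompressed little-endian greyscale TIFF.
#'
#' @param pages A numeric matrix or list of equally sized matrices.
#' @param path Output path.
#' @param sample_format `"uint"` (8 or 16 bits) or `"float"` (32-bit).
#' @param bits Bits per sample: 8 or 16 for `"uint"` (default 16), fixed 32
#'   for `"float"`.
#' @param description Optional text stored in the ImageDescription tag of
#'   the first page (photonsim records pixel units here).
#' @return `path`, invisibly.
#' @seealso [read_tiff()], [read_concatenated_tiff()]
#' @export
write_tiff <- function(pages, path, sample_format = c("uint", "float"),
                       bits = NULL, description = NULL) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) ps_io_error("no pages to write.")
  dims <- dim(pages[[1]])
  for (p in pages) {
    if (!is.matrix(p) || !identical(dim(p), dims)) {
      ps_io_error("all TIFF pages must be equally sized matrices.")
    }
  }
  if (sample_format == "float") {
    bits <- 32L
  } else {
    bits <- as.integer(bits %||% 16L)
    if (!bits %in% c(8L, 16L)) {
      ps_parameter_error("uint TIFF output supports 8 or 16 bits per sample.")
    }
    rng <- range(vapply(pages, range, numeric(2)))
    if (rng[1] < 0 || rng[2] > 2^bits - 1) {
      ps_io_error(sprintf(
        "pixel values [%.4g, %.4g] do not fit %d-bit unsigned samples.",
        rng[1], rng[2], bits))
    }
  }
  sf_code <- if (sample_format == "float") 3L else 1L
  m <- dims[1]; n <- dims[2]
  bytes_px <- bits %/% 8L
  data_len <- m * n * bytes_px

  desc_raw <- NULL
  if (!is.null(description)) {
    desc_raw <- c(charToRaw(as.character(description)), as.raw(0))
    if (length(desc_raw) %% 2L == 1L) desc_raw <- c(desc_raw, as.raw(0))
  }

  n_pages <- length(pages)
  n_entries <- ifelse(seq_len(n_pages) == 1L & !is.null(desc_raw), 11L, 10L)
  ifd_len <- 2L + 12L * n_entries + 4L

  off <- 8L
  desc_off <- 0L
  if (!is.null(desc_raw)) { desc_off <- off; off <- off + length(desc_raw) }
  data_off <- ifd_off <- integer(n_pages)
  for (k in seq_len(n_pages)) {
    data_off[k] <- off; off <- off + data_len
    ifd_off[k] <- off; off <- off + ifd_len[k]
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  w_int(con, 42, 2)
  w_int(con, ifd_off[1], 4)
  if (!is.null(desc_raw)) writeBin(desc_raw, con)

  entry <- function(tag, type, count, value) {
    w_int(con, tag, 2); w_int(con, type, 2); w_int(con, count, 4)
    if (type == 3L) { w_int(con, value, 2); w_int(con, 0, 2) }
    else w_int(con, value, 4)
  }
  for (k in seq_len(n_pages)) {
    vals <- as.vector(t(pages[[k]]))   # TIFF strips are row-major
    if (sample_format == "float") {
      writeBin(as.numeric(vals), con, size = 4, endian = "little")
    } else {
      w_int(con, round(vals), bytes_px)
    }
    w_int(con, n_entries[k], 2)
    entry(256, 4, 1, n)          # ImageWidth
    entry(257, 4, 1, m)          # ImageLength
    entry(258, 3, 1, bits)       # BitsPerSample
    entry(259, 3, 1, 1)          # Compression: none
    entry(262, 3, 1, 1)          # Photometric: BlackIsZero
    if (n_entries[k] == 11L) entry(270, 2, length(desc_raw), desc_off)
    entry(273, 4, 1, data_off[k])   # StripOffsets
    entry(277, 3, 1, 1)             # SamplesPerPixel
    entry(278, 4, 1, m)             # RowsPerStrip
    entry(279, 4, 1, data_len)      # StripByteCounts
    entry(339, 3, 1, sf_code)       # SampleFormat
    w_int(con, if (k < n_pages) ifd_off[k + 1] else 0L, 4)
  }
  invisible(path)
}

## ---- reading -------------------------------------------------------------

rd_uint <- function(r, pos, size, n = 1L, endian = "little") {
  ## pos: 1-based offset of the first byte
  v <- readBin(r[pos:(pos + size * n - 1L)], "integer", n = n, size = size,
               signed = size == 4L, endian = endian)
  if (size == 4L) v <- ifelse(v < 0, v + 2^32, v)
  v
}

#' Read a greyscale TIFF
#'
#' Reads an uncompressed greyscale TIFF (8/16-bit unsigned or 32-bit
#' float, single- or multi-page, either byte order).  Colour, palette,
#' compressed, or tiled files are rejected with a format error; convert
#' such data to plain greyscale before loading.
#'
#' @param path File path.
#' @return A list: `pages` (list of numeric matrices), `bits`,
#'   `sample_format` (`"uint"` or `"float"`), `n_pages`, and `description`
#'   (ImageDescription of the first page, or `NA`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) ps_io_error(sprintf("file not found: %s", path))
  r <- readBin(path, "raw", n = file.size(path))
  if (length(r) < 8L) ps_format_error(sprintf("not a TIFF file: %s", path))
  order_tag <- rawToChar(r[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   ps_format_error(sprintf("not a TIFF file: %s", path)))
  if (rd_uint(r, 3, 2, endian = endian) != 42) {
    ps_format_error(sprintf("not a TIFF file (bad magic): %s", path))
  }
  ifd_off <- rd_uint(r, 5, 4, endian = endian)
  pages <- list()
  description <- NA_character_
  bits_out <- sf_out <- NULL
  while (ifd_off != 0) {
    n_ent <- rd_uint(r, ifd_off + 1, 2, endian = endian)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2L + 12L * (e - 1L)
      tag <- rd_uint(r, base + 1, 2, endian = endian)
      type <- rd_uint(r, base + 3, 2, endian = endian)
      count <- rd_uint(r, base + 5, 4, endian = endian)
      tags[[as.character(tag)]] <- list(type = type, count = count,
                                        vpos = base + 9L)
    }
    getv <- function(tag, default = NULL) {
      tg <- tags[[as.character(tag)]]
      if (is.null(tg)) return(default)
      tb <- TIFF_TYPE_BYTES[as.character(tg$type)]
      if (is.na(tb)) return(default)
      total <- tb * tg$count
      pos <- if (total <= 4L) tg$vpos
             else rd_uint(r, tg$vpos, 4, endian = endian) + 1L
      if (tg$type == 2L) {
        bytes <- r[pos:(pos + tg$count - 1L)]
        nul <- which(bytes == as.raw(0))
        if (length(nul)) bytes <- bytes[seq_len(nul[1] - 1L)]
        return(rawToChar(bytes))
      }
      rd_uint(r, pos, tb, n = tg$count, endian = endian)
    }
    width <- getv(256); height <- getv(257)
    if (is.null(width) || is.null(height)) {
      ps_format_error("TIFF page lacks width/height tags.")
    }
    bits <- getv(258, 1L)[1]
    compression <- getv(259, 1L)
    photometric <- getv(262, 1L)
    samples <- getv(277, 1L)
    sf <- getv(339, 1L)[1]
    if (!is.null(getv(322))) {
      ps_format_error("tiled TIFFs are not supported; save with strip layout.")
    }
    if (compression != 1L) {
      ps_format_error(sprintf(
        "compressed TIFF (compression code %d) is not supported; save uncompressed.",
        compression))
    }
    if (samples != 1L || !photometric %in% c(0L, 1L)) {
      ps_format_error(
        "only single-channel greyscale TIFFs are supported; convert RGB/palette images to greyscale.")
    }
    if (!bits %in% c(8L, 16L, 32L)) {
      ps_format_error(sprintf("unsupported bits per sample: %d (need 8, 16 or 32).",
                              bits))
    }
    if (!sf %in% c(1L, 3L)) {
      ps_format_error(sprintf("unsupported TIFF sample format code %d.", sf))
    }
    if (bits == 32L && sf == 1L) {
      ps_format_error("32-bit unsigned integer TIFFs are not supported.")
    }
    strip_off <- getv(273); strip_cnt <- getv(279)
    if (is.null(strip_off) || is.null(strip_cnt)) {
      ps_format_error("TIFF page lacks strip offsets/byte counts.")
    }
    payload <- unlist(lapply(seq_along(strip_off), function(s) {
      r[(strip_off[s] + 1L):(strip_off[s] + strip_cnt[s])]
    }), use.names = FALSE)
    npx <- width * height
    vals <- if (sf == 3L) {
      readBin(payload, "numeric", n = npx, size = 4, endian = endian)
    } else {
      as.numeric(rd_uint(payload, 1L, bits %/% 8L, n = npx, endian = endian))
    }
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = height, ncol = width,
                                          byrow = TRUE)
    if (length(pages) == 1L) description <- getv(270, NA_character_)
    bits_out <- bits; sf_out <- sf
    ifd_off <- rd_uint(r, ifd_off + 2L + 12L * n_ent + 1L, 4, endian = endian)
  }
  if (!length(pages)) ps_format_error(sprintf("TIFF has no pages: %s", path))
  list(pages = pages, bits = bits_out,
       sample_format = if (sf_out == 3L) "float" else "uint",
       n_pages = length(pages), description = description)
}

#' Read a row-concatenated SIM TIFF (2D triplet or 3D stack)
#'
#' Reads a greyscale TIFF and validates the raw SIM acquisition layout:
#' every page must be 3M x N (three phase images stacked row-wise), all
#' pages equally sized.  Page order is depth order for 3D data.
#'
#' @param path File path.
#' @param expected_layout `"auto"` (any page count), `"triplet"` (exactly
#'   one page) or `"stack"` (one page per depth).
#' @return A list: `pages` (list of 3M x N matrices), `n_pages`, `rows`,
#'   `cols`, `bits`, `sample_format`, `description`.
#' @export
read_concatenated_tiff <- function(path,
                                   expected_layout = c("auto", "triplet", "stack")) {
  expected_layout <- match.arg(expected_layout)
  tf <- read_tiff(path)
  dims <- dim(tf$pages[[1]])
  for (i in seq_along(tf$pages)) {
    if (!identical(dim(tf$pages[[i]]), dims)) {
      ps_stack_error(sprintf(
        "page %d is %d x %d but page 1 is %d x %d; all depths must match.",
        i, nrow(tf$pages[[i]]), ncol(tf$pages[[i]]), dims[1], dims[2]))
    }
  }
  if (dims[1] %% 3L != 0L) {
    ps_layout_error(sprintf(
      "expected three row-concatenated phase images (rows divisible by 3); got %d x %d.",
      dims[1], dims[2]))
  }
  if (expected_layout == "triplet" && tf$n_pages != 1L) {
    ps_layout_error(sprintf(
      "expected a single-page 2D triplet but the file has %d pages.", tf$n_pages))
  }
  list(pages = tf$pages, n_pages = tf$n_pages,
       rows = dims[1], cols = dims[2], bits = tf$bits,
       sample_format = tf$sample_format, description = tf$description)
}
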