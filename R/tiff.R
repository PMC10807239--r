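# Minimal baseline TIFF codec (little-endian, uncompressed, one strip per
# page written; multi-strip pages accepted on read). Supports 8/16-bit
# unsigned and 32-bit float samples, 1 (grayscale) or 3 (RGB) samples per
# pixel, and an ImageDescription string on the first page. This exists
# because no TIFF package ships with the target R installation; the format
# subset is the one interoperable with tifffile/ImageJ.

TIFF_BYTES <- c(uint8 = 1L, uint16 = 2L, float32 = 4L)

tiff_pixel_bytes <- function(page, fmt, spp) {
  d <- dim(page)
  as.integer(d[1]) * as.integer(d[2]) * spp * TIFF_BYTES[[fmt]]
}

# serialize one page row-major (TIFF order); RGB interleaved per pixel
tiff_serialize_page <- function(con, page, fmt) {
  d <- dim(page)
  if (length(d) == 3) {
    v <- as.vector(aperm(page, c(3, 2, 1)))
  } else {
    v <- as.vector(t(page))
  }
  if (fmt == "uint8") {
    writeBin(as.raw(pmin(pmax(round(v), 0), 255)), con)
  } else if (fmt == "uint16") {
    iv <- as.integer(pmin(pmax(round(v), 0), 65535))
    iv <- ifelse(iv > 32767L, iv - 65536L, iv)
    writeBin(iv, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(v), con, size = 4, endian = "little")
  }
}

tiff_entry <- function(tag, type, count, value_or_offset) {
  # returns list for later emission; value_or_offset is the 4-byte payload
  list(tag = as.integer(tag), type = as.integer(type),
       count = as.integer(count), val = value_or_offset)
}

emit_u16 <- function(con, x) writeBin(as.integer(x), con, size = 2, endian = "little")
emit_u32 <- function(con, x) {
  x <- as.numeric(x)
  lo <- x %% 65536
  hi <- x %/% 65536
  emit_u16(con, lo)
  emit_u16(con, hi)
}

#' Write a multi-page TIFF
#'
#' @param path output file.
#' @param pages a list of numeric matrices (grayscale) or `h x w x 3` arrays
#'   (RGB), all of equal size, or a 3D array `(n_pages, h, w)`.
#' @param sample_format `"uint8"`, `"uint16"` or `"float32"`.
#' @param description optional string stored as ImageDescription of page 1
#'   (used for JSON metadata).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, sample_format = "uint8", description = NULL) {
  if (is.array(pages) && length(dim(pages)) == 3 && !is.list(pages)) {
    pages <- lapply(seq_len(dim(pages)[1]), function(z) pages[z, , ])
  }
  if (!is.list(pages) || !length(pages)) stopf("pages must be a non-empty list")
  fmt <- match.arg(sample_format, names(TIFF_BYTES))
  spp <- if (length(dim(pages[[1]])) == 3) 3L else 1L
  h <- dim(pages[[1]])[1]; w <- dim(pages[[1]])[2]
  for (p in pages) {
    if (!all(dim(p)[1:2] == c(h, w))) stopf("all pages must share one size")
  }
  n <- length(pages)
  bps <- TIFF_BYTES[[fmt]] * 8L
  sfmt <- if (fmt == "float32") 3L else 1L
  desc_raw <- if (!is.null(description)) c(charToRaw(description), as.raw(0)) else raw(0)
  if (length(desc_raw) %% 2) desc_raw <- c(desc_raw, as.raw(0))

  # layout: header | page data blocks | ext area (desc, rgb bps) | IFDs
  data_bytes <- vapply(pages, tiff_pixel_bytes, integer(1), fmt = fmt, spp = spp)
  data_bytes_pad <- data_bytes + data_bytes %% 2
  data_off <- 8 + cumsum(c(0, data_bytes_pad[-n]))
  ext_off <- 8 + sum(data_bytes_pad)
  desc_off <- ext_off
  bps_arr_off <- ext_off + length(desc_raw)
  ext_len <- length(desc_raw) + if (spp == 3L) 6L else 0L
  if (ext_len %% 2) ext_len <- ext_len + 1L
  ifd0 <- ext_off + ext_len

  n_entries <- function(i) 10L + (spp == 3L) + (i == 1L && length(desc_raw) > 0)
  ifd_len <- function(i) 2L + 12L * n_entries(i) + 4L
  ifd_offs <- ifd0 + cumsum(c(0, vapply(seq_len(n - 1), ifd_len, integer(1))))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  emit_u16(con, 42)
  emit_u32(con, ifd_offs[1])
  for (i in seq_len(n)) tiff_serialize_page(con, pages[[i]], fmt)
  # ext area
  if (length(desc_raw)) writeBin(desc_raw, con)
  if (spp == 3L) emit_u16(con, c(bps, bps, bps))
  if ((length(desc_raw) + if (spp == 3L) 6L else 0L) %% 2) writeBin(as.raw(0), con)

  for (i in seq_len(n)) {
    ents <- list(
      tiff_entry(256, 4, 1, w),
      tiff_entry(257, 4, 1, h),
      if (spp == 3L) tiff_entry(258, 3, 3, bps_arr_off) else tiff_entry(258, 3, 1, bps),
      tiff_entry(259, 3, 1, 1),
      tiff_entry(262, 3, 1, if (spp == 3L) 2 else 1)
    )
    if (i == 1L && length(desc_raw))
      ents <- c(ents, list(tiff_entry(270, 2, length(desc_raw), desc_off)))
    ents <- c(ents, list(
      tiff_entry(273, 4, 1, data_off[i]),
      tiff_entry(277, 3, 1, spp),
      tiff_entry(278, 4, 1, h),
      tiff_entry(279, 4, 1, data_bytes[i]),
      tiff_entry(339, 3, 1, sfmt)
    ))
    emit_u16(con, length(ents))
    for (e in ents) {
      emit_u16(con, e$tag)
      emit_u16(con, e$type)
      emit_u32(con, e$count)
      if (e$type == 3 && e$count == 1) {  # SHORT packed left-justified
        emit_u16(con, e$val); emit_u16(con, 0)
      } else {
        emit_u32(con, e$val)
      }
    }
    emit_u32(con, if (i < n) ifd_offs[i + 1] else 0)
  }
  invisible(path)
}

read_u16 <- function(raw, off) {  # off is 0-based
  as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
}
read_u32 <- function(raw, off) {
  as.numeric(read_u16(raw, off)) + 65536 * read_u16(raw, off + 2)
}

#' Read a multi-page TIFF
#'
#' Accepts the uncompressed little-endian subset written by [write_tiff()]
#' (and by common scientific writers at default settings).
#'
#' @param path TIFF file.
#' @return list with `pages` (list of matrices or `h x w x 3` arrays) and
#'   `description` (string or `NULL`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || read_u16(raw, 2) != 42L)
    stopf("not a little-endian TIFF: %s", path)
  type_bytes <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)
  off <- read_u32(raw, 4)
  pages <- list()
  description <- NULL
  while (off != 0) {
    ne <- read_u16(raw, off)
    tags <- list()
    for (k in seq_len(ne)) {
      e <- off + 2 + 12 * (k - 1)
      tag <- read_u16(raw, e)
      type <- read_u16(raw, e + 2)
      count <- read_u32(raw, e + 4)
      nb <- type_bytes[type] * count
      voff <- if (nb <= 4) e + 8 else read_u32(raw, e + 8)
      vals <- switch(as.character(type),
        "3" = vapply(seq_len(count), function(m) read_u16(raw, voff + 2 * (m - 1)), integer(1)),
        "4" = vapply(seq_len(count), function(m) read_u32(raw, voff + 4 * (m - 1)), numeric(1)),
        "2" = rawToChar(raw[(voff + 1):(voff + count - 1)]),
        NULL)
      tags[[as.character(tag)]] <- vals
    }
    gt <- function(tag, default = NULL) tags[[as.character(tag)]] %||% default
    w <- gt(256); h <- gt(257)
    if (is.null(w) || is.null(h)) stopf("TIFF page missing dimensions")
    if (gt(259, 1)[1] != 1) stopf("compressed TIFF not supported")
    if (gt(284, 1)[1] != 1) stopf("planar TIFF not supported")
    spp <- gt(277, 1)[1]
    if (!spp %in% c(1, 3)) stopf("unsupported samples per pixel: %d", spp)
    bps <- gt(258, 8)[1]
    sfmt <- gt(339, 1)[1]
    if (!is.null(gt(270)) && is.null(description)) description <- gt(270)
    strip_offs <- gt(273)
    strip_counts <- gt(279, (as.numeric(w) * h * spp * bps / 8))
    buf <- raw(0)
    for (s in seq_along(strip_offs))
      buf <- c(buf, raw[(strip_offs[s] + 1):(strip_offs[s] + strip_counts[s])])
    n_px <- as.integer(w) * as.integer(h) * as.integer(spp)
    v <- if (bps == 8) {
      as.integer(buf[seq_len(n_px)])
    } else if (bps == 16) {
      readBin(buf, "integer", n_px, size = 2, signed = FALSE, endian = "little")
    } else if (bps == 32 && identical(sfmt, 3L)) {
      readBin(buf, "double", n_px, size = 4, endian = "little")
    } else stopf("unsupported TIFF sample: %d-bit format %s", bps, sfmt)
    page <- if (spp == 3) {
      aperm(array(v, dim = c(3, w, h)), c(3, 2, 1))
    } else {
      t(matrix(v, nrow = w, ncol = h))
    }
    pages[[length(pages) + 1]] <- page
    off <- read_u32(raw, off + 2 + 12 * ne)
  }
  list(pages = pages, description = description)
}
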