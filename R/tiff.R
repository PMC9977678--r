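## Minimal baseline TIFF codec for single-channel integer label images:
## uncompressed, one sample per pixel, unsigned 8/16/32-bit. No R TIFF
## package is assumed; this covers exactly the raster interchange needed
## for label masks and nothing more (no compression, tiles, or colour).

tiff_uint <- function(raw, offset, size, endian) {
  ## offset is 0-based into `raw`
  b <- as.integer(raw[(offset + 1):(offset + size)])
  if (endian == "big") b <- rev(b)
  sum(b * 256^(seq_len(size) - 1))
}

read_tiff_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) sc_stop("not a TIFF file (too short)", "spatcoloc_format_error")
  byte_order <- rawToChar(raw[1:2])
  endian <- switch(byte_order, II = "little", MM = "big",
                   sc_stop("not a TIFF file (bad byte-order mark)",
                           "spatcoloc_format_error"))
  if (tiff_uint(raw, 2, 2, endian) != 42) {
    sc_stop("not a TIFF file (bad magic number)", "spatcoloc_format_error")
  }
  ifd <- tiff_uint(raw, 4, 4, endian)
  n_entries <- tiff_uint(raw, ifd, 2, endian)
  type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4)
  tags <- list()
  for (i in seq_len(n_entries)) {
    off <- ifd + 2 + (i - 1) * 12
    tag <- tiff_uint(raw, off, 2, endian)
    typ <- tiff_uint(raw, off + 2, 2, endian)
    cnt <- tiff_uint(raw, off + 4, 4, endian)
    sz <- type_size[as.character(typ)]
    if (is.na(sz)) next  # rational/other types: not needed for labels
    total <- sz * cnt
    voff <- if (total <= 4) off + 8 else tiff_uint(raw, off + 8, 4, endian)
    vals <- vapply(seq_len(cnt), function(k) {
      tiff_uint(raw, voff + (k - 1) * sz, sz, endian)
    }, numeric(1))
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) {
        sc_stop(sprintf("TIFF missing required tag %d", tag),
                "spatcoloc_format_error")
      }
      default
    } else v
  }
  width <- need(256); height <- need(257)
  bits <- need(258, 1)
  if (need(259, 1) != 1) {
    sc_stop("only uncompressed TIFF is supported", "spatcoloc_format_error")
  }
  if (need(277, 1) != 1) {
    sc_stop("only single-channel (1 sample/pixel) TIFF is supported",
            "spatcoloc_format_error")
  }
  fmt <- need(339, 1)
  if (fmt != 1) {
    sc_stop("only unsigned-integer TIFF samples are supported (labels must be integral)",
            "spatcoloc_format_error")
  }
  if (length(bits) != 1 || !(bits %in% c(8, 16, 32))) {
    sc_stop("only 8/16/32-bit TIFF samples are supported", "spatcoloc_format_error")
  }
  strip_off <- need(273)
  strip_cnt <- need(279)
  rows_per_strip <- need(278, height)
  bpp <- bits / 8
  px <- numeric(width * height)
  pos <- 0
  for (s in seq_along(strip_off)) {
    n_vals <- strip_cnt[s] / bpp
    con_off <- strip_off[s]
    vals <- readBin(raw[(con_off + 1):(con_off + strip_cnt[s])],
                    what = "integer", n = n_vals, size = bpp,
                    signed = bpp > 2, endian = endian)
    if (bpp <= 2) vals <- as.numeric(vals)
    if (any(vals < 0)) {
      sc_stop("TIFF labels exceed 2^31 - 1; not representable as R integers",
              "spatcoloc_format_error")
    }
    px[pos + seq_len(n_vals)] <- vals
    pos <- pos + n_vals
  }
  if (pos != width * height) {
    sc_stop("TIFF strip data does not cover the full image", "spatcoloc_format_error")
  }
  matrix(px, nrow = height, ncol = width, byrow = TRUE)
}

write_tiff_gray <- function(m, path) {
  stopifnot(is.matrix(m))
  v <- as.vector(t(m))  # row-major
  maxv <- if (length(v)) max(v) else 0
  bits <- if (maxv < 256) 8L else if (maxv < 65536) 16L else 32L
  bpp <- bits / 8L
  entries <- list(
    c(256, 4, 1, ncol(m)),           # ImageWidth
    c(257, 4, 1, nrow(m)),           # ImageLength
    c(258, 3, 1, bits),              # BitsPerSample
    c(259, 3, 1, 1),                 # Compression: none
    c(262, 3, 1, 1),                 # Photometric: BlackIsZero
    c(273, 4, 1, NA),                # StripOffsets (patched below)
    c(277, 3, 1, 1),                 # SamplesPerPixel
    c(278, 4, 1, nrow(m)),           # RowsPerStrip: single strip
    c(279, 4, 1, length(v) * bpp),   # StripByteCounts
    c(339, 3, 1, 1)                  # SampleFormat: unsigned
  )
  data_offset <- 8L + 2L + 12L * length(entries) + 4L
  entries[[6]][4] <- data_offset
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 4, endian = "little")          # first IFD at byte 8
  writeBin(length(entries), con, size = 2, endian = "little")
  for (e in entries) {
    writeBin(as.integer(e[1]), con, size = 2, endian = "little")
    writeBin(as.integer(e[2]), con, size = 2, endian = "little")
    writeBin(as.integer(e[3]), con, size = 4, endian = "little")
    if (e[2] == 3) {  # SHORT values are left-justified in the 4-byte slot
      writeBin(as.integer(e[4]), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(e[4]), con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little")          # no next IFD
  writeBin(as.integer(v), con, size = bpp, endian = "little")
  invisible(path)
}
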