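## Readers/writers for the delimited external formats. The canonical unit
## throughout the package is the micrometre; pixel-space inputs are converted
## at read time using the raster pixel size.

detect_sep <- function(header_line) {
  if (grepl("\t", header_line, fixed = TRUE)) "\t" else ","
}

#' Construct a transcript table
#'
#' One row per detected RNA molecule: slide and ROI identifiers, gene symbol
#' and 2D coordinates in um. All spatial operations downstream are confined
#' within one (slide_id, roi_id) unit.
#'
#' @param df data frame with columns `slide_id`, `roi_id`, `gene`, `x_um`,
#'   `y_um` (extra columns are kept).
#' @return the validated data frame with class `transcript_table` prepended.
#' @export
transcript_table <- function(df) {
  req <- c("slide_id", "roi_id", "gene", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    sc_stop(sprintf("transcript table is missing column(s): %s",
                    paste(miss, collapse = ", ")), "spatcoloc_format_error")
  }
  df$slide_id <- as.character(df$slide_id)
  df$roi_id <- as.character(df$roi_id)
  df$gene <- as.character(df$gene)
  if (nrow(df) > 0) {
    if (any(!nzchar(df$gene)) || anyNA(df$gene)) {
      sc_stop("transcript table has empty gene symbols", "spatcoloc_format_error")
    }
    bad <- !is.finite(df$x_um) | !is.finite(df$y_um) | df$x_um < 0 | df$y_um < 0
    if (any(bad)) {
      sc_stop(sprintf("transcript coordinates must be finite and >= 0 (%d bad row(s), first at row %d)",
                      sum(bad), which(bad)[1]), "spatcoloc_format_error")
    }
  }
  class(df) <- unique(c("transcript_table", class(df)))
  df
}

read_delim_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    sc_stop(sprintf("file not found: %s", path), "spatcoloc_io_error")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) {
    sc_stop(sprintf("file is empty (no header): %s", path), "spatcoloc_io_error")
  }
  sep <- detect_sep(header)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          quote = "\"", comment.char = "", stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    sc_stop(sprintf("%s: missing required column(s): %s", path,
                    paste(miss, collapse = ", ")), "spatcoloc_format_error")
  }
  for (col in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !(df[[col]] %in% c("NA", ""))
    bad <- bad | is.na(v)
    if (any(bad)) {
      ## +1 for the header line
      sc_stop(sprintf("%s: unparseable value '%s' in column '%s' at line %d",
                      path, df[[col]][which(bad)[1]], col, which(bad)[1] + 1L),
              "spatcoloc_format_error")
    }
    df[[col]] <- v
  }
  df
}

#' Read a transcript table from delimited text
#'
#' Accepts comma- or tab-separated text (auto-detected from the header line)
#' with header columns `slide_id, roi_id, gene, x_um, y_um` in any order.
#' Coordinates are decimal micrometres.
#'
#' @param path path to the file.
#' @return a [transcript_table()].
#' @export
read_transcript_table <- function(path) {
  df <- read_delim_checked(path,
                           required = c("slide_id", "roi_id", "gene", "x_um", "y_um"),
                           numeric_cols = c("x_um", "y_um"))
  transcript_table(df)
}

#' Write a transcript table to delimited text
#'
#' @param table a [transcript_table()].
#' @param path output path; `.tsv` extension selects tab separation,
#'   otherwise comma.
#' @return `path`, invisibly.
#' @export
write_transcript_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(table), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Construct a spot set
#'
#' Channel-tagged fluorescence spot centroids from upstream spot detection,
#' one row per spot with a tissue-core identifier and coordinates in um. The
#' z coordinate is either present for every spot or absent entirely; mixed
#' dimensionality within one set is rejected.
#'
#' @param channel channel name, e.g. `"green"` or `"red"`.
#' @param df data frame with columns `core_id`, `x_um`, `y_um` and optional
#'   `z_um`.
#' @return an object of class `spot_set`.
#' @export
spot_set <- function(channel, df) {
  stopifnot(is.character(channel), length(channel) == 1L, nzchar(channel))
  req <- c("core_id", "x_um", "y_um")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    sc_stop(sprintf("spot table is missing column(s): %s",
                    paste(miss, collapse = ", ")), "spatcoloc_format_error")
  }
  df$core_id <- as.character(df$core_id)
  has_z <- "z_um" %in% names(df)
  if (has_z && nrow(df) > 0 && anyNA(df$z_um)) {
    sc_stop("z_um must be present for all spots or absent entirely",
            "spatcoloc_format_error")
  }
  num <- c("x_um", "y_um", if (has_z) "z_um")
  for (col in num) {
    if (nrow(df) > 0 && any(!is.finite(df[[col]]))) {
      sc_stop(sprintf("spot coordinates in '%s' must be finite", col),
              "spatcoloc_format_error")
    }
  }
  structure(list(channel = channel,
                 spots = df[, c("core_id", num), drop = FALSE]),
            class = "spot_set")
}

#' Read a spot table
#'
#' Delimited text with header `channel, core_id, x_um, y_um[, z_um]`. All
#' rows must share one channel value.
#'
#' @param path path to the file.
#' @return a [spot_set()].
#' @export
read_spot_table <- function(path) {
  df <- read_delim_checked(path,
                           required = c("channel", "core_id", "x_um", "y_um"),
                           numeric_cols = c("x_um", "y_um", "z_um"))
  ch <- unique(df$channel)
  if (nrow(df) == 0L) ch <- if (length(ch)) ch else "unknown"
  if (length(ch) > 1L) {
    sc_stop(sprintf("%s: spot table mixes channels (%s); one channel per set",
                    path, paste(ch, collapse = ", ")), "spatcoloc_format_error")
  }
  df$channel <- NULL
  spot_set(ch[1], df)
}

#' Write a spot set to delimited text
#'
#' @param set a [spot_set()].
#' @param path output path (`.tsv` selects tabs, else commas).
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(set, path) {
  df <- cbind(channel = set$channel, set$spots)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: channel '%s', %d spots, %s, %d core(s)\n",
              x$channel, nrow(x$spots),
              if ("z_um" %in% names(x$spots)) "3D" else "2D",
              length(unique(x$spots$core_id))))
  invisible(x)
}

#' Construct a label raster
#'
#' A single-channel integer image: 0 marks background, positive integers mark
#' segment (nucleus) ids; ids need not be contiguous. The pixel size converts
#' pixel indices to micrometres: a point (x, y) in um falls in the 0-based
#' pixel (row = floor(y / pixel_size), col = floor(x / pixel_size)), with the
#' origin at the top-left corner, x running along columns and y along rows.
#'
#' @param pixels integer-valued matrix (rows = y, cols = x).
#' @param pixel_size um per pixel edge, > 0.
#' @return an object of class `label_raster`.
#' @export
label_raster <- function(pixels, pixel_size) {
  if (!is.matrix(pixels)) {
    if (is.array(pixels)) {
      sc_stop("label raster must be 2D; only single-channel 2D rasters are supported",
              "spatcoloc_format_error")
    }
    sc_stop("label raster must be a matrix", "spatcoloc_format_error")
  }
  if (!is_number(pixel_size) || pixel_size <= 0) {
    sc_stop("pixel_size must be a positive number (um per pixel)",
            "spatcoloc_format_error")
  }
  if (is.double(pixels)) {
    if (any(pixels != floor(pixels) | !is.finite(pixels))) {
      sc_stop("label raster has non-integral pixel values; labels must be integers",
              "spatcoloc_format_error")
    }
    storage.mode(pixels) <- "integer"
  }
  if (any(pixels < 0L)) {
    sc_stop("label raster has negative labels", "spatcoloc_format_error")
  }
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "label_raster")
}

#' @export
print.label_raster <- function(x, ...) {
  labs <- unique(as.vector(x$pixels))
  cat(sprintf("label_raster: %d x %d px at %g um/px, %d segment(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              sum(labs > 0L)))
  invisible(x)
}

#' Read a label raster
#'
#' Supported formats, chosen by extension: grayscale uncompressed TIFF
#' (`.tif`/`.tiff`, 8/16/32-bit unsigned), ASCII PGM (`.pgm`, magic `P2`),
#' or a plain delimited integer grid (anything else; one raster row per
#' line, whitespace/comma separated).
#'
#' @param path path to the raster file.
#' @param pixel_size um per pixel edge.
#' @return a [label_raster()].
#' @export
read_label_raster <- function(path, pixel_size) {
  if (!file.exists(path)) {
    sc_stop(sprintf("file not found: %s", path), "spatcoloc_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  m <- if (ext %in% c("tif", "tiff")) {
    read_tiff_gray(path)
  } else if (ext == "pgm") {
    read_pgm(path)
  } else {
    read_grid_text(path)
  }
  label_raster(m, pixel_size)
}

#' Write a label raster
#'
#' Format chosen by extension as in [read_label_raster()]. TIFF output picks
#' the smallest unsigned bit depth (8/16/32) that fits the maximum label.
#'
#' @param raster a [label_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_raster <- function(raster, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    write_tiff_gray(raster$pixels, path)
  } else if (ext == "pgm") {
    write_pgm(raster$pixels, path)
  } else {
    utils::write.table(raster$pixels, path, sep = " ", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

read_grid_text <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    v <- strsplit(trimws(l), "[,;[:space:]]+")[[1]]
    n <- suppressWarnings(as.numeric(v))
    if (anyNA(n)) {
      sc_stop(sprintf("unparseable raster value '%s'", v[which(is.na(n))[1]]),
              "spatcoloc_format_error")
    }
    n
  })
  if (length(unique(lengths(rows))) > 1L) {
    sc_stop("raster rows have unequal lengths; grid must be rectangular",
            "spatcoloc_format_error")
  }
  do.call(rbind, rows)
}

read_pgm <- function(path) {
  toks <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (length(toks) < 4L || toks[1] != "P2") {
    sc_stop("only ASCII PGM (magic P2) is supported", "spatcoloc_format_error")
  }
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != w * h) {
    sc_stop(sprintf("PGM pixel count %d does not match %d x %d header",
                    length(vals), w, h), "spatcoloc_format_error")
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), as.character(max(m, 1L))), con)
  utils::write.table(m, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
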