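# Minimal baseline TIFF: little-endian, uncompressed, single-sample grayscale,
# multi-page. Writer emits 32-bit float samples with calibration metadata in
# the ImageDescription of the first page; reader additionally accepts 8/16-bit
# unsigned data and multi-strip layouts (covers plain OME-TIFF exports).

TIFF_TAGS <- c(width = 256L, height = 257L, bits = 258L, compression = 259L,
               photometric = 262L, description = 270L, strip_offsets = 273L,
               samples_per_pixel = 277L, rows_per_strip = 278L,
               strip_bytecounts = 279L, sample_format = 339L)

#' Write a frame stack as a multi-page TIFF
#'
#' @param frames Numeric array X x Y x M (or a matrix for a single page).
#' @param path Output file.
#' @param description Optional character scalar stored as ImageDescription of
#'   the first page (the movie writer stores calibration JSON here).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, description = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  stopifnot(length(dim(frames)) == 3L)
  nx <- dim(frames)[1]; ny <- dim(frames)[2]; M <- dim(frames)[3]
  desc_raw <- if (!is.null(description)) {
    c(charToRaw(as.character(description)), as.raw(0L))
  } else raw(0)

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  page_bytes <- nx * ny * 4
  desc_off <- 8
  data_off <- desc_off + length(desc_raw)
  ifd_start <- data_off + M * page_bytes
  ifd_size <- function(p) 2 + 12 * (if (p == 1 && length(desc_raw)) 10 else 9) + 4
  ifd_offsets <- cumsum(c(ifd_start, vapply(seq_len(M), ifd_size, 0)))[seq_len(M)]

  writeBin(charToRaw("II"), con)
  w2(42)
  w4(ifd_offsets[1])
  if (length(desc_raw)) writeBin(desc_raw, con)
  for (p in seq_len(M)) {
    writeBin(as.numeric(frames[, , p]), con, size = 4, endian = "little")
  }

  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3L && count == 1L) { w2(value); w2(0L) } else w4(value)
  }
  for (p in seq_len(M)) {
    has_desc <- p == 1 && length(desc_raw) > 0
    w2(if (has_desc) 10L else 9L)
    entry(TIFF_TAGS[["width"]], 4L, 1L, nx)
    entry(TIFF_TAGS[["height"]], 4L, 1L, ny)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, 32L)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    if (has_desc) {
      entry(TIFF_TAGS[["description"]], 2L, length(desc_raw), desc_off)
    }
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, data_off + (p - 1) * page_bytes)
    entry(TIFF_TAGS[["samples_per_pixel"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_bytecounts"]], 4L, 1L, page_bytes)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 3L)
    w4(if (p < M) ifd_offsets[p + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports uncompressed little/big-endian baseline TIFF with 8/16-bit
#' unsigned or 32-bit float samples, one sample per pixel.
#'
#' @param path TIFF file.
#' @return List with `frames` (X x Y x M array) and `description` (string or
#'   `NULL`).
#' @export
read_tiff_stack <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8) stop("not a TIFF file", call. = FALSE)
  order_tag <- rawToChar(raw_all[1:2])
  endian <- if (order_tag == "II") "little" else if (order_tag == "MM") "big"
    else stop("not a TIFF file", call. = FALSE)
  rd <- function(off, n, size, what = "integer", signed = TRUE) {
    readBin(raw_all[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  ru2 <- function(off, n = 1) rd(off, n, 2, signed = FALSE)
  ru4 <- function(off, n = 1) {
    v <- rd(off, n, 4)
    ifelse(v < 0, v + 2^32, v)
  }
  if (ru2(2) != 42) stop("not a TIFF file", call. = FALSE)

  pages <- list()
  description <- NULL
  ifd <- ru4(4)
  while (ifd != 0) {
    n_entries <- ru2(ifd)
    tags <- list()
    for (e in seq_len(n_entries)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- ru2(off); type <- ru2(off + 2); count <- ru4(off + 4)
      type_size <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8)[type]
      inline <- count * type_size <= 4
      voff <- if (inline) off + 8 else ru4(off + 8)
      value <- switch(as.character(type),
        "1" = rd(voff, count, 1, signed = FALSE),
        "2" = {
          chars <- raw_all[(voff + 1):(voff + count)]
          rawToChar(chars[chars != as.raw(0)])
        },
        "3" = ru2(voff, count),
        "4" = ru4(voff, count),
        "11" = rd(voff, count, 4, what = "numeric"),
        NULL)
      tags[[as.character(tag)]] <- value
    }
    g <- function(id, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[id]])]]
      if (is.null(v)) default else v
    }
    if (!is.null(g("compression")) && g("compression") != 1) {
      stop("only uncompressed TIFF is supported", call. = FALSE)
    }
    nx <- g("width"); ny <- g("height")
    bits <- g("bits", 8L)[1]
    fmt <- g("sample_format", 1L)[1]
    offs <- g("strip_offsets"); cnts <- g("strip_bytecounts")
    if (is.null(cnts)) cnts <- nx * ny * bits / 8
    vals <- numeric(0)
    for (s in seq_along(offs)) {
      npx <- cnts[s] / (bits / 8)
      vals <- c(vals, if (fmt == 3) {
        rd(offs[s], npx, 4, what = "numeric")
      } else if (bits == 8) {
        rd(offs[s], npx, 1, signed = FALSE)
      } else if (bits == 16) {
        rd(offs[s], npx, 2, signed = FALSE)
      } else {
        ru4(offs[s], npx)
      })
    }
    if (is.null(description)) description <- g("description")
    pages[[length(pages) + 1]] <- matrix(vals, nx, ny)
    ifd <- ru4(ifd + 2 + n_entries * 12)
  }
  frames <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  list(frames = frames, description = description)
}

#' Write a movie to per-channel multi-page TIFF files
#'
#' @param mv An [movie()].
#' @param prefix Path prefix; files are written as `<prefix>_<channel>.tif`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_movie_tiff <- function(mv, prefix) {
  stopifnot(inherits(mv, "lm_movie"))
  meta <- jsonlite::toJSON(list(pixel_size = mv$pixel_size,
                                frame_interval = mv$frame_interval,
                                patient_id = mv$patient_id,
                                movie_id = mv$movie_id), auto_unbox = TRUE)
  paths <- vapply(mv$channel_names, function(ch) {
    p <- paste0(prefix, "_", ch, ".tif")
    write_tiff_stack(mv$channels[[ch]], p, description = as.character(meta))
    p
  }, "")
  invisible(paths)
}

#' Read a movie from per-channel TIFF files
#'
#' @param paths Named character vector (names = channel labels) of TIFF files.
#' @param pixel_size,frame_interval Calibration overrides; when `NULL` the
#'   values are taken from the embedded metadata (if present) or defaults.
#' @return An [movie()].
#' @export
read_movie_tiff <- function(paths, pixel_size = NULL, frame_interval = NULL) {
  stopifnot(!is.null(names(paths)))
  stacks <- lapply(paths, read_tiff_stack)
  meta <- NULL
  d <- stacks[[1]]$description
  if (!is.null(d) && startsWith(trimws(d), "{")) {
    meta <- tryCatch(jsonlite::fromJSON(d), error = function(e) NULL)
  }
  movie(lapply(stacks, `[[`, "frames"),
        pixel_size = pixel_size %||% meta$pixel_size %||% DEFAULT_PIXEL_SIZE,
        frame_interval = frame_interval %||% meta$frame_interval %||%
          DEFAULT_FRAME_INTERVAL,
        patient_id = meta$patient_id %||% "P0",
        movie_id = meta$movie_id %||% "M0")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
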