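#' Write tracks to CSV
#'
#' Schema: `track_id, frame, t_seconds, x_px, y_px, x_um, y_um, phenotype,
#' regime` (missing columns are filled from calibration metadata or NA).
#'
#' @param tracks `lm_tracks` table.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_tracks_csv <- function(tracks, path) {
  ps <- attr(tracks, "pixel_size") %||% DEFAULT_PIXEL_SIZE
  fi <- attr(tracks, "frame_interval") %||% DEFAULT_FRAME_INTERVAL
  df <- data.frame(
    track_id = tracks$track_id,
    frame = tracks$frame,
    t_seconds = tracks$t_seconds %||% (tracks$frame * fi),
    x_px = tracks$x_px %||% (tracks$x %||% NA),
    y_px = tracks$y_px %||% (tracks$y %||% NA))
  df$x_um <- tracks$x_um %||% (df$x_px * ps)
  df$y_um <- tracks$y_um %||% (df$y_px * ps)
  df$phenotype <- tracks$phenotype %||% NA_character_
  df$regime <- tracks$regime %||% NA_character_
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' @param path CSV written by [write_tracks_csv()].
#' @param pixel_size,frame_interval Calibration metadata to attach.
#' @return `lm_tracks` table.
#' @export
read_tracks_csv <- function(path, pixel_size = DEFAULT_PIXEL_SIZE,
                            frame_interval = DEFAULT_FRAME_INTERVAL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(df, "pixel_size") <- pixel_size
  attr(df, "frame_interval") <- frame_interval
  class(df) <- c("lm_tracks", "data.frame")
  df
}

#' Write a scene configuration as a YAML-style key-value file
#'
#' @param config A [scene_config()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_scene_config <- function(config, path) {
  lines <- vapply(names(config), function(k) {
    sprintf("%s: %s", k, paste(config[[k]], collapse = " "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a scene configuration file
#'
#' @param path File written by [write_scene_config()].
#' @return A [scene_config()].
#' @export
read_scene_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- lapply(strsplit(lines, ":", fixed = TRUE), function(p) {
    val <- strsplit(trimws(paste(p[-1], collapse = ":")), "\\s+")[[1]]
    num <- suppressWarnings(as.numeric(val))
    list(key = trimws(p[1]),
         value = if (all(is.finite(num))) num
                 else if (identical(val, "TRUE") || identical(val, "FALSE"))
                   as.logical(val) else val)
  })
  args <- setNames(lapply(kv, `[[`, "value"), vapply(kv, `[[`, "", "key"))
  do.call(scene_config, args[names(args) %in% names(formals(scene_config))])
}
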