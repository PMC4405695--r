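#' Single-particle track
#'
#' A `track` is the unit of all motion statistics: the time-ordered 2-D
#' positions of one particle in physical units (micrometres), together with
#' the frame interval in seconds. Positions are stored with the pixel origin
#' at the centre of pixel (0,0); conversion from a pixel table multiplies by
#' the pixel size.
#'
#' @param frame strictly increasing integer frame indices (gaps allowed).
#' @param x,y positions in micrometres.
#' @param frame_interval time between consecutive frames, seconds.
#' @param track_id identifier (coerced to character).
#' @param pixel_size optional provenance metadata, micrometres per pixel.
#'
#' @return An object of class `track`: a data frame with columns `frame`,
#'   `x`, `y` and attributes `track_id`, `frame_interval`, `pixel_size`.
#' @export
track <- function(frame, x, y, frame_interval, track_id = "1",
                  pixel_size = NA_real_) {
  frame <- as.integer(frame)
  if (length(frame) < 2)
    stop("a track needs at least 2 points", call. = FALSE)
  if (any(diff(frame) <= 0))
    stop("'frame' must be strictly increasing", call. = FALSE)
  if (length(x) != length(frame) || length(y) != length(frame))
    stop("'x', 'y' and 'frame' must have equal length", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("positions must be finite", call. = FALSE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  out <- data.frame(frame = frame, x = as.numeric(x), y = as.numeric(y))
  attr(out, "track_id") <- as.character(track_id)
  attr(out, "frame_interval") <- frame_interval
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("track", "data.frame")
  out
}

#' @export
print.track <- function(x, ...) {
  cat(sprintf("<track %s: %d points, dt = %g s, %.2f s span>\n",
              attr(x, "track_id"), nrow(x), attr(x, "frame_interval"),
              track_duration(x)))
  invisible(x)
}

track_positions <- function(trk) cbind(trk$x, trk$y)

#' Track duration in seconds
#'
#' Elapsed time between the first and last observed frame.
#' @param trk a [track()].
#' @return Duration in seconds.
#' @export
track_duration <- function(trk) {
  (trk$frame[nrow(trk)] - trk$frame[1]) * attr(trk, "frame_interval")
}

## Elapsed time (s) between consecutive observed points; gap frames give
## a larger elapsed time rather than a missing sample.
track_dts <- function(trk) diff(trk$frame) * attr(trk, "frame_interval")

#' Convert a list of tracks to a long-format table
#'
#' @param tracks list of [track()] objects.
#' @return Data frame with columns `track_id`, `frame`, `x_um`, `y_um`.
#' @export
tracks_to_table <- function(tracks) {
  do.call(rbind, lapply(tracks, function(t)
    data.frame(track_id = attr(t, "track_id"), frame = t$frame,
               x_um = t$x, y_um = t$y)))
}

#' Write tracks to CSV
#'
#' Columns: `track_id`, `frame`, `x_um`, `y_um`. Round-trips through
#' [read_tracks()] to 6 decimal places.
#'
#' @param tracks list of [track()] objects sharing a frame interval.
#' @param path output file.
#' @export
write_tracks <- function(tracks, path) {
  tab <- tracks_to_table(tracks)
  tab$x_um <- round(tab$x_um, 6)
  tab$y_um <- round(tab$y_um, 6)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read tracks from CSV
#'
#' Expects columns `track_id`, `frame`, `x_um`, `y_um`. Tracks violating the
#' track invariants (fewer than 2 points, non-monotone frames, non-finite
#' positions) are excluded and counted in the attached rejection report.
#'
#' @param path CSV file.
#' @param frame_interval seconds between frames (not stored in the CSV).
#' @return List of [track()] objects with attribute `rejected`: a data frame
#'   of excluded track ids and reasons.
#' @export
read_tracks <- function(path, frame_interval) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("track_id", "frame", "x_um", "y_um")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("track file is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ids <- unique(tab$track_id)
  tracks <- list()
  rejected <- data.frame(track_id = character(), reason = character())
  for (id in ids) {
    rows <- tab[tab$track_id == id, , drop = FALSE]
    reason <- NULL
    if (nrow(rows) < 2) reason <- "fewer than 2 points"
    else if (any(diff(rows$frame) <= 0)) reason <- "frames not strictly increasing"
    else if (!all(is.finite(rows$x_um)) || !all(is.finite(rows$y_um)))
      reason <- "non-finite positions"
    if (is.null(reason)) {
      tracks[[length(tracks) + 1L]] <-
        track(rows$frame, rows$x_um, rows$y_um, frame_interval, track_id = id)
    } else {
      rejected <- rbind(rejected,
                        data.frame(track_id = as.character(id), reason = reason))
    }
  }
  attr(tracks, "rejected") <- rejected
  tracks
}
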