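#' Microtubule length from a filament mask
#'
#' Each filament is thinned to a 1-pixel skeleton (Zhang-Suen); its length is
#' the sum over skeleton-adjacent pixel pairs of the step length — 1 pixel
#' for axial neighbours, sqrt(2) for diagonal neighbours that are not part
#' of an axial triangle — times the pixel size.
#'
#' @param mask a [label_image()] (labelled filaments) or a binary/labelled
#'   matrix together with `pixel_size`.
#' @param pixel_size um per pixel (taken from the label image if omitted).
#' @return List with `per_filament` (data frame `filament`, `length_um`)
#'   and `total_um`.
#' @export
microtubule_length <- function(mask, pixel_size = NULL) {
  if (inherits(mask, "label_image")) {
    lab <- mask$labels
    if (is.null(pixel_size)) pixel_size <- mask$pixel_size
  } else {
    lab <- as.matrix(mask)
    if (is.null(pixel_size))
      stop("pixel_size required with a plain matrix mask", call. = FALSE)
  }
  if (all(lab == 0)) stop("empty microtubule mask", call. = FALSE)
  ids <- sort(unique(lab[lab > 0]))
  lens <- vapply(ids, function(id) {
    idx <- which(lab == id, arr.ind = TRUE)
    r0 <- max(1, min(idx[, 1]) - 1); r1 <- min(nrow(lab), max(idx[, 1]) + 1)
    c0 <- max(1, min(idx[, 2]) - 1); c1 <- min(ncol(lab), max(idx[, 2]) + 1)
    skel <- skeletonize_mask(lab[r0:r1, c0:c1] == id)
    skeleton_length_px(skel) * pixel_size
  }, numeric(1))
  list(per_filament = data.frame(filament = ids, length_um = lens),
       total_um = sum(lens))
}

## Path length (pixels) of a skeleton: axial adjacencies count 1, diagonal
## adjacencies count sqrt(2) unless the two pixels share an axial neighbour
## on the skeleton (which would double-count the corner of an L-step).
skeleton_length_px <- function(skel) {
  nr <- nrow(skel); nc <- ncol(skel)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- skel
  s <- function(dr, dc) pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  ax <- sum(skel & s(0, 1)) + sum(skel & s(1, 0))
  diag_ok <- function(dr, dc) {
    both <- skel & s(dr, dc) == 1
    ## shared 4-neighbours of (r,c) and (r+dr,c+dc): (r,c+dc) and (r+dr,c)
    shared <- (s(0, dc) == 1) | (s(dr, 0) == 1)
    sum(both & !shared)
  }
  dg <- diag_ok(1, 1) + diag_ok(1, -1)
  ax + sqrt(2) * dg
}

#' Motor density on microtubules
#'
#' Mean per-frame count of spots falling on the filament mask (dilated by a
#' configurable radius to absorb localization error), divided by the total
#' microtubule length.
#'
#' @param spots data frame with `frame`, `x_um`, `y_um`.
#' @param mask a [label_image()] of filaments.
#' @param mt_length total microtubule length, um (> 0); computed with
#'   [microtubule_length()] when `NULL`.
#' @param dilate_px dilation radius applied to the mask, pixels.
#' @param n_frames number of movie frames (frames with no spot count as
#'   zero); defaults to the number of distinct frames in `spots`.
#' @param unit_flux single-emitter integrated flux. When given and the spot
#'   table has a `flux` column, each on-mask detection counts as
#'   `round(flux / unit_flux)` motors (at least 1): stoichiometry-style
#'   correction for optically unresolved spot pairs, which plain maxima
#'   counting merges into one detection. `NULL` (default) counts detections.
#' @return List with `motors_per_um`, `mean_count_per_frame`, `mt_length_um`.
#' @export
motor_density <- function(spots, mask, mt_length = NULL, dilate_px = 1,
                          n_frames = NULL, unit_flux = NULL) {
  stopifnot(inherits(mask, "label_image"))
  if (is.null(mt_length)) mt_length <- microtubule_length(mask)$total_um
  check_scalar(mt_length, "mt_length", min = 0, strict_min = TRUE)
  m <- mask$labels > 0
  if (dilate_px > 0)
    m <- EBImage::imageData(EBImage::dilate(
      m * 1, EBImage::makeBrush(2 * dilate_px + 1, shape = "box"))) > 0
  ps <- mask$pixel_size
  if (nrow(spots) == 0)
    return(list(motors_per_um = 0, mean_count_per_frame = 0,
                mt_length_um = mt_length))
  row <- pmin(pmax(round(spots$y_um / ps) + 1, 1), nrow(m))
  col <- pmin(pmax(round(spots$x_um / ps) + 1, 1), ncol(m))
  on <- m[cbind(row, col)]
  w <- rep(1, nrow(spots))
  if (!is.null(unit_flux) && !is.null(spots$flux))
    w <- pmax(1, round(spots$flux / unit_flux))
  if (is.null(n_frames)) n_frames <- length(unique(spots$frame))
  mean_count <- sum(w[on]) / n_frames
  list(motors_per_um = mean_count / mt_length,
       mean_count_per_frame = mean_count, mt_length_um = mt_length)
}

#' Classify a motor track as moving
#'
#' A motor is moving iff its mean speed exceeds `speed_min`, its net
#' start-to-end displacement exceeds `distance_min`, and it was tracked
#' longer than `duration_min` — all strict inequalities. Net displacement
#' (not path length) is used so diffusive jitter does not qualify; set
#' `distance = "path"` for the path-length alternative.
#'
#' @param trk a [track()].
#' @param speed_min um/s.
#' @param distance_min um.
#' @param duration_min s.
#' @param distance `"net"` (default) or `"path"`.
#' @return Logical.
#' @export
classify_moving <- function(trk, speed_min = 0.12, distance_min = 0.2,
                            duration_min = 0.9, distance = c("net", "path")) {
  distance <- match.arg(distance)
  check_scalar(speed_min, "speed_min", min = 0, strict_min = TRUE)
  check_scalar(distance_min, "distance_min", min = 0, strict_min = TRUE)
  check_scalar(duration_min, "duration_min", min = 0, strict_min = TRUE)
  xy <- track_positions(trk)
  d <- if (distance == "net")
    sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  else sum(step_lengths(xy))
  mean_speed(trk) > speed_min && d > distance_min &&
    track_duration(trk) > duration_min
}

#' Percent of moving motors
#'
#' Denominator counts every track regardless of duration, consistent with
#' assays where a large immobile short-lived pool coexists with a small
#' moving fraction.
#'
#' @param tracks list of [track()] objects.
#' @param ... thresholds passed to [classify_moving()].
#' @return Percentage in `[0, 100]`.
#' @export
percent_moving <- function(tracks, ...) {
  if (!length(tracks)) return(NA_real_)
  100 * mean(vapply(tracks, classify_moving, logical(1), ...))
}

#' Lifespan statistics of motor tracks
#'
#' Lifespan is (last frame - first frame) x frame interval.
#'
#' @param tracks non-empty list of [track()] objects.
#' @param cutoff optional cutoff, s, for the reported survival fraction.
#' @return List with `median_lifespan_s`, `lifespans_s`, and
#'   `fraction_beyond_cutoff` when a cutoff is given.
#' @export
lifespan_stats <- function(tracks, cutoff = NULL) {
  if (!length(tracks)) stop("need at least one track", call. = FALSE)
  ls <- vapply(tracks, track_duration, numeric(1))
  out <- list(median_lifespan_s = stats::median(ls), lifespans_s = ls)
  if (!is.null(cutoff)) out$fraction_beyond_cutoff <- mean(ls > cutoff)
  out
}

#' Full single-molecule assay report
#'
#' @param tracks list of [track()] objects from the movie.
#' @param spots spot table used for the density (see [motor_density()]).
#' @param mask filament [label_image()].
#' @param mt_length total filament length, um; computed if `NULL`.
#' @param ... thresholds passed to [classify_moving()].
#' @return List of class `motor_assay_report`: `motors_per_um`,
#'   `percent_moving`, `median_lifespan`, `n_motors`, `mt_total_length`
#'   and a per-track data frame with `moving`, `lifespan`, `max_excursion`,
#'   `mean_speed`.
#' @export
motor_assay_report <- function(tracks, spots, mask, mt_length = NULL, ...) {
  dens <- motor_density(spots, mask, mt_length)
  per_track <- do.call(rbind, lapply(tracks, function(trk) {
    xy <- track_positions(trk)
    data.frame(track_id = attr(trk, "track_id"),
               moving = classify_moving(trk, ...),
               lifespan = track_duration(trk),
               max_excursion = max(sqrt((xy[, 1] - xy[1, 1])^2 +
                                          (xy[, 2] - xy[1, 2])^2)),
               mean_speed = mean_speed(trk))
  }))
  structure(list(motors_per_um = dens$motors_per_um,
                 percent_moving = percent_moving(tracks, ...),
                 median_lifespan = if (length(tracks))
                   lifespan_stats(tracks)$median_lifespan_s else NA_real_,
                 n_motors = length(tracks),
                 mt_total_length = dens$mt_length_um,
                 per_track = per_track),
            class = "motor_assay_report")
}
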