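#' Detect spots in an image stack
#'
#' Local-maximum detection with subpixel refinement: a pixel is a candidate
#' if it is at least as bright as its 8 neighbours and above the intensity
#' threshold; its position is the intensity-weighted centroid of the 3x3
#' neighbourhood. Candidates closer than `min_separation` keep only the
#' brighter one.
#'
#' @param stack list of 2-D numeric matrices (frames), or a single matrix.
#' @param intensity_threshold AU; maxima at or below it are discarded.
#' @param min_separation pixels.
#' @param pixel_size um per pixel, used to express positions in um.
#' @param integration_radius half-width (pixels) of the window used for the
#'   reported integrated `flux` (background-subtracted by the frame median);
#'   the flux of an unresolved spot pair is about twice that of a single
#'   emitter, which supports stoichiometry-style multiplicity counting.
#' @return Data frame (`frame`, `x_um`, `y_um`, `x_px`, `y_px`, `intensity`,
#'   `flux`) with 0-based pixel coordinates in the `*_px` columns.
#' @export
detect_spots <- function(stack, intensity_threshold, min_separation = 3,
                         pixel_size = 1, integration_radius = 2) {
  if (is.matrix(stack)) stack <- list(stack)
  if (!length(stack)) stop("empty image stack", call. = FALSE)
  check_scalar(intensity_threshold, "intensity_threshold")
  check_scalar(min_separation, "min_separation", min = 0)
  out <- lapply(seq_along(stack), function(f) {
    img <- stack[[f]]
    nr <- nrow(img); nc <- ncol(img)
    pad <- matrix(-Inf, nr + 2, nc + 2)
    pad[2:(nr + 1), 2:(nc + 1)] <- img
    ismax <- matrix(TRUE, nr, nc)
    any_strict <- matrix(FALSE, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbv <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
      ## strict against earlier-raster neighbours so an intensity plateau
      ## yields exactly one maximum
      ismax <- ismax & if (dr < 0 || (dr == 0 && dc < 0)) img > nbv
                       else img >= nbv
      any_strict <- any_strict | (is.finite(nbv) & img > nbv)
    }
    ## a peak must exceed at least one real neighbour: uniform regions and
    ## flat backgrounds yield no detections
    ismax <- ismax & any_strict & img > intensity_threshold
    idx <- which(ismax, arr.ind = TRUE)
    if (!nrow(idx)) return(NULL)
    cand <- data.frame(row = idx[, 1], col = idx[, 2],
                       intensity = img[idx])
    cand <- cand[order(-cand$intensity), ]
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d2 <- (cand$row[keep] - cand$row[i])^2 + (cand$col[keep] - cand$col[i])^2
      keep[i] <- all(d2 >= min_separation^2)
    }
    cand <- cand[keep, , drop = FALSE]
    ## subpixel: intensity-weighted centroid over the 3x3 neighbourhood
    bg <- stats::median(img)
    ir <- as.integer(integration_radius)
    xpx <- numeric(nrow(cand)); ypx <- numeric(nrow(cand))
    flux <- numeric(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      r0 <- max(1, cand$row[i] - 1):min(nr, cand$row[i] + 1)
      c0 <- max(1, cand$col[i] - 1):min(nc, cand$col[i] + 1)
      w <- pmax(img[r0, c0, drop = FALSE], 0)
      tot <- sum(w)
      if (tot <= 0) { xpx[i] <- cand$col[i] - 1; ypx[i] <- cand$row[i] - 1 }
      else {
        xpx[i] <- sum(rep(c0 - 1, each = length(r0)) * w) / tot
        ypx[i] <- sum(rep(r0 - 1, times = length(c0)) * w) / tot
      }
      ri <- max(1, cand$row[i] - ir):min(nr, cand$row[i] + ir)
      ci <- max(1, cand$col[i] - ir):min(nc, cand$col[i] + ir)
      flux[i] <- sum(img[ri, ci]) - length(ri) * length(ci) * bg
    }
    data.frame(frame = f, x_um = xpx * pixel_size, y_um = ypx * pixel_size,
               x_px = xpx, y_px = ypx, intensity = cand$intensity,
               flux = flux)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(0), x_um = numeric(0),
                      y_um = numeric(0), x_px = numeric(0),
                      y_px = numeric(0), intensity = numeric(0),
                      flux = numeric(0))
  out
}

#' Link spots into tracks
#'
#' Greedy nearest-neighbour assignment, frame by frame, with all candidate
#' links at a frame sorted globally by distance; links farther than
#' `max_disp` per elapsed frame are forbidden, and a track may bridge up to
#' `max_gap` missing frames. Every spot joins at most one track.
#'
#' @param spots data frame with `frame`, `x_um`, `y_um` (e.g. from
#'   [detect_spots()] or a simulator).
#' @param max_disp maximum displacement, um per frame.
#' @param max_gap frames a track may skip.
#' @param frame_interval seconds per frame for the returned tracks.
#' @return List of [track()] objects (singleton detections are dropped;
#'   their count is in attribute `n_singletons`).
#' @export
link_spots <- function(spots, max_disp, max_gap = 0, frame_interval = 1) {
  check_scalar(max_disp, "max_disp", min = 0, strict_min = TRUE)
  check_scalar(max_gap, "max_gap", min = 0, integer = TRUE)
  frames <- sort(unique(spots$frame))
  ## active track state: last x, y, frame, and row indices of members
  tr_x <- numeric(0); tr_y <- numeric(0); tr_f <- numeric(0)
  members <- list()
  for (f in frames) {
    rows <- which(spots$frame == f)
    sx <- spots$x_um[rows]; sy <- spots$y_um[rows]
    open <- which(tr_f >= f - 1 - max_gap & tr_f < f)
    assigned_spot <- rep(FALSE, length(rows))
    assigned_trk <- rep(FALSE, length(open))
    if (length(open) && length(rows)) {
      dx <- outer(tr_x[open], sx, "-")
      dy <- outer(tr_y[open], sy, "-")
      d <- sqrt(dx^2 + dy^2)
      lim <- outer(f - tr_f[open], rep(1, length(rows))) * max_disp
      cand <- which(d <= lim, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(d[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          ti <- cand[r, 1]; si <- cand[r, 2]
          if (assigned_trk[ti] || assigned_spot[si]) next
          assigned_trk[ti] <- TRUE; assigned_spot[si] <- TRUE
          k <- open[ti]
          members[[k]] <- c(members[[k]], rows[si])
          tr_x[k] <- sx[si]; tr_y[k] <- sy[si]; tr_f[k] <- f
        }
      }
    }
    for (si in which(!assigned_spot)) {
      members[[length(members) + 1L]] <- rows[si]
      tr_x <- c(tr_x, sx[si]); tr_y <- c(tr_y, sy[si]); tr_f <- c(tr_f, f)
    }
  }
  lens <- lengths(members)
  tracks <- lapply(which(lens >= 2), function(k) {
    m <- members[[k]]
    track(spots$frame[m], spots$x_um[m], spots$y_um[m], frame_interval,
          track_id = as.character(k))
  })
  attr(tracks, "n_singletons") <- sum(lens == 1)
  tracks
}
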