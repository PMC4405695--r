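#' Simulate a single-molecule motor field
#'
#' Emulates a TIRF motility assay: straight microtubule filaments of known
#' summed length rendered into a label mask, decorated with motor spots at a
#' stated linear density. Each spot is static or moves along its filament at
#' the given speed; all spots are present from the first frame and detach
#' when their exponential lifespan expires or a moving spot runs off its
#' filament end. Ground-truth moving/static labels are returned alongside
#' the observable spot table.
#'
#' @param mt_total_length summed filament length, um (> 0).
#' @param density motors per um of filament (Poisson-distributed count).
#' @param moving_fraction proportion of spots that move, in `[0, 1]`.
#' @param speed um/s for moving spots.
#' @param lifespan_mean mean exponential lifespan, s (`Inf` for immortal).
#' @param n_frames,frame_interval movie geometry (TIRF default 0.041 s).
#' @param seed integer seed.
#' @param image_shape `c(rows, cols)` pixels.
#' @param pixel_size um per pixel.
#' @param filament_length target length per filament, um.
#' @param line_width_px rendered filament width.
#' @param angles `"lattice"` (default) restricts filament orientations to
#'   multiples of 45 degrees so the rendered skeleton length is pixel-exact;
#'   `"uniform"` draws arbitrary orientations (digital line length is then
#'   accurate only to a few percent).
#' @return List with `mask` (a [label_image()] of filaments), `spots`
#'   (data frame `track_id`, `frame`, `x_um`, `y_um`, `intensity`),
#'   `truth` (per-spot `track_id`, `moving`, `filament`, `lifespan_s`),
#'   `filaments` (endpoints and lengths) and `mt_total_length`.
#' @export
simulate_motor_field <- function(mt_total_length, density, moving_fraction,
                                 speed = 0.5, lifespan_mean = Inf,
                                 n_frames = 10, frame_interval = 0.041,
                                 seed = NULL,
                                 image_shape = c(256, 256), pixel_size = 0.16,
                                 filament_length = 20, line_width_px = 3,
                                 angles = c("lattice", "uniform")) {
  angles <- match.arg(angles)
  check_scalar(mt_total_length, "mt_total_length", min = 0, strict_min = TRUE)
  check_scalar(density, "density", min = 0)
  check_scalar(moving_fraction, "moving_fraction", min = 0, max = 1)
  check_scalar(speed, "speed", min = 0)
  check_scalar(n_frames, "n_frames", min = 1, integer = TRUE)
  check_scalar(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  with_seed(seed, {
    fl <- rep(filament_length, floor(mt_total_length / filament_length))
    rem <- mt_total_length - sum(fl)
    if (rem > 1e-9) fl <- c(fl, rem)
    extent <- (image_shape - 1) * pixel_size   # um, x along cols, y along rows
    margin <- (line_width_px + 2) * pixel_size
    ends <- matrix(NA_real_, length(fl), 4)    # x0 y0 x1 y1
    for (i in seq_along(fl)) {
      for (try in 1:200) {
        x0 <- stats::runif(1, margin, extent[2] - margin)
        y0 <- stats::runif(1, margin, extent[1] - margin)
        th <- if (angles == "lattice") sample(0:7, 1) * pi / 4
              else stats::runif(1, 0, 2 * pi)
        x1 <- x0 + fl[i] * cos(th); y1 <- y0 + fl[i] * sin(th)
        if (x1 >= margin && x1 <= extent[2] - margin &&
            y1 >= margin && y1 <= extent[1] - margin) break
        if (try == 200)
          stop("cannot place filament inside the field; enlarge image_shape",
               call. = FALSE)
      }
      ends[i, ] <- c(x0, y0, x1, y1)
    }
    lab <- matrix(0L, image_shape[1], image_shape[2])
    for (i in seq_along(fl)) {
      np <- max(2, ceiling(fl[i] / (pixel_size / 4)))
      s <- seq(0, 1, length.out = np)
      cx <- round((ends[i, 1] + s * (ends[i, 3] - ends[i, 1])) / pixel_size) + 1
      cy <- round((ends[i, 2] + s * (ends[i, 4] - ends[i, 2])) / pixel_size) + 1
      half <- (line_width_px - 1) %/% 2
      for (d1 in -half:half) for (d2 in -half:half) {
        rr <- pmin(pmax(cy + d1, 1), image_shape[1])
        cc <- pmin(pmax(cx + d2, 1), image_shape[2])
        lab[cbind(rr, cc)] <- i
      }
    }
    n_spots <- stats::rpois(1, density * mt_total_length)
    spots <- data.frame(track_id = character(0), frame = integer(0),
                        x_um = numeric(0), y_um = numeric(0),
                        intensity = numeric(0))
    truth <- data.frame(track_id = character(0), moving = logical(0),
                        filament = integer(0), lifespan_s = numeric(0))
    if (n_spots > 0) {
      fil <- sample.int(length(fl), n_spots, replace = TRUE, prob = fl)
      s0 <- stats::runif(n_spots, 0, fl[fil])
      moving <- stats::runif(n_spots) < moving_fraction
      dir <- sample(c(-1, 1), n_spots, replace = TRUE)
      life <- if (is.finite(lifespan_mean))
        stats::rexp(n_spots, 1 / lifespan_mean) else rep(Inf, n_spots)
      rows <- vector("list", n_spots)
      for (i in seq_len(n_spots)) {
        t <- (seq_len(n_frames) - 1) * frame_interval
        alive <- t < life[i]
        s <- if (moving[i]) s0[i] + dir[i] * speed * t else rep(s0[i], n_frames)
        on_fil <- s >= 0 & s <= fl[fil[i]]
        keep <- which(alive & on_fil)
        if (length(keep) && any(!on_fil))        # detach permanently at end
          keep <- keep[keep < min(which(!on_fil), n_frames + 1L)]
        if (!length(keep)) next
        e <- ends[fil[i], ]
        frac <- s[keep] / fl[fil[i]]
        rows[[i]] <- data.frame(track_id = as.character(i), frame = keep,
                                x_um = e[1] + frac * (e[3] - e[1]),
                                y_um = e[2] + frac * (e[4] - e[2]),
                                intensity = 1000)
      }
      spots <- do.call(rbind, c(rows, list(spots)))
      truth <- data.frame(track_id = as.character(seq_len(n_spots)),
                          moving = moving, filament = fil, lifespan_s = life)
    }
    list(mask = label_image(lab, pixel_size, channel = "microtubule"),
         spots = spots, truth = truth,
         filaments = data.frame(filament = seq_along(fl), length_um = fl,
                                x0 = ends[, 1], y0 = ends[, 2],
                                x1 = ends[, 3], y1 = ends[, 4]),
         mt_total_length = mt_total_length,
         frame_interval = frame_interval, n_frames = n_frames)
  })
}

#' Render a spot table into an image stack
#'
#' Stamps each detection as a 2-D Gaussian of the given PSF width, then adds
#' background and Gaussian readout noise — the observable movie matching a
#' simulated spot table.
#'
#' @param spots data frame with `frame`, `x_um`, `y_um`, `intensity`.
#' @param n_frames number of frames to render.
#' @param image_shape `c(rows, cols)` pixels.
#' @param pixel_size um per pixel.
#' @param psf_sigma Gaussian sigma in pixels.
#' @param background,noise_sd intensity offset and noise, AU.
#' @param seed integer seed for the noise.
#' @return List of numeric matrices, one per frame.
#' @export
render_spot_frames <- function(spots, n_frames, image_shape = c(256, 256),
                               pixel_size = 0.16, psf_sigma = 1.2,
                               background = 0, noise_sd = 0, seed = NULL) {
  with_seed(seed, {
    win <- ceiling(4 * psf_sigma)
    lapply(seq_len(n_frames), function(f) {
      img <- matrix(background, image_shape[1], image_shape[2])
      sub <- spots[spots$frame == f, , drop = FALSE]
      for (i in seq_len(nrow(sub))) {
        cx <- sub$x_um[i] / pixel_size   # 0-based pixel coordinates
        cy <- sub$y_um[i] / pixel_size
        cols <- max(0, floor(cx) - win):min(image_shape[2] - 1, ceiling(cx) + win)
        rows <- max(0, floor(cy) - win):min(image_shape[1] - 1, ceiling(cy) + win)
        if (!length(cols) || !length(rows)) next
        gx <- exp(-(cols - cx)^2 / (2 * psf_sigma^2))
        gy <- exp(-(rows - cy)^2 / (2 * psf_sigma^2))
        img[rows + 1, cols + 1] <- img[rows + 1, cols + 1] +
          sub$intensity[i] * outer(gy, gx)
      }
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                            nrow(img), ncol(img))
      img
    })
  })
}

#' Simulate an equilibrium binding table
#'
#' One-site saturation: `signal = bmax * L / (kd + L)`, optionally corrupted
#' by multiplicative Gaussian noise of the stated coefficient of variation.
#'
#' @param kd dissociation constant, uM (> 0).
#' @param bmax maximal signal, AU.
#' @param concentrations ligand concentrations, uM (>= 0, non-empty).
#' @param noise_cv multiplicative noise CV (0 for noise-free).
#' @param seed integer seed.
#' @return Data frame with `concentration_um` and `signal`.
#' @export
simulate_binding_table <- function(kd, bmax, concentrations, noise_cv = 0,
                                   seed = NULL) {
  check_scalar(kd, "kd", min = 0, strict_min = TRUE)
  check_scalar(bmax, "bmax", min = 0, strict_min = TRUE)
  check_scalar(noise_cv, "noise_cv", min = 0)
  if (!length(concentrations))
    stop("'concentrations' must be non-empty", call. = FALSE)
  if (any(!is.finite(concentrations) | concentrations < 0))
    stop_field("concentrations", "must be finite and >= 0")
  with_seed(seed, {
    s <- bmax * concentrations / (kd + concentrations)
    if (noise_cv > 0)
      s <- s * (1 + stats::rnorm(length(s), sd = noise_cv))
    data.frame(concentration_um = concentrations, signal = s)
  })
}
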