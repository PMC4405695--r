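#' Parameters for trajectory simulation
#'
#' Defines the two vesicle motion archetypes the downstream statistics
#' distinguish: `confined` (Brownian motion hard-reflected inside a disc
#' about the start point, so the true occupied area is exactly pi R^2) and
#' `directed` (constant-speed motion along a fixed axis whose heading flips
#' 180 degrees as a Poisson process). In both modes pauses begin as a Poisson
#' process during movement and last exponentially; a pause suppresses true
#' displacement but not localization noise. Event times are drawn in
#' continuous time and sampled at frame boundaries, so an excursion shorter
#' than one frame may be invisible in the sampled track.
#'
#' Defaults emulate live-cell imaging of Golgi-derived vesicles: 2 s frame
#' interval, 71 frames, ~0.5 um/s linear speed, 0.5 um confinement radius,
#' 0.05 um^2/s diffusion, 0.05/s pause and reversal rates, 0.02 um
#' localization jitter.
#'
#' @param mode `"confined"` or `"directed"`.
#' @param diffusion_coefficient um^2/s (confined mode).
#' @param confinement_radius um (confined mode).
#' @param speed um/s (directed mode).
#' @param reversal_rate 180-degree heading flips per second (directed mode).
#' @param pause_rate pause onsets per second of movement.
#' @param pause_duration_mean mean pause length, seconds.
#' @param frame_interval seconds per frame.
#' @param n_frames number of frames (>= 2).
#' @param localization_noise_sd per-axis Gaussian localization error, um.
#' @param seed integer seed; same seed and parameters give identical output.
#' @return A `track_sim_params` list.
#' @export
track_sim_params <- function(mode = c("confined", "directed"),
                             diffusion_coefficient = 0.05,
                             confinement_radius = 0.5,
                             speed = 0.5,
                             reversal_rate = 0.05,
                             pause_rate = 0.05,
                             pause_duration_mean = 4,
                             frame_interval = 2,
                             n_frames = 71,
                             localization_noise_sd = 0.02,
                             seed = NULL) {
  mode <- match.arg(mode)
  check_scalar(diffusion_coefficient, "diffusion_coefficient", min = 0)
  check_scalar(confinement_radius, "confinement_radius", min = 0,
               strict_min = (mode == "confined"))
  check_scalar(speed, "speed", min = 0)
  check_scalar(reversal_rate, "reversal_rate", min = 0)
  check_scalar(pause_rate, "pause_rate", min = 0)
  check_scalar(pause_duration_mean, "pause_duration_mean", min = 0)
  check_scalar(frame_interval, "frame_interval", min = 0, strict_min = TRUE)
  check_scalar(n_frames, "n_frames", min = 2, integer = TRUE)
  check_scalar(localization_noise_sd, "localization_noise_sd", min = 0)
  structure(list(mode = mode,
                 diffusion_coefficient = diffusion_coefficient,
                 confinement_radius = confinement_radius,
                 speed = speed, reversal_rate = reversal_rate,
                 pause_rate = pause_rate,
                 pause_duration_mean = pause_duration_mean,
                 frame_interval = frame_interval, n_frames = n_frames,
                 localization_noise_sd = localization_noise_sd,
                 seed = seed),
            class = "track_sim_params")
}

## Alternating renewal pause process on [0, total]: movement periods are
## Exp(rate), pause durations Exp(mean). Returns a 2-column (on, off) matrix
## of disjoint, sorted intervals.
sim_pause_intervals <- function(total, rate, mean_dur) {
  if (rate <= 0 || mean_dur <= 0)
    return(matrix(numeric(0), ncol = 2))
  on <- numeric(0); off <- numeric(0); t <- 0
  repeat {
    t <- t + stats::rexp(1, rate)
    if (t >= total) break
    d <- stats::rexp(1, 1 / mean_dur)
    on <- c(on, t); off <- c(off, min(t + d, total))
    t <- t + d
    if (t >= total) break
  }
  cbind(on, off)
}

## Per-frame-step integrals over [0, total] split at frame boundaries:
## active (non-paused) time, and heading-signed active time given flip times.
frame_integrals <- function(n_frames, dt, pauses, flips = numeric(0)) {
  total <- (n_frames - 1) * dt
  bounds <- (0:(n_frames - 1)) * dt
  bp <- sort(unique(c(bounds, pauses[, 1], pauses[, 2], flips)))
  bp <- bp[bp >= 0 & bp <= total]
  mid <- (bp[-1] + bp[-length(bp)]) / 2
  len <- diff(bp)
  active <- rep(TRUE, length(mid))
  if (nrow(pauses) > 0) {
    flat <- as.vector(t(pauses))
    active <- findInterval(mid, flat) %% 2 == 0
  }
  sgn <- rep(1, length(mid))
  if (length(flips) > 0)
    sgn <- ifelse(findInterval(mid, sort(flips)) %% 2 == 0, 1, -1)
  step <- findInterval(mid, bounds, rightmost.closed = TRUE)
  step <- pmin(pmax(step, 1L), n_frames - 1L)
  agg <- function(v) {
    out <- numeric(n_frames - 1)
    s <- rowsum(v, step)
    out[as.integer(rownames(s))] <- s
    out
  }
  list(active = agg(len * active), signed = agg(len * active * sgn))
}

## Fold a radius into [0, R] by reflection at the disc boundary.
reflect_radius <- function(r, R) {
  r <- r %% (2 * R)
  ifelse(r > R, 2 * R - r, r)
}

#' Simulate one vesicle trajectory
#'
#' @param params a [track_sim_params()].
#' @param track_id identifier for the returned track.
#' @return A [track()] of `n_frames` positions at uniform `frame_interval`,
#'   starting at the origin, with attribute `truth` recording the generating
#'   parameters, pause intervals and (directed mode) heading-flip times.
#' @export
simulate_track <- function(params, track_id = "1") {
  stopifnot(inherits(params, "track_sim_params"))
  p <- params
  n <- p$n_frames
  dt <- p$frame_interval
  total <- (n - 1) * dt
  with_seed(p$seed, {
    pauses <- sim_pause_intervals(total, p$pause_rate, p$pause_duration_mean)
    pos <- matrix(0, n, 2)
    flips <- numeric(0)
    if (p$mode == "confined") {
      ints <- frame_integrals(n, dt, pauses)
      R <- p$confinement_radius
      sds <- sqrt(2 * p$diffusion_coefficient * ints$active)
      cur <- c(0, 0)
      for (i in seq_len(n - 1)) {
        prop <- cur + stats::rnorm(2, sd = sds[i])
        r <- sqrt(sum(prop^2))
        if (r > R) prop <- prop * (reflect_radius(r, R) / r)
        cur <- prop
        pos[i + 1, ] <- cur
      }
    } else {
      if (p$reversal_rate > 0) {
        n_flip <- stats::rpois(1, p$reversal_rate * total)
        flips <- sort(stats::runif(n_flip, 0, total))
      }
      ints <- frame_integrals(n, dt, pauses, flips)
      theta <- stats::runif(1, 0, 2 * pi)
      u <- c(cos(theta), sin(theta))
      disp <- p$speed * ints$signed
      pos[, 1] <- c(0, cumsum(disp * u[1]))
      pos[, 2] <- c(0, cumsum(disp * u[2]))
    }
    if (p$localization_noise_sd > 0)
      pos <- pos + matrix(stats::rnorm(2 * n, sd = p$localization_noise_sd),
                          n, 2)
    trk <- track(seq_len(n), pos[, 1], pos[, 2], dt, track_id = track_id)
    attr(trk, "truth") <- list(params = p, pauses = pauses, flips = flips)
    trk
  })
}

#' Simulate a labelled cohort of tracks
#'
#' Convenience wrapper generating `n` tracks from one parameter set, with
#' seeds derived deterministically from `seed`.
#'
#' @param n number of tracks.
#' @param params a [track_sim_params()] (its `seed` field is ignored).
#' @param seed integer seed for the cohort.
#' @return List of [track()] objects.
#' @export
simulate_cohort <- function(n, params, seed = 1) {
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- derive_seed(seed, 1000, i)
    simulate_track(p, track_id = as.character(i))
  })
}
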