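## Shared fixtures: small deterministic scenes and tracks built in code.

straight_track <- function(v = 0.5, dt = 2, n = 20, angle = 0) {
  d <- v * dt * (0:(n - 1))
  track(1:n, d * cos(angle), d * sin(angle), dt)
}

## rigid-motion transform of a track
transform_track <- function(trk, angle = 0, dx = 0, dy = 0) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  xy <- cbind(trk$x, trk$y) %*% t(R)
  track(trk$frame, xy[, 1] + dx, xy[, 2] + dy,
        attr(trk, "frame_interval"), attr(trk, "track_id"))
}

## one-cell scene with objects of given areas and mean intensities
simple_cell_scene <- function(areas, intensities = rep(100, length(areas)),
                              noise_sd = 0, psf_sigma = 0, seed = NULL,
                              marker = 100) {
  cell <- rect_polygon(1, 1, 24, 24)
  xs <- seq(5, 20, length.out = length(areas))
  obj <- data.frame(cell = 1L, x_um = xs, y_um = rep(12, length(areas)),
                    area_um2 = areas, mean_intensity = intensities)
  p <- image_sim_params(image_shape = c(128, 128), pixel_size = 0.2,
                        cells = list(cell), golgi_objects = obj,
                        marker_mean_intensity = marker, background = 10,
                        noise_sd = noise_sd, psf_sigma = psf_sigma,
                        seed = seed)
  render_cell_image(p)
}
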