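test_that("confined tracks without noise never leave the stated radius", {
  for (R in c(0.15, 0.5, 1.2)) {
    p <- track_sim_params(mode = "confined", confinement_radius = R,
                          diffusion_coefficient = 0.1, n_frames = 150,
                          localization_noise_sd = 0, seed = round(100 * R))
    trk <- simulate_track(p)
    expect_true(all(sqrt(trk$x^2 + trk$y^2) <= R + 1e-12))
  }
})

test_that("noise-free directed motion gives exact uniform collinear steps", {
  p <- track_sim_params(mode = "directed", speed = 0.5, reversal_rate = 0,
                        pause_rate = 0, localization_noise_sd = 0,
                        frame_interval = 2, n_frames = 30, seed = 11)
  trk <- simulate_track(p)
  steps <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_equal(steps, rep(1.0, 29), tolerance = 1e-12)
  ## collinearity: area of every consecutive triangle is zero
  cross <- diff(trk$x)[-1] * diff(trk$y)[-29] - diff(trk$x)[-29] * diff(trk$y)[-1]
  expect_equal(max(abs(cross)), 0, tolerance = 1e-12)
  expect_equal(mean_speed(trk), 0.5, tolerance = 1e-12)
})

test_that("same seed and parameters reproduce a track bit-identically", {
  p <- track_sim_params(mode = "directed", seed = 99)
  expect_identical(simulate_track(p), simulate_track(p))
  p2 <- track_sim_params(mode = "confined", seed = 99)
  expect_identical(simulate_track(p2), simulate_track(p2))
})

test_that("reversal events occur at the stated Poisson rate", {
  n_seeds <- 150
  rho <- 0.05; total <- 299 * 0.3
  counts <- vapply(seq_len(n_seeds), function(i) {
    p <- track_sim_params(mode = "directed", reversal_rate = rho,
                          pause_rate = 0, n_frames = 300,
                          frame_interval = 0.3, localization_noise_sd = 0,
                          seed = 4000 + i)
    length(attr(simulate_track(p), "truth")$flips)
  }, numeric(1))
  se <- sd(counts) / sqrt(n_seeds)
  expect_lt(abs(mean(counts) - rho * total), 3 * se)
})

test_that("pauses suppress true displacement but not localization noise", {
  p <- track_sim_params(mode = "directed", speed = 0.5, pause_rate = 0.5,
                        pause_duration_mean = 10, localization_noise_sd = 0,
                        n_frames = 100, seed = 21)
  trk <- simulate_track(p)
  steps <- sqrt(diff(trk$x)^2 + diff(trk$y)^2)
  expect_true(any(steps == 0))              # fully paused frames
  p$localization_noise_sd <- 0.02
  trk2 <- simulate_track(p)
  steps2 <- sqrt(diff(trk2$x)^2 + diff(trk2$y)^2)
  expect_true(all(steps2 > 0))              # jitter persists through pauses
})

test_that("invalid simulation parameters are rejected by field name", {
  expect_error(track_sim_params(mode = "confined", confinement_radius = -1),
               "confinement_radius")
  expect_error(track_sim_params(n_frames = 1), "n_frames")
  expect_error(track_sim_params(frame_interval = 0), "frame_interval")
  expect_error(track_sim_params(localization_noise_sd = NaN),
               "localization_noise_sd")
})

test_that("binding table generator obeys the one-site identities", {
  d <- simulate_binding_table(2, 5, c(0, 2, 10))
  expect_equal(d$signal[1], 0)
  expect_equal(d$signal[2], 2.5)            # half-saturation at L = kd
  expect_error(simulate_binding_table(1, 1, numeric(0)), "non-empty")
  expect_error(simulate_binding_table(-1, 1, 1), "kd")
  d1 <- simulate_binding_table(1, 1, c(1, 2), noise_cv = 0.1, seed = 5)
  d2 <- simulate_binding_table(1, 1, c(1, 2), noise_cv = 0.1, seed = 5)
  expect_identical(d1, d2)
})

test_that("motor field simulator honours density, movement and geometry", {
  empty <- simulate_motor_field(50, 0, 0.5, seed = 1)
  expect_equal(nrow(empty$spots), 0)
  ## Poisson spot-count oracle
  counts <- vapply(1:100, function(i)
    nrow(simulate_motor_field(100, 0.3, 0, n_frames = 1,
                              seed = 600 + i)$spots), numeric(1))
  se <- sd(counts) / sqrt(100)
  expect_lt(abs(mean(counts) - 30), 3 * se)
  ## moving spots advance exactly speed * dt along the filament
  f <- simulate_motor_field(40, 0.2, 1, speed = 0.5, n_frames = 6,
                            frame_interval = 0.5, seed = 9)
  for (id in unique(f$spots$track_id)) {
    s <- f$spots[f$spots$track_id == id, ]
    if (nrow(s) < 2) next
    d <- sqrt(diff(s$x_um)^2 + diff(s$y_um)^2) / diff(s$frame)
    expect_equal(d, rep(0.25, length(d)), tolerance = 1e-9)
  }
  expect_error(simulate_motor_field(0, 0.1, 0), "mt_total_length")
})

test_that("ground-truth label images partition the rendered foreground", {
  scene <- simple_cell_scene(c(5, 1, 2.5))
  areas_px <- table(scene$object_labels$labels[scene$object_labels$labels > 0])
  expect_equal(sum(areas_px), sum(scene$object_labels$labels > 0))
  expect_equal(as.numeric(areas_px) * 0.2^2,
               scene$truth$area_um2_achieved, tolerance = 1e-12)
  expect_equal(scene$truth$integrated_intensity,
               scene$truth$area_um2_achieved / 0.04 * 100, tolerance = 1e-9)
})

test_that("cell-image renderer rejects objects outside their cell", {
  cell <- rect_polygon(1, 1, 10, 10)
  obj <- data.frame(cell = 1L, x_um = 20, y_um = 20, area_um2 = 2,
                    mean_intensity = 50)
  p <- image_sim_params(image_shape = c(64, 64), pixel_size = 0.2,
                        cells = list(cell), golgi_objects = obj)
  expect_error(render_cell_image(p), "outside cell polygon")
})
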