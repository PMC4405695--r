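test_that("microtubule length follows the skeleton step geometry", {
  bar <- matrix(0L, 20, 120); bar[9:11, 11:110] <- 1L
  expect_equal(microtubule_length(label_image(bar, 0.1))$total_um, 9.9,
               tolerance = 1e-9)
  diag <- matrix(0L, 60, 60)
  for (i in 1:50) diag[i + 2, i + 2] <- 1L
  expect_equal(microtubule_length(label_image(diag, 0.1))$total_um,
               49 * sqrt(2) * 0.1, tolerance = 1e-9)
  expect_error(microtubule_length(label_image(matrix(0L, 5, 5), 0.1)),
               "empty")
})

test_that("rendered filament fields recover their total length within 5%", {
  for (s in 1:4) {
    f <- simulate_motor_field(100, 0, 0, seed = s, filament_length = 15)
    est <- microtubule_length(f$mask)$total_um
    expect_lt(abs(est / 100 - 1), 0.05)
  }
})

test_that("motor density is count over length and rotation invariant", {
  mask <- matrix(0L, 50, 50); mask[24:26, 6:45] <- 1L
  li <- label_image(mask, 1)
  spots <- data.frame(frame = rep(1:4, each = 10),
                      x_um = rep(seq(6, 44, length.out = 10), 4),
                      y_um = 24)
  d <- motor_density(spots, li, mt_length = 40)
  expect_equal(d$motors_per_um, 0.25)
  expect_equal(motor_density(spots[0, ], li, mt_length = 40)$motors_per_um, 0)
  ## rotate the scene by 90 degrees: labels transposed, coordinates swapped
  li_r <- label_image(t(mask), 1)
  spots_r <- data.frame(frame = spots$frame, x_um = spots$y_um,
                        y_um = spots$x_um)
  expect_equal(motor_density(spots_r, li_r, mt_length = 40)$motors_per_um,
               d$motors_per_um)
})

test_that("moving-motor rule applies strict thresholds", {
  moving <- make_boundary_track(0.2, 0.5, 1.0)
  expect_true(classify_moving(moving))
  at_speed <- make_boundary_track(0.12, 0.1, 1.0)
  expect_false(classify_moving(at_speed))          # strict > 0.12
  short <- make_boundary_track(0.3, 0.25, 0.5)
  expect_false(classify_moving(short))
  expect_equal(percent_moving(list(moving, at_speed, short)), 100 / 3,
               tolerance = 1e-9)
  ## path-length reading admits tracks that net displacement rejects
  zig <- track(1:5, c(0, 0.4, 0.05, 0.45, 0.1), rep(0, 5), 0.5)
  expect_false(classify_moving(zig, distance = "net"))
  expect_true(classify_moving(zig, distance = "path"))
})

test_that("percent moving is monotone non-increasing in each threshold", {
  tracks <- lapply(1:40, function(i) {
    set.seed(i)
    v <- runif(1, 0.05, 0.4); d <- runif(1, 0.05, v * 2); t <- runif(1, 0.5, 2)
    if (v * t < d) d <- v * t
    make_boundary_track(v, d, t)
  })
  for (par in c("speed_min", "distance_min", "duration_min")) {
    lo <- do.call(percent_moving, c(list(tracks),
                                    stats::setNames(list(0.05), par)))
    hi <- do.call(percent_moving, c(list(tracks),
                                    stats::setNames(list(0.8), par)))
    expect_lte(hi, lo)
  }
})

test_that("lifespan statistics match arithmetic and exponential oracles", {
  mk <- function(l) track(c(1, 1 + max(1, round(l / 0.1))),
                          c(0, 0.1), c(0, 0), 0.1)
  expect_equal(lifespan_stats(list(mk(0.4), mk(0.7), mk(5)))$median_lifespan_s,
               0.7, tolerance = 1e-9)
  expect_equal(lifespan_stats(list(mk(1.3)))$median_lifespan_s, 1.3,
               tolerance = 1e-9)
  expect_error(lifespan_stats(list()), "at least one")
  set.seed(12)
  ls <- rexp(1000, 1)
  meds <- vapply(1:50, function(i) {
    s <- sample(ls, 200, replace = TRUE)
    lifespan_stats(lapply(s, mk))$median_lifespan_s
  }, numeric(1))
  se <- sd(meds) / sqrt(50)
  expect_lt(abs(mean(meds) - log(2)), 3 * se + 0.05)
})

test_that("full field pipeline recovers the moving fraction", {
  hits <- vapply(1:25, function(i) {
    f <- simulate_motor_field(60, 0.08, 0.5, speed = 0.4, n_frames = 30,
                              frame_interval = 0.1, seed = 700 + i,
                              image_shape = c(320, 320), pixel_size = 0.107)
    trks <- link_spots(f$spots, max_disp = 0.2, frame_interval = 0.1)
    if (!length(trks)) return(NA_real_)
    percent_moving(trks, speed_min = 0.12, distance_min = 0.2,
                   duration_min = 0.9)
  }, numeric(1))
  hits <- hits[is.finite(hits)]
  se <- sd(hits) / sqrt(length(hits))
  expect_lt(abs(mean(hits) - 50), 3 * se + 5)
})

test_that("assay report aggregates density, movement and lifespan", {
  f <- simulate_motor_field(80, 0.15, 0.5, speed = 0.4, n_frames = 25,
                            frame_interval = 0.1, seed = 41)
  trks <- link_spots(f$spots, max_disp = 0.2, frame_interval = 0.1)
  rep <- motor_assay_report(trks, f$spots, f$mask)
  expect_gte(rep$percent_moving, 0)
  expect_lte(rep$percent_moving, 100)
  expect_gt(rep$mt_total_length, 0)
  expect_equal(rep$n_motors, length(trks))
  expect_equal(nrow(rep$per_track), length(trks))
})
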