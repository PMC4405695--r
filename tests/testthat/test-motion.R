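test_that("msd obeys the stationary and ballistic identities", {
  still <- track(1:20, rep(1, 20), rep(2, 20), 1)
  expect_true(all(msd(still, 6)$msd == 0))
  trk <- straight_track(v = 0.5, dt = 2, n = 40)
  m <- msd(trk, 10)
  expect_equal(m$msd, (0.5 * m$lag_s)^2, tolerance = 1e-12)
})

test_that("msd of long confined tracks plateaus near the squared radius", {
  plateaus <- vapply(1:10, function(s) {
    p <- track_sim_params(mode = "confined", confinement_radius = 0.5,
                          diffusion_coefficient = 0.02, n_frames = 600,
                          pause_rate = 0, localization_noise_sd = 0, seed = s)
    m <- msd(simulate_track(p), 20)
    mean(m$msd[15:20])
  }, numeric(1))
  expect_lt(abs(mean(plateaus) / 0.25 - 1), 0.2)
})

test_that("classification separates directed, diffusive and confined motion", {
  lin <- classify_track(straight_track(n = 50))
  expect_equal(lin$class, "linear")
  expect_equal(lin$msd_exponent, 2, tolerance = 0.01)
  ## free diffusion: confined mode with a radius far beyond reach
  p <- track_sim_params(mode = "confined", confinement_radius = 100,
                        diffusion_coefficient = 0.05, n_frames = 200,
                        pause_rate = 0, localization_noise_sd = 0, seed = 5)
  fr <- classify_track(simulate_track(p))
  expect_equal(fr$class, "unclassified")
  expect_lt(abs(fr$msd_exponent - 1), 0.3)
  still <- track(1:30, rep(0, 30), rep(0, 30), 1)
  deg <- classify_track(still)
  expect_equal(deg$class, "confined")
  expect_equal(deg$msd_exponent, 0)
  short <- track(1:5, 0:4, rep(0, 5), 1)
  expect_equal(classify_track(short)$class, "unclassified")
  expect_error(classify_track(still, alpha_confined = 2, alpha_linear = 1),
               "alpha_confined")
})

test_that("minimal enclosing circle matches hand geometry", {
  expect_equal(min_enclosing_circle(rbind(c(0, 0), c(2, 0)))$area, pi,
               tolerance = 1e-12)
  got <- min_enclosing_circle(rbind(c(0, 0), c(1, 0), c(0.5, 0.5)))
  expect_equal(got$radius, 0.5, tolerance = 1e-12)
  expect_equal(got$area, pi / 4, tolerance = 1e-12)
  one <- min_enclosing_circle(rbind(c(3, 3), c(3, 3)))
  expect_equal(one$area, 0)
})

test_that("minimal enclosing circle equals brute force on random sets", {
  set.seed(7)
  for (i in 1:120) {
    n <- sample(2:25, 1)
    xy <- matrix(runif(2 * n, -3, 3), n, 2)
    if (i %% 4 == 0) xy[, 2] <- 0.5 * xy[, 1] + 1       # collinear sets too
    a <- min_enclosing_circle(xy)
    b <- mec_brute_force(xy)
    expect_equal(a$radius, b$radius, tolerance = 1e-9)
  }
})

test_that("confinement area approaches the disc area from long tracks", {
  p <- track_sim_params(mode = "confined", confinement_radius = 0.4,
                        diffusion_coefficient = 0.05, n_frames = 500,
                        pause_rate = 0, localization_noise_sd = 0, seed = 2)
  a <- confinement_area(simulate_track(p))
  expect_lt(abs(a / (pi * 0.16) - 1), 0.15)
  ## 2-sigma ellipse alternative is available and positive
  expect_gt(confinement_area(simulate_track(p), method = "sd_ellipse"), 0)
})

test_that("mean speed follows hand arithmetic and rigid-motion invariance", {
  trk <- track(1:3, c(0, 0.2, 0.6), c(0, 0, 0), 2)
  expect_equal(mean_speed(trk), 0.15)
  expect_equal(mean_speed(track(1:5, rep(1, 5), rep(1, 5), 1)), 0)
  p <- track_sim_params(mode = "directed", seed = 77)
  t1 <- simulate_track(p)
  for (ang in c(0.3, 1.2, 2.5)) {
    t2 <- transform_track(t1, angle = ang, dx = 5, dy = -2)
    expect_equal(mean_speed(t2), mean_speed(t1), tolerance = 1e-10)
  }
})

test_that("pause detection counts onsets below a strict threshold", {
  trk <- track(1:6, cumsum(c(0, 0.5, 0.05, 0.05, 0.5, 0.05)), rep(0, 6), 1)
  dp <- detect_pauses(trk)
  expect_equal(dp$n_pauses, 2)
  expect_equal(dp$pause_rate, 0.4)
  fast <- straight_track(v = 0.5, n = 10, dt = 1)
  expect_equal(detect_pauses(fast)$n_pauses, 0)
  ## a step at exactly the threshold speed is not a pause
  edge <- track(1:3, c(0, 0.1, 0.2), c(0, 0, 0), 1)
  expect_equal(detect_pauses(edge, 0.1)$n_pauses, 0)
  expect_equal(detect_pauses(edge, 0.100001)$n_pauses, 1)
})

test_that("direction changes count principal-axis sign flips", {
  mono <- straight_track(n = 10)
  expect_equal(direction_changes(mono)$n_changes, 0)
  zig <- track(1:7, c(0, 1, 2, 1, 0, 1, 2), rep(0, 7), 1)
  dc <- direction_changes(zig)
  expect_equal(dc$n_changes, 2)
  expect_equal(dc$rate, 2 / 6, tolerance = 1e-12)
  ## invariance under reflection (principal-axis sign ambiguity)
  zig_r <- track(1:7, -c(0, 1, 2, 1, 0, 1, 2), rep(0, 7), 1)
  expect_equal(direction_changes(zig_r)$n_changes, 2)
  ## all-paused track reports missing
  crawl <- track(1:5, c(0, 0.01, 0.02, 0.03, 0.04), rep(0, 5), 1)
  expect_true(is.na(direction_changes(crawl)$rate))
})

test_that("motion report populates exactly the class-appropriate fields", {
  tracks <- c(simulate_cohort(6, track_sim_params(mode = "confined"), seed = 1),
              simulate_cohort(6, track_sim_params(mode = "directed"), seed = 2))
  rep <- motion_report(tracks)
  expect_equal(nrow(rep), 12)
  expect_true(all(is.na(rep$confinement_area[rep$class != "confined"])))
  expect_true(all(rep$confinement_area[rep$class == "confined"] > 0))
  expect_true(all(is.na(rep$direction_changes_per_s[rep$class != "linear"])))
  expect_true(all(rep$mean_speed >= 0) && all(rep$pause_rate >= 0))
})

test_that("group comparison uses the rank-sum test with sane reporting", {
  a <- data.frame(mean_speed = rnorm(30, 1, 0.1))
  same <- compare_groups(a, a, "mean_speed")
  expect_gt(same$p_value, 0.9)
  expect_equal(same$fold_change, 1)
  set.seed(10)
  hits <- vapply(1:20, function(i) {
    x <- data.frame(v = rnorm(50, 0, 1))
    y <- data.frame(v = rnorm(50, 2, 1))     # shift = 2 SD
    compare_groups(x, y, "v")$p_value < 1e-3
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  tiny <- compare_groups(data.frame(v = 1), data.frame(v = 2), "v")
  expect_true(is.finite(tiny$statistic))
  expect_error(compare_groups(a, data.frame(z = 1:5), "mean_speed"),
               "absent in group b")
})
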