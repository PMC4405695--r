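test_that("track construction enforces its invariants", {
  expect_error(track(1, 0, 0, 1), "at least 2")
  expect_error(track(c(1, 1), c(0, 1), c(0, 1), 1), "strictly increasing")
  expect_error(track(1:2, c(0, NA), c(0, 1), 1), "finite")
  expect_error(track(1:2, c(0, 1), c(0, 1), 0), "frame_interval")
  trk <- track(c(1, 3, 4), c(0, 1, 2), c(0, 0, 0), 2, track_id = "a")
  expect_equal(track_duration(trk), 6)
})

test_that("track CSV round-trip preserves values to 6 decimals", {
  tracks <- simulate_cohort(20, track_sim_params(mode = "directed"), seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracks(tracks, path)
  back <- read_tracks(path, frame_interval = 2)
  expect_length(back, 20)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$x, tracks[[i]]$x, tolerance = 1e-6)
    expect_equal(back[[i]]$y, tracks[[i]]$y, tolerance = 1e-6)
    expect_identical(back[[i]]$frame, tracks[[i]]$frame)
  }
})

test_that("track reader rejects malformed input with a useful report", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(track_id = 1, frame = 1:3, x_um = 0:2),
            path, row.names = FALSE)
  expect_error(read_tracks(path, 1), "y_um")
  tab <- data.frame(track_id = c(1, 1, 2), frame = c(1, 2, 1),
                    x_um = c(0, 1, 0), y_um = c(0, 0, 0))
  write.csv(tab, path, row.names = FALSE)
  got <- read_tracks(path, 1)
  expect_length(got, 1)                         # track 2 has a single point
  rej <- attr(got, "rejected")
  expect_equal(rej$track_id, "2")
  expect_match(rej$reason, "fewer than 2")
})

test_that("spot detection finds a rendered spot with subpixel accuracy", {
  sp <- data.frame(frame = 1, x_um = 10, y_um = 20, intensity = 1000)
  img <- render_spot_frames(sp, 1, image_shape = c(64, 64), pixel_size = 1,
                            psf_sigma = 1.2)[[1]]
  det <- detect_spots(img, intensity_threshold = 50, min_separation = 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 10), 0.1)
  expect_lt(abs(det$y_px - 20), 0.1)
})

test_that("spot detection handles uniform images and close pairs", {
  expect_equal(nrow(detect_spots(matrix(5, 32, 32), 1)), 0)
  ## two spots one pixel apart with min_separation 3 keep only the brighter
  sp <- data.frame(frame = 1, x_um = c(15, 16), y_um = c(15, 15),
                   intensity = c(1000, 600))
  img <- render_spot_frames(sp, 1, image_shape = c(32, 32), pixel_size = 1,
                            psf_sigma = 0.8)[[1]]
  det <- detect_spots(img, 50, min_separation = 3)
  expect_equal(nrow(det), 1)
  expect_lt(abs(det$x_px - 15), 0.6)
  expect_error(detect_spots(list(), 1), "empty")
})

test_that("greedy linking follows single and parallel trajectories", {
  ## one spot walking 0.1 um per frame
  sp <- data.frame(frame = 1:10, x_um = 0.1 * (0:9), y_um = 0)
  trks <- link_spots(sp, max_disp = 0.5)
  expect_length(trks, 1)
  expect_equal(nrow(trks[[1]]), 10)
  ## two parallel spots 5 um apart never cross-link at max_disp 1
  sp2 <- rbind(data.frame(frame = 1:8, x_um = 0.2 * (0:7), y_um = 0),
               data.frame(frame = 1:8, x_um = 0.2 * (0:7), y_um = 5))
  trks2 <- link_spots(sp2, max_disp = 1)
  expect_length(trks2, 2)
  for (t in trks2) expect_equal(sd(t$y), 0)
})

test_that("linking bridges gaps up to max_gap and no further", {
  sp <- data.frame(frame = c(1, 2, 4, 5), x_um = c(0, 0.1, 0.3, 0.4),
                   y_um = 0)
  bridged <- link_spots(sp, max_disp = 0.15, max_gap = 1)
  expect_length(bridged, 1)
  expect_equal(nrow(bridged[[1]]), 4)
  split <- link_spots(sp, max_disp = 0.15, max_gap = 0)
  expect_length(split, 2)
})

test_that("linking agrees with exhaustive assignment on tiny instances", {
  ## brute force: over all one-to-one assignments between consecutive frames,
  ## minimise summed distance under the max_disp constraint
  brute_pairs <- function(a, b, max_disp) {
    n <- nrow(a); m <- nrow(b)
    best <- NULL; best_cost <- Inf
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (pm in perms(seq_len(m))) {
      k <- min(n, m)
      d <- sqrt((a$x_um[seq_len(k)] - b$x_um[pm[seq_len(k)]])^2 +
                  (a$y_um[seq_len(k)] - b$y_um[pm[seq_len(k)]])^2)
      ok <- d <= max_disp
      cost <- sum(d[ok]) - 1e6 * sum(ok)     # maximise links, then distance
      if (cost < best_cost) { best_cost <- cost; best <- ok }
    }
    sum(best)
  }
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(2:3, 1)
    a <- data.frame(frame = 1, x_um = runif(n, 0, 4), y_um = runif(n, 0, 4))
    b <- data.frame(frame = 2, x_um = a$x_um + rnorm(n, 0, 0.1),
                    y_um = a$y_um + rnorm(n, 0, 0.1))
    got <- link_spots(rbind(a, b), max_disp = 0.5)
    expect_equal(length(got), brute_pairs(a, b, 0.5))
  }
})

test_that("detect then link reproduces well-separated simulated tracks", {
  f <- simulate_motor_field(60, 0.05, 1, speed = 0.5, n_frames = 8,
                            frame_interval = 0.5, seed = 31,
                            image_shape = c(320, 320), pixel_size = 0.16)
  frames <- render_spot_frames(f$spots, 8, image_shape = c(320, 320),
                               pixel_size = 0.16, psf_sigma = 1.0)
  det <- detect_spots(frames, 100, min_separation = 2, pixel_size = 0.16)
  trks <- link_spots(det, max_disp = 0.5, frame_interval = 0.5)
  long_truth <- table(f$spots$track_id)
  expect_equal(length(trks), sum(long_truth >= 2))
  for (t in trks) {
    sp <- f$spots[abs(f$spots$x_um - t$x[1]) < 0.2 &
                    abs(f$spots$y_um - t$y[1]) < 0.2, ]
    expect_gt(nrow(sp), 0)
  }
})
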