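## Parameter-recovery and oracle-equivalence checks. Each check_* function
## recomputes a quantity from freshly simulated ground truth and returns
## rows of (check, metric, expected, observed, tolerance, pass);
## acceptance_suite() assembles the full table.

acc_row <- function(check, metric, expected, observed, tolerance, pass, n) {
  data.frame(check = check, metric = metric, expected = expected,
             observed = observed, tolerance = tolerance, pass = pass, n = n)
}

check_mec_oracle <- function(seed = 1, n_sets = 1000) {
  agree <- with_seed(seed, {
    vapply(seq_len(n_sets), function(i) {
      n <- sample(3:25, 1)
      xy <- matrix(stats::runif(2 * n, -5, 5), n, 2)
      a <- min_enclosing_circle(xy)$radius
      b <- mec_brute_force(xy)$radius
      abs(a - b) <= 1e-9 * max(b, 1)
    }, logical(1))
  })
  frac <- mean(agree)
  acc_row("mec_oracle", "agreement_fraction", 1, frac, 0, frac == 1, n_sets)
}

check_confinement_recovery <- function(seed = 1, n_seeds = 100,
                                       radii = c(0.2, 0.5, 1.0),
                                       n_frames = 500) {
  rows <- lapply(radii, function(R) {
    areas <- vapply(seq_len(n_seeds), function(i) {
      p <- track_sim_params(mode = "confined", confinement_radius = R,
                            diffusion_coefficient = 0.05, pause_rate = 0,
                            n_frames = n_frames, frame_interval = 2,
                            localization_noise_sd = 0,
                            seed = derive_seed(seed, 1, round(R * 100), i))
      confinement_area(simulate_track(p))
    }, numeric(1))
    med <- stats::median(areas)
    rel <- abs(med / (pi * R^2) - 1)
    acc_row("confinement_recovery", sprintf("median_area_R%.1f", R),
            pi * R^2, med, 0.15 * pi * R^2, rel <= 0.15, n_seeds)
  })
  do.call(rbind, rows)
}

check_reversal_recovery <- function(seed = 1, n_seeds = 200,
                                    rates = c(0.02, 0.05, 0.1),
                                    n_frames = 300, frame_interval = 0.3) {
  rows <- lapply(rates, function(rho) {
    r <- vapply(seq_len(n_seeds), function(i) {
      p <- track_sim_params(mode = "directed", speed = 0.5,
                            reversal_rate = rho, pause_rate = 0,
                            n_frames = n_frames,
                            frame_interval = frame_interval,
                            localization_noise_sd = 0.02,
                            seed = derive_seed(seed, 2, round(rho * 1000), i))
      direction_changes(simulate_track(p))$rate
    }, numeric(1))
    m <- mean(r); se <- stats::sd(r) / sqrt(n_seeds)
    acc_row("reversal_recovery", sprintf("rate_%.2f_per_s", rho),
            rho, m, 3 * se, abs(m - rho) <= 3 * se, n_seeds)
  })
  do.call(rbind, rows)
}

check_classification <- function(seed = 1, n_per_class = 200) {
  conf <- simulate_cohort(n_per_class, track_sim_params(mode = "confined"),
                          seed = derive_seed(seed, 31))
  dire <- simulate_cohort(n_per_class, track_sim_params(mode = "directed"),
                          seed = derive_seed(seed, 53))
  acc_conf <- mean(vapply(conf, function(t)
    classify_track(t)$class == "confined", logical(1)))
  acc_dir <- mean(vapply(dire, function(t)
    classify_track(t)$class == "linear", logical(1)))
  rbind(
    acc_row("classification", "confined_accuracy", 1, acc_conf, 0.10,
            acc_conf >= 0.90, n_per_class),
    acc_row("classification", "directed_accuracy", 1, acc_dir, 0.10,
            acc_dir >= 0.90, n_per_class))
}

## Straight-out-and-back track with prescribed mean speed, net displacement
## and duration (possible whenever speed * duration >= distance).
make_boundary_track <- function(speed, distance, duration) {
  d1 <- (speed * duration + distance) / 2
  d2 <- (speed * duration - distance) / 2
  track(frame = 1:3, x = c(0, d1, d1 - d2), y = c(0, 0, 0),
        frame_interval = duration / 2)
}

check_moving_classifier <- function() {
  grid <- expand.grid(speed = c(0.10, 0.12, 0.30),
                      distance = c(0.15, 0.20, 0.25),
                      duration = c(0.8, 0.9, 1.5))
  grid <- grid[grid$speed * grid$duration >= grid$distance, ]
  got <- mapply(function(v, d, t)
    classify_moving(make_boundary_track(v, d, t)),
    grid$speed, grid$distance, grid$duration)
  want <- grid$speed > 0.12 & grid$distance > 0.2 & grid$duration > 0.9
  frac <- mean(got == want)
  acc_row("moving_classifier", "boundary_agreement", 1, frac, 0,
          frac == 1, nrow(grid))
}

## Full observable path at TIRF-realistic sampling (16 um camera pixel at
## 150x -> 0.107 um/px; diffraction sigma ~94 nm = 0.88 px). Two detections
## can never be closer than 2 px, so unresolvable spot pairs merge; finer
## sampling keeps that optical loss small against the stated densities.
run_density_pipeline <- function(density, seed, noise_sd = 0,
                                 mt_total_length = 100, n_frames = 1) {
  field <- simulate_motor_field(mt_total_length, density,
                                moving_fraction = 0, lifespan_mean = Inf,
                                n_frames = n_frames, frame_interval = 0.041,
                                seed = seed, image_shape = c(320, 320),
                                pixel_size = 0.08, filament_length = 12)
  frames <- render_spot_frames(field$spots, n_frames,
                               image_shape = c(320, 320), pixel_size = 0.08,
                               psf_sigma = 1.0, background = 0,
                               noise_sd = noise_sd, seed = seed + 7L)
  det <- detect_spots(frames, intensity_threshold = 100,
                      min_separation = 2, pixel_size = 0.08)
  ## the known summed filament length is an input of the experiment;
  ## skeleton-based length estimation is exercised by its own checks.
  ## unit flux self-calibrates on the median detection (a single motor),
  ## so unresolved pairs count as two.
  uf <- if (nrow(det)) stats::median(det$flux) else NULL
  motor_density(det, field$mask, mt_length = mt_total_length,
                n_frames = n_frames, unit_flux = uf)$motors_per_um
}

check_density_recovery <- function(seed = 1, n_seeds = 100,
                                   densities = c(0.1, 0.3)) {
  rows <- lapply(densities, function(d) {
    clean <- vapply(seq_len(n_seeds), function(i)
      run_density_pipeline(d, derive_seed(seed, 4, round(d * 100), i)),
      numeric(1))
    m <- mean(clean)
    r1 <- acc_row("density_recovery", sprintf("density_%.1f_clean", d),
                  d, m, 0.1 * d, abs(m - d) <= 0.1 * d, n_seeds)
    noisy <- vapply(seq_len(n_seeds), function(i)
      run_density_pipeline(d, derive_seed(seed, 5, round(d * 100), i),
                           noise_sd = 20, n_frames = 3),
      numeric(1))
    mn <- mean(noisy); se <- stats::sd(noisy) / sqrt(n_seeds)
    r2 <- acc_row("density_recovery", sprintf("density_%.1f_noisy", d),
                  d, mn, 3 * se, abs(mn - d) <= 3 * se, n_seeds)
    rbind(r1, r2)
  })
  do.call(rbind, rows)
}

## One-cell scene with two discs of equal integrated intensity and areas
## 5 and 1 um^2; the large-object fraction is 0.5 by construction.
golgi_two_object_scene <- function(pixel_size = 0.2, noise_sd = 0) {
  cell <- rect_polygon(1, 1, 24, 24)
  obj <- data.frame(cell = 1L, x_um = c(7, 17), y_um = c(12, 12),
                    area_um2 = c(5, 1), mean_intensity = c(100, 100))
  p0 <- image_sim_params(image_shape = c(128, 128), pixel_size = pixel_size,
                         cells = list(cell), golgi_objects = obj,
                         background = 10, noise_sd = 0, psf_sigma = 0)
  t0 <- render_cell_image(p0)$truth
  ## rescale mean intensities so both integrated intensities are equal
  obj$mean_intensity <- 100 * t0$area_um2_achieved[1] / t0$area_um2_achieved
  p <- image_sim_params(image_shape = c(128, 128), pixel_size = pixel_size,
                        cells = list(cell), golgi_objects = obj,
                        background = 10, noise_sd = noise_sd, psf_sigma = 0)
  render_cell_image(p)
}

score_scene <- function(scene, area_threshold, pixel_size = 0.2) {
  seg <- segment_channel(scene$golgi, method = "fixed", threshold = 50,
                         min_object_area = 0, pixel_size = pixel_size)
  golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                            scene$marker, area_threshold = area_threshold)
}

golgi_population_scores <- function(n_cells, fragmented, seed,
                                    area_threshold = 4.11) {
  cell <- rect_polygon(0.6, 0.6, 12, 12)
  vapply(seq_len(n_cells), function(i) {
    with_seed(derive_seed(seed, i), {
      if (fragmented) {
        pos <- expand.grid(x = seq(2.5, 10.5, length.out = 4),
                           y = seq(2.5, 10.5, length.out = 3))[1:10, ]
        obj <- data.frame(cell = 1L, x_um = pos$x, y_um = pos$y,
                          area_um2 = 1,
                          mean_intensity = stats::rnorm(10, 100, 10))
      } else {
        obj <- data.frame(cell = 1L, x_um = 6.5, y_um = 6.5, area_um2 = 20,
                          mean_intensity = stats::rnorm(1, 100, 10))
      }
      p <- image_sim_params(image_shape = c(64, 64), pixel_size = 0.2,
                            cells = list(cell), golgi_objects = obj,
                            marker_mean_intensity = stats::rnorm(1, 100, 5),
                            background = 10, noise_sd = 2, psf_sigma = 0,
                            seed = derive_seed(seed, 100, i))
      sc <- score_scene(render_cell_image(p), area_threshold)
      sc$normalized_score[1]
    })
  }, numeric(1))
}

check_golgi_score <- function(seed = 1, n_cells = 30) {
  scene <- golgi_two_object_scene()
  truth <- scene$truth
  rows <- lapply(c(4.11, 2.74), function(thr) {
    want <- sum(truth$integrated_intensity[truth$area_um2_achieved > thr]) /
      sum(truth$integrated_intensity)
    got <- score_scene(scene, thr)$large_fraction[1]
    acc_row("golgi_score", sprintf("large_fraction_thr%.2f", thr),
            want, got, 1e-9, abs(got - want) <= 1e-9, nrow(truth))
  })
  intact <- golgi_population_scores(n_cells, FALSE, derive_seed(seed, 61))
  frag <- golgi_population_scores(n_cells, TRUE, derive_seed(seed, 67))
  p <- stats::t.test(intact, frag)$p.value
  rows$sep <- acc_row("golgi_score", "intact_vs_fragmented_p",
                      0, p, 1e-3, p < 1e-3, 2 * n_cells)
  do.call(rbind, rows)
}

check_pearson <- function(seed = 1, n_seeds = 100) {
  mask <- label_image(matrix(1L, 100, 100), pixel_size = 0.2)
  a <- with_seed(seed, matrix(stats::runif(1e4, 10, 100), 100, 100))
  r_same <- pearson_colocalization(a, a, mask)$pooled
  r_inv <- pearson_colocalization(a, 150 - a, mask)$pooled
  nulls <- with_seed(seed + 1L, vapply(seq_len(n_seeds), function(i) {
    x <- matrix(stats::rnorm(1e4), 100, 100)
    y <- matrix(stats::rnorm(1e4), 100, 100)
    abs(pearson_colocalization(x, y, mask)$pooled)
  }, numeric(1)))
  frac <- mean(nulls < 0.05)
  rbind(
    acc_row("pearson", "identical_r", 1, r_same, 1e-12,
            abs(r_same - 1) <= 1e-12, 1e4),
    acc_row("pearson", "inverted_r", -1, r_inv, 1e-12,
            abs(r_inv + 1) <= 1e-12, 1e4),
    acc_row("pearson", "null_fraction_below_0.05", 1, frac, 0.05,
            frac >= 0.95, n_seeds))
}

check_kd_recovery <- function(seed = 1, n_seeds = 100) {
  L <- c(0.25, 0.5, 1, 2, 4, 8)
  clean <- simulate_binding_table(1, 1, L, noise_cv = 0)
  f0 <- fit_one_site(clean$concentration_um, clean$signal)
  rel0 <- abs(f0$kd - 1)
  ## triplicate 8-point titration: the residual degrees of freedom make the
  ## +/- 2 SE interval's nominal coverage comfortably exceed 90%
  Ln <- rep(c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 30), each = 3)
  fits <- lapply(seq_len(n_seeds), function(i)
    with(simulate_binding_table(1, 1, Ln, noise_cv = 0.05,
                                seed = derive_seed(seed, 7, i)),
         fit_one_site(concentration_um, signal)))
  kds <- vapply(fits, `[[`, numeric(1), "kd")
  cover <- vapply(fits, function(f)
    abs(f$kd - 1) <= 2 * f$kd_se, logical(1))
  M <- c(0.1, 0.25, 0.5, 1, 2.5, 5, 10, 25)
  ratios <- vapply(seq_len(n_seeds), function(i) {
    da <- simulate_binding_table(0.46, 0.8, M, noise_cv = 0.05,
                                 seed = derive_seed(seed, 8, i))
    db <- simulate_binding_table(4.6, 0.8, M, noise_cv = 0.05,
                                 seed = derive_seed(seed, 9, i))
    fa <- fit_cosedimentation(da$concentration_um, pmin(da$signal, 1))
    fb <- fit_cosedimentation(db$concentration_um, pmin(db$signal, 1))
    kd_shift_ratio(fa, fb)$ratio
  }, numeric(1))
  rbind(
    acc_row("kd_recovery", "noise_free_rel_error", 0, rel0, 1e-6,
            rel0 <= 1e-6, length(L)),
    acc_row("kd_recovery", "noisy_mean_kd", 1, mean(kds), 0.1,
            abs(mean(kds) - 1) <= 0.1, n_seeds),
    acc_row("kd_recovery", "ci_coverage_2se", 0.95, mean(cover), 0.05,
            mean(cover) >= 0.90, n_seeds),
    acc_row("kd_recovery", "shift_ratio_10x", 10, mean(ratios), 1.5,
            abs(mean(ratios) - 10) <= 1.5, n_seeds))
}

check_determinism <- function(seed = 1) {
  cfg <- default_config()
  cfg$seed <- seed
  cfg$simulate$n_tracks <- 20L
  cfg$simulate$n_frames <- 40L
  d1 <- tempfile("run1_"); d2 <- tempfile("run2_")
  cfg$output_dir <- d1; run_pipeline(cfg)
  cfg$output_dir <- d2; run_pipeline(cfg)
  files <- c("tracks.csv", "tracks_truth.csv", "motion_report.csv")
  same <- vapply(files, function(f)
    identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
              readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))),
    logical(1))
  unlink(c(d1, d2), recursive = TRUE)
  acc_row("determinism", "rerun_byte_identical", 1, mean(same), 0,
          all(same), length(files))
}

#' Run the full parameter-recovery acceptance suite
#'
#' Recomputes every oracle-equivalence and parameter-recovery check from
#' freshly generated synthetic data: minimal-enclosing-circle agreement with
#' brute force, confinement-area and reversal-rate recovery, motion
#' classification accuracy, the moving-motor boundary table, motor-density
#' recovery through the detect-and-count pipeline, Golgi fragmentation
#' scoring and population separation, Pearson colocalization identities and
#' null, K_D recovery and shift ratio, and whole-pipeline determinism.
#'
#' @param seed integer seed for every source of randomness.
#' @param scale multiplier on the number of Monte Carlo replicates (1 = the
#'   full suite; use e.g. 0.2 for a quick pass).
#' @return Data frame with columns `check`, `metric`, `expected`,
#'   `observed`, `tolerance`, `pass`, `n`.
#' @export
acceptance_suite <- function(seed = 1, scale = 1) {
  ns <- function(n) max(10L, as.integer(round(n * scale)))
  out <- rbind(
    check_mec_oracle(seed, n_sets = ns(1000)),
    check_confinement_recovery(seed, n_seeds = ns(100)),
    check_reversal_recovery(seed, n_seeds = ns(200)),
    check_classification(seed, n_per_class = ns(200)),
    check_moving_classifier(),
    check_density_recovery(seed, n_seeds = ns(100)),
    check_golgi_score(seed, n_cells = ns(30)),
    check_pearson(seed, n_seeds = ns(100)),
    check_kd_recovery(seed, n_seeds = ns(100)),
    check_determinism(seed))
  rownames(out) <- NULL
  out
}
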