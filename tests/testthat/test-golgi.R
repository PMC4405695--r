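test_that("segmentation recovers rendered discs with 8-connectivity", {
  scene <- simple_cell_scene(c(5, 2.5, 1))
  seg <- segment_channel(scene$golgi, method = "fixed", threshold = 50,
                         pixel_size = 0.2)
  expect_equal(n_objects(seg), 3)
  got <- sort(object_areas(seg), decreasing = TRUE)
  want <- sort(scene$truth$area_um2_achieved, decreasing = TRUE)
  expect_equal(unname(got), want, tolerance = 1e-12)
  ## labels are ordered by decreasing area
  expect_equal(unname(object_areas(seg)), sort(unname(object_areas(seg)),
                                               decreasing = TRUE))
})

test_that("two blobs touching only diagonally form one object", {
  m <- matrix(0, 8, 8)
  m[2:3, 2:3] <- 100; m[4:5, 4:5] <- 100
  seg <- segment_channel(m, method = "fixed", threshold = 50, pixel_size = 1)
  expect_equal(n_objects(seg), 1)
  m2 <- matrix(0, 8, 8); m2[2, 2] <- 100; m2[6, 6] <- 100
  expect_equal(n_objects(segment_channel(m2, "fixed", threshold = 50,
                                         pixel_size = 1)), 2)
})

test_that("degenerate and over-filtered segmentations are flagged", {
  expect_warning(seg <- segment_channel(matrix(5, 16, 16), method = "otsu"),
                 "uniform")
  expect_equal(n_objects(seg), 0)
  scene <- simple_cell_scene(c(1, 0.5))
  expect_warning(seg2 <- segment_channel(scene$golgi, "fixed", threshold = 50,
                                         min_object_area = 50,
                                         pixel_size = 0.2), "no objects")
  expect_equal(n_objects(seg2), 0)
})

test_that("fragmentation score reproduces hand-computed ground truth", {
  scene <- simple_cell_scene(c(5, 1))     # equal mean intensity
  seg <- segment_channel(scene$golgi, "fixed", threshold = 50,
                         pixel_size = 0.2)
  sc <- golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                                  scene$marker, area_threshold = 4.11)
  tr <- scene$truth
  want <- sum(tr$integrated_intensity[tr$area_um2_achieved > 4.11]) /
    sum(tr$integrated_intensity)
  expect_equal(sc$large_fraction[1], want, tolerance = 1e-12)
  ## every object above threshold
  sc2 <- golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                                   scene$marker, area_threshold = 0.5)
  expect_equal(sc2$large_fraction[1], 1)
  ## large_fraction is monotone non-increasing in the threshold
  fr <- vapply(c(0.5, 2.74, 4.11, 6), function(th)
    golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                              scene$marker, th)$large_fraction[1],
    numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("scores respect channel gain: golgi-scale invariant, marker-inverse", {
  scene <- simple_cell_scene(c(5, 1))
  seg <- segment_channel(scene$golgi, "fixed", threshold = 50,
                         pixel_size = 0.2)
  base <- golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                                    scene$marker, 4.11)
  ## doubling Golgi gain: subtract background, scale, re-add
  g2 <- (scene$golgi - 10) * 2 + 10
  seg_g2 <- segment_channel(g2, "fixed", threshold = 90, pixel_size = 0.2)
  up <- golgi_fragmentation_score(g2, seg_g2, scene$cell_labels,
                                  scene$marker, 4.11)
  expect_equal(up$large_fraction, base$large_fraction, tolerance = 1e-9)
  m2 <- (scene$marker - 10) * 2 + 10
  half <- golgi_fragmentation_score(scene$golgi, seg, scene$cell_labels,
                                    m2, 4.11)
  expect_equal(half$normalized_score, base$normalized_score / 2,
               tolerance = 1e-9)
  expect_equal(half$large_fraction, base$large_fraction)
})

test_that("cells without objects are reported missing, not silently dropped", {
  scene <- simple_cell_scene(c(5, 1))
  seg <- segment_channel(scene$golgi, "fixed", threshold = 50,
                         pixel_size = 0.2)
  ## add an empty second cell
  cl <- scene$cell_labels$labels
  cl[1:20, 1:20] <- 2L
  cells2 <- label_image(cl, 0.2)
  sc <- golgi_fragmentation_score(scene$golgi, seg, cells2, scene$marker, 4.11)
  expect_equal(nrow(sc), 2)
  expect_true(is.na(sc$large_fraction[2]))
  expect_equal(attr(sc, "qc")$cells_without_objects, 2)
})

test_that("condition comparison is a Welch test with a calibrated null", {
  a <- data.frame(normalized_score = rnorm(30, 1, 0.1))
  same <- compare_conditions(a, a)
  expect_gt(same$p_value, 0.9)
  set.seed(3)
  ps <- vapply(1:150, function(i) {
    x <- data.frame(normalized_score = rnorm(25, 5, 1))
    y <- data.frame(normalized_score = rnorm(40, 5, 3))
    compare_conditions(x, y)$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(compare_conditions(a, data.frame(normalized_score = 1)),
               "at least 2")
})

test_that("intact populations outscore fragmented ones at both presets", {
  for (thr in c(4.11, 2.74)) {
    intact <- kinemetry:::golgi_population_scores(12, FALSE, 91,
                                                  area_threshold = thr)
    frag <- kinemetry:::golgi_population_scores(12, TRUE, 97,
                                                area_threshold = thr)
    expect_gt(min(intact), max(frag))
    expect_lt(stats::t.test(intact, frag)$p.value, 1e-3)
  }
})

test_that("pearson colocalization honours exact and null identities", {
  mask <- label_image(matrix(rep(c(1L, 2L), each = 800), 40, 40), 0.2)
  set.seed(6)
  a <- matrix(runif(1600, 10, 50), 40, 40)
  expect_equal(pearson_colocalization(a, a, mask)$pooled, 1)
  inv <- pearson_colocalization(a, 60 - a, mask)
  expect_equal(inv$pooled, -1)
  expect_equal(inv$per_object$r, c(-1, -1))
  flat <- matrix(7, 40, 40)
  expect_true(is.na(pearson_colocalization(a, flat, mask)$pooled))
  expect_error(pearson_colocalization(a, matrix(1, 10, 10), mask), "shape")
  expect_error(pearson_colocalization(a, a, label_image(matrix(0L, 40, 40),
                                                        0.2)), "empty")
})

test_that("total cell intensity is background-subtracted sums", {
  img <- matrix(0, 30, 30)
  cl <- matrix(0L, 30, 30); cl[11:20, 11:20] <- 1L
  img[cl == 1L] <- 10
  li <- label_image(cl, 0.2)
  expect_equal(total_cell_intensity(img, li)$total_intensity, 1000)
  expect_equal(total_cell_intensity(img + 5, li)$total_intensity, 1000)
  expect_equal(total_cell_intensity(matrix(4, 30, 30), li)$total_intensity, 0)
  scene <- simple_cell_scene(c(5, 1))
  tci <- total_cell_intensity(scene$golgi, scene$cell_labels)
  expect_equal(tci$total_intensity, sum(scene$truth$integrated_intensity),
               tolerance = 1e-9)
})
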