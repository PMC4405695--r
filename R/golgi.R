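#' Segment a fluorescence channel into labelled objects
#'
#' Threshold (Otsu-derived or fixed), 8-connected components, discard
#' objects below a minimum area, and label in order of decreasing area.
#'
#' @param image 2-D numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold AU, required for `method = "fixed"`.
#' @param min_object_area um^2; smaller components are dropped.
#' @param pixel_size um per pixel.
#' @return A [label_image()]; empty (all background) with a warning when
#'   nothing survives thresholding, and flagged degenerate (attribute
#'   `degenerate`) when thresholding a near-uniform image.
#' @export
segment_channel <- function(image, method = c("otsu", "fixed"),
                            threshold = NULL, min_object_area = 0,
                            pixel_size = 1) {
  method <- match.arg(method)
  image <- as.matrix(image)
  degenerate <- FALSE
  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) <= 0) {
      warning("uniform image: Otsu threshold undefined, returning empty labels")
      return(structure(label_image(matrix(0L, nrow(image), ncol(image)),
                                   pixel_size), degenerate = TRUE))
    }
    threshold <- EBImage::otsu(EBImage::Image(image), range = rng)
  } else {
    check_scalar(threshold, "threshold")
  }
  mask <- image > threshold
  lab <- cc_label_8(mask)
  if (min_object_area > 0 && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab)) * pixel_size^2
    drop <- which(areas < min_object_area)
    if (length(drop)) {
      lab[lab %in% drop] <- 0L
      lab <- relabel_by_area(lab)
    }
  }
  if (max(lab) == 0)
    warning("segmentation produced no objects")
  if (max(lab) == 1 && sum(lab > 0) > 0.9 * length(lab))
    degenerate <- TRUE
  structure(label_image(lab, pixel_size), degenerate = degenerate)
}

## Median intensity outside all cell masks: robust, parameter-free
## background estimate.
background_level <- function(image, cell_labels) {
  out <- image[cell_labels$labels == 0]
  if (!length(out)) 0 else stats::median(out)
}

#' Per-cell Golgi fragmentation score
#'
#' For each cell, the fraction of background-subtracted Golgi staining held
#' in segmented objects larger than `area_threshold`, optionally normalized
#' by the cell's mean background-subtracted marker intensity. Objects are
#' assigned to the cell holding the majority of their pixels (ties to the
#' lower cell id).
#'
#' @param golgi_img Golgi-channel intensity matrix.
#' @param golgi_labels [label_image()] of Golgi objects.
#' @param cell_labels [label_image()] of cell masks.
#' @param marker_img marker-channel intensity matrix (expression
#'   normalization); may be `NULL` to skip normalization.
#' @param area_threshold um^2; objects strictly larger count as "large".
#'   Presets: 4.11 (siRNA experiments) and 2.74 (nocodazole experiments).
#' @param weight `"intensity"` (fraction of staining, default) or `"area"`
#'   (fraction of object area).
#' @return Data frame of class `cell_scores`, one row per cell: `cell_id`,
#'   `n_objects`, `golgi_total_intensity`, `large_object_intensity`,
#'   `large_fraction`, `mean_marker_intensity`, `normalized_score`,
#'   `area_threshold`. Cells without Golgi objects get `NA` scores and are
#'   listed in attribute `qc`.
#' @export
golgi_fragmentation_score <- function(golgi_img, golgi_labels, cell_labels,
                                      marker_img = NULL, area_threshold = 4.11,
                                      weight = c("intensity", "area")) {
  weight <- match.arg(weight)
  check_scalar(area_threshold, "area_threshold", min = 0, strict_min = TRUE)
  stopifnot(inherits(golgi_labels, "label_image"),
            inherits(cell_labels, "label_image"))
  ps <- golgi_labels$pixel_size
  bg <- background_level(golgi_img, cell_labels)
  mbg <- if (!is.null(marker_img)) background_level(marker_img, cell_labels)
         else NA_real_
  k <- n_objects(golgi_labels)
  obj <- if (k > 0) {
    lab <- golgi_labels$labels
    idx <- which(lab > 0)
    df <- data.frame(object = lab[idx],
                     cell = cell_labels$labels[idx],
                     val = golgi_img[idx] - bg)
    per <- do.call(rbind, lapply(split(df, df$object), function(d) {
      cells <- d$cell[d$cell > 0]
      cell <- if (!length(cells)) 0L else {
        tab <- table(cells)
        cand <- as.integer(names(tab)[tab == max(tab)])
        min(cand)                        # deterministic tie-break
      }
      data.frame(object = d$object[1], cell = cell,
                 area = nrow(d) * ps^2, intensity = sum(d$val))
    }))
    per
  } else data.frame(object = integer(0), cell = integer(0),
                    area = numeric(0), intensity = numeric(0))
  w <- if (weight == "intensity") obj$intensity else obj$area
  cells <- seq_len(n_objects(cell_labels))
  rows <- lapply(cells, function(cid) {
    mine <- obj$cell == cid
    cell_px <- cell_labels$labels == cid
    marker_mean <- if (!is.null(marker_img))
      mean(marker_img[cell_px]) - mbg else NA_real_
    if (!any(mine)) {
      return(data.frame(cell_id = cid, n_objects = 0L,
                        golgi_total_intensity = NA_real_,
                        large_object_intensity = NA_real_,
                        large_fraction = NA_real_,
                        mean_marker_intensity = marker_mean,
                        normalized_score = NA_real_,
                        area_threshold = area_threshold))
    }
    total <- sum(w[mine])
    large <- sum(w[mine & obj$area > area_threshold])
    frac <- if (total > 0) large / total else NA_real_
    norm <- if (!is.null(marker_img) && is.finite(marker_mean) &&
                marker_mean > 0) frac / marker_mean else NA_real_
    data.frame(cell_id = cid, n_objects = sum(mine),
               golgi_total_intensity = sum(obj$intensity[mine]),
               large_object_intensity = sum(obj$intensity[mine &
                                                obj$area > area_threshold]),
               large_fraction = frac,
               mean_marker_intensity = marker_mean,
               normalized_score = norm,
               area_threshold = area_threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "qc") <- list(cells_without_objects = out$cell_id[out$n_objects == 0],
                          background_golgi = bg, background_marker = mbg)
  class(out) <- c("cell_scores", "data.frame")
  out
}

#' Compare Golgi scores between two conditions
#'
#' Two-sided two-sample t-test (Welch by default) on a per-cell score.
#'
#' @param scores_a,scores_b [golgi_fragmentation_score()] outputs.
#' @param metric column to compare (default `normalized_score`; falls back
#'   to `large_fraction` when normalization is absent).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return List with `statistic`, `p_value`, `mean_a`, `mean_b`, `se_a`,
#'   `se_b`, `n_a`, `n_b`.
#' @export
compare_conditions <- function(scores_a, scores_b, metric = "normalized_score",
                               var_equal = FALSE) {
  pick <- function(s) {
    v <- s[[metric]]
    if (is.null(v) || all(!is.finite(v))) v <- s[["large_fraction"]]
    v[is.finite(v)]
  }
  a <- pick(scores_a); b <- pick(scores_b)
  if (length(a) < 2 || length(b) < 2)
    stop("need at least 2 cells per group", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_a = mean(a), mean_b = mean(b),
       se_a = stats::sd(a) / sqrt(length(a)),
       se_b = stats::sd(b) / sqrt(length(b)),
       n_a = length(a), n_b = length(b))
}

#' Masked Pearson colocalization
#'
#' Pearson correlation between two channels over the pixels of each mask
#' object, and pooled over all object pixels.
#'
#' @param channel_a,channel_b intensity matrices of identical shape.
#' @param mask [label_image()] whose positive labels define the pixels used.
#' @return List with `per_object` (data frame `object`, `r`, `n_pixels`) and
#'   `pooled` (r over all masked pixels). Zero-variance objects give `NA`.
#' @export
pearson_colocalization <- function(channel_a, channel_b, mask) {
  stopifnot(inherits(mask, "label_image"))
  if (!all(dim(channel_a) == dim(channel_b)) ||
      !all(dim(channel_a) == dim(mask$labels)))
    stop("channel and mask shapes differ", call. = FALSE)
  idx <- which(mask$labels > 0)
  if (!length(idx)) stop("mask is empty", call. = FALSE)
  safe_cor <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }
  labs <- mask$labels[idx]
  per <- do.call(rbind, lapply(sort(unique(labs)), function(l) {
    i <- idx[labs == l]
    data.frame(object = l, r = safe_cor(channel_a[i], channel_b[i]),
               n_pixels = length(i))
  }))
  list(per_object = per,
       pooled = safe_cor(channel_a[idx], channel_b[idx]))
}

#' Total background-subtracted intensity per cell
#'
#' Expression-matching QC: the sum of background-subtracted pixel
#' intensities within each cell mask.
#'
#' @param image intensity matrix.
#' @param cell_labels [label_image()] of cell masks.
#' @return Data frame with `cell_id`, `total_intensity`, `area_um2`.
#' @export
total_cell_intensity <- function(image, cell_labels) {
  stopifnot(inherits(cell_labels, "label_image"))
  bg <- background_level(image, cell_labels)
  ps <- cell_labels$pixel_size
  cells <- seq_len(n_objects(cell_labels))
  do.call(rbind, lapply(cells, function(cid) {
    px <- cell_labels$labels == cid
    data.frame(cell_id = cid,
               total_intensity = sum(image[px]) - sum(px) * bg,
               area_um2 = sum(px) * ps^2)
  }))
}
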