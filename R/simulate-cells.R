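#' Parameters for two-channel cell image simulation
#'
#' Describes a field of cells (polygons in micrometres), disc-shaped Golgi
#' objects with requested areas and mean intensities, and a diffuse marker
#' channel that is uniform within each cell — the ground-truth scene behind
#' Golgi-fragmentation scoring and masked colocalization.
#'
#' @param image_shape `c(rows, cols)` pixels.
#' @param pixel_size um per pixel.
#' @param cells list of polygon matrices/data frames with columns x, y (um).
#' @param golgi_objects data frame with `cell`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity` (one disc per row; centroid must lie inside its cell).
#' @param marker_mean_intensity per-cell marker level, AU (recycled).
#' @param background,noise_sd additive offset and Gaussian noise, AU.
#' @param psf_sigma Gaussian blur applied to the Golgi structures, pixels.
#' @param seed integer seed.
#' @return An `image_sim_params` list.
#' @export
image_sim_params <- function(image_shape = c(256, 256), pixel_size = 0.2,
                             cells, golgi_objects,
                             marker_mean_intensity = 100,
                             background = 10, noise_sd = 0, psf_sigma = 0,
                             seed = NULL) {
  check_scalar(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_scalar(background, "background", min = 0)
  check_scalar(noise_sd, "noise_sd", min = 0)
  check_scalar(psf_sigma, "psf_sigma", min = 0)
  if (!is.list(cells) || !length(cells))
    stop_field("cells", "must be a non-empty list of polygons")
  need <- c("cell", "x_um", "y_um", "area_um2", "mean_intensity")
  if (!all(need %in% names(golgi_objects)))
    stop_field("golgi_objects",
               paste("must have columns", paste(need, collapse = ", ")))
  if (any(golgi_objects$area_um2 <= 0))
    stop_field("golgi_objects$area_um2", "must be > 0")
  marker <- rep_len(marker_mean_intensity, length(cells))
  structure(list(image_shape = image_shape, pixel_size = pixel_size,
                 cells = lapply(cells, as.matrix),
                 golgi_objects = golgi_objects,
                 marker_mean_intensity = marker, background = background,
                 noise_sd = noise_sd, psf_sigma = psf_sigma, seed = seed),
            class = "image_sim_params")
}

## Pixel-centre coordinate grids in um for an image shape.
pixel_grid <- function(shape, pixel_size) {
  x <- ((seq_len(shape[2]) - 1) * pixel_size)
  y <- ((seq_len(shape[1]) - 1) * pixel_size)
  list(x = matrix(x, shape[1], shape[2], byrow = TRUE),
       y = matrix(y, shape[1], shape[2]))
}

#' Render a two-channel cell image with ground truth
#'
#' Golgi objects are rasterized as filled discs of the requested area
#' (nearest achievable on the pixel grid; the achieved pixel-quantized area
#' is what the ground truth records), optionally Gaussian-blurred, plus
#' background and noise. The marker channel is uniform inside each cell.
#'
#' @param params an [image_sim_params()].
#' @return List with `golgi` and `marker` (intensity matrices), `cell_labels`
#'   and `object_labels` ([label_image()]s), and `truth`: a data frame per
#'   object with achieved area (um^2) and integrated intensity before blur
#'   and noise.
#' @export
render_cell_image <- function(params) {
  stopifnot(inherits(params, "image_sim_params"))
  p <- params
  shape <- p$image_shape
  g <- pixel_grid(shape, p$pixel_size)
  cell_lab <- matrix(0L, shape[1], shape[2])
  for (i in seq_along(p$cells)) {
    poly <- p$cells[[i]]
    inside <- pracma::inpolygon(as.vector(g$x), as.vector(g$y),
                                poly[, 1], poly[, 2], boundary = TRUE)
    cell_lab[matrix(inside, shape[1], shape[2])] <- i
  }
  obj <- p$golgi_objects
  for (i in seq_len(nrow(obj))) {
    poly <- p$cells[[obj$cell[i]]]
    if (!pracma::inpolygon(obj$x_um[i], obj$y_um[i], poly[, 1], poly[, 2],
                           boundary = TRUE))
      stop(sprintf("golgi object %d lies outside cell polygon %d",
                   i, obj$cell[i]), call. = FALSE)
  }
  golgi <- matrix(0, shape[1], shape[2])
  obj_lab <- matrix(0L, shape[1], shape[2])
  truth <- obj
  truth$area_um2_achieved <- NA_real_
  truth$integrated_intensity <- NA_real_
  for (i in seq_len(nrow(obj))) {
    r <- sqrt(obj$area_um2[i] / pi)
    inside <- (g$x - obj$x_um[i])^2 + (g$y - obj$y_um[i])^2 <= r^2
    npx <- sum(inside)
    golgi[inside] <- golgi[inside] + obj$mean_intensity[i]
    obj_lab[inside] <- i
    truth$area_um2_achieved[i] <- npx * p$pixel_size^2
    truth$integrated_intensity[i] <- npx * obj$mean_intensity[i]
  }
  if (p$psf_sigma > 0)
    golgi <- EBImage::imageData(EBImage::gblur(golgi, sigma = p$psf_sigma,
                                               boundary = "replicate"))
  marker <- matrix(0, shape[1], shape[2])
  for (i in seq_along(p$cells))
    marker[cell_lab == i] <- p$marker_mean_intensity[i]
  golgi <- golgi + p$background
  marker <- marker + p$background
  with_seed(p$seed, {
    if (p$noise_sd > 0) {
      golgi <- golgi + matrix(stats::rnorm(length(golgi), sd = p$noise_sd),
                              shape[1], shape[2])
      marker <- marker + matrix(stats::rnorm(length(marker), sd = p$noise_sd),
                                shape[1], shape[2])
    }
    list(golgi = golgi, marker = marker,
         cell_labels = label_image(cell_lab, p$pixel_size, "cell mask"),
         object_labels = label_image(obj_lab, p$pixel_size, "golgi truth"),
         truth = truth)
  })
}

#' Convenience polygon: a rectangle in micrometres
#' @param x0,y0,x1,y1 corners, um.
#' @return 4x2 matrix of vertices.
#' @export
rect_polygon <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}
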