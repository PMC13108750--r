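# Synthetic image generators. These emulate the brightfield well images the
# morphometry stage consumes, with stored ground truth so segmentation, yield
# and aggregation metrics can be checked against known answers.

render_intensity <- function(mask, contrast, blur_sigma, noise_sd, background = 0) {
  img <- matrix(background, nrow(mask), ncol(mask))
  img[mask] <- background + contrast
  if (blur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, sigma = blur_sigma))
  if (noise_sd > 0)
    img <- img + matrix(rnorm(length(img), sd = noise_sd), nrow(img), ncol(img))
  img
}

#' Generate a single synthetic spheroid image
#'
#' Renders one disk of known radius into a frame, with Gaussian-blurred edges
#' and additive Gaussian noise. The analytic disk area is the ground truth for
#' segmentation-recovery tests.
#'
#' @param radius_px disk radius in pixels (>= 3).
#' @param center disk center as `c(row, col)` pixel coordinates; default is the
#'   frame center.
#' @param contrast intensity step between disk and background.
#' @param blur_sigma Gaussian blur sigma in pixels (>= 0; 0 = sharp edge).
#' @param noise_sd additive Gaussian noise standard deviation, in intensity
#'   units (>= 0).
#' @param seed integer RNG seed; identical calls give bit-identical frames.
#' @param dim frame dimensions `c(rows, cols)` in pixels.
#' @param pixel_size micrometers per pixel.
#' @return An [image_frame()] with attribute `truth` holding the generating
#'   parameters and the analytic disk area in square micrometers.
#' @examples
#' fr <- make_spheroid_frame(radius_px = 40, noise_sd = 0.1, seed = 1,
#'                           dim = c(128, 128))
#' @export
make_spheroid_frame <- function(radius_px, center = NULL, contrast = 1,
                                blur_sigma = 0, noise_sd = 0, seed = 1,
                                dim = c(512, 512), pixel_size = 2.5) {
  check_number(radius_px, "radius_px", lower = 3)
  check_number(blur_sigma, "blur_sigma", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  if (is.null(center)) center <- (dim + 1) / 2
  if (center[1] - radius_px < 1 || center[1] + radius_px > dim[1] ||
      center[2] - radius_px < 1 || center[2] + radius_px > dim[2])
    stop_sf("disk (center ", paste(round(center, 1), collapse = ","),
            ", radius ", radius_px, " px) does not fit inside a ",
            dim[1], "x", dim[2], " frame")
  mask <- raster_disk(dim, center, radius_px)
  img <- with_seed(seed, render_intensity(mask, contrast, blur_sigma, noise_sd))
  fr <- image_frame(img, pixel_size = pixel_size, timestamp = 0)
  attr(fr, "truth") <- list(
    radius_px = radius_px, center = center,
    area_px = pi * radius_px^2,
    area_um2 = pi * (radius_px * pixel_size)^2
  )
  fr
}

# Deterministic close-packed positions filling a disk of radius `final_radius`
# with cells of radius `cell_radius` (concentric rings). Units: micrometers,
# relative to the aggregate center.
equilibrium_positions <- function(final_radius, cell_radius) {
  rho_max <- final_radius - cell_radius
  n_rings <- max(1L, ceiling(rho_max / (1.2 * cell_radius)))
  radii <- seq(0, rho_max, length.out = n_rings + 1L)
  pos <- list(c(0, 0))
  for (rho in radii[-1]) {
    n_k <- max(3L, round(2 * pi * rho / (1.4 * cell_radius)))
    ang <- 2 * pi * seq_len(n_k) / n_k + rho  # ring-dependent phase offset
    for (a in ang) pos[[length(pos) + 1L]] <- rho * c(cos(a), sin(a))
  }
  do.call(rbind, pos)
}

#' Generate a synthetic spheroid aggregation time-lapse
#'
#' Emulates cells aggregating on a non-adhesive substrate: small cell disks
#' drift with overdamped (exponential) kinetics from scattered initial
#' positions toward a close-packed equilibrium configuration of radius
#' `final_radius`. Projected size therefore shrinks monotonically in
#' expectation and circularity rises toward ~1, as in time-lapse recordings of
#' liquid-overlay spheroid formation. Frames are spaced 0.5 h apart.
#'
#' @param n_frames number of frames (>= 2).
#' @param scatter0 standard deviation (um) of the initial cell displacement
#'   from its equilibrium position; 0 gives a compact round aggregate from
#'   frame one.
#' @param final_radius equilibrium aggregate radius in micrometers.
#' @param rate aggregation rate constant in 1/h (> 0); `Inf` collapses the
#'   sequence to its equilibrium configuration from the first frame.
#' @param seed integer RNG seed.
#' @param dim,pixel_size frame geometry (pixels; um/pixel).
#' @param contrast,blur_sigma,noise_sd rendering parameters as in
#'   [make_spheroid_frame()].
#' @param cell_radius radius of an individual cell disk (um); default
#'   `final_radius / 5`.
#' @return A list of [image_frame()]s with attribute `truth` containing the
#'   equilibrium area actually covered by the rendered equilibrium
#'   configuration (um^2) and the generating parameters.
#' @export
make_aggregation_timelapse <- function(n_frames, scatter0, final_radius, rate,
                                       seed = 1, dim = c(512, 512),
                                       pixel_size = 2.5, contrast = 1,
                                       blur_sigma = 1, noise_sd = 0.02,
                                       cell_radius = final_radius / 5) {
  if (n_frames < 2) stop_sf("`n_frames` must be >= 2")
  check_number(scatter0, "scatter0", lower = 0)
  if (!(rate > 0)) stop_sf("`rate` must be > 0")
  half_um <- min(dim) / 2 * pixel_size
  if (final_radius >= half_um)
    stop_sf("`final_radius` (", final_radius, " um) exceeds the frame half-extent (",
            half_um, " um)")
  q <- equilibrium_positions(final_radius, cell_radius)
  center_px <- (dim + 1) / 2
  times <- 0.5 * (seq_len(n_frames) - 1L)

  render_at <- function(pos_um, blur, noise) {
    mask <- matrix(FALSE, dim[1], dim[2])
    r_px <- cell_radius / pixel_size
    for (i in seq_len(nrow(pos_um))) {
      ctr <- center_px + pos_um[i, ] / pixel_size
      mask <- mask | raster_disk(dim, ctr, r_px)
    }
    render_intensity(mask, contrast, blur, noise)
  }

  with_seed(seed, {
    d <- matrix(rnorm(2 * nrow(q), sd = scatter0), ncol = 2)
    frames <- vector("list", n_frames)
    for (k in seq_len(n_frames)) {
      decay <- if (is.infinite(rate)) 0 else exp(-rate * times[k])
      frames[[k]] <- image_frame(render_at(q + d * decay, blur_sigma, noise_sd),
                                 pixel_size = pixel_size, timestamp = times[k])
    }
    # equilibrium ground truth: the rendered equilibrium mask itself
    eq_mask <- render_at(q, 0, 0) > 0
    attr(frames, "truth") <- list(
      final_radius = final_radius, cell_radius = cell_radius,
      rate = rate, scatter0 = scatter0,
      equilibrium_area_um2 = sum(eq_mask) * pixel_size^2
    )
    frames
  })
}

#' Generate a synthetic plate with per-well ground truth
#'
#' Each well independently receives 0, 1 or >= 2 objects; a single object is
#' round (a disk) with probability `1 - p_irregular` and otherwise an elongated
#' ellipse whose circularity falls below typical "round" thresholds. The truth
#' table makes plate yield exactly countable, independent of segmentation.
#'
#' @param n_wells number of wells (>= 1).
#' @param p_zero,p_multi,p_irregular probabilities of an empty well, a
#'   multi-object well, and (given a single object) an irregular shape.
#'   `p_zero + p_multi` must be <= 1.
#' @param seed integer RNG seed.
#' @param dim,pixel_size per-well frame geometry.
#' @param render if `FALSE`, skip image rendering and return truth only.
#' @param blur_sigma,noise_sd,contrast rendering parameters.
#' @return A list with `truth` (one row per well: `well_id`, `n_objects`,
#'   `single_round`), `objects` (one row per object with center/radius/class),
#'   `frames` (list of [image_frame()], `NULL` when `render = FALSE`), and the
#'   well geometry (`well_radius_um`, `well_center_um`).
#' @export
make_plate_truth <- function(n_wells, p_zero = 0.1, p_multi = 0.1,
                             p_irregular = 0.1, seed = 1,
                             dim = c(128, 128), pixel_size = 2.5,
                             render = TRUE, blur_sigma = 1, noise_sd = 0.05,
                             contrast = 1) {
  if (n_wells < 1) stop_sf("`n_wells` must be >= 1")
  for (p in c(p_zero, p_multi, p_irregular))
    if (p < 0 || p > 1) stop_sf("probabilities must lie in [0, 1]")
  if (p_zero + p_multi > 1) stop_sf("`p_zero` + `p_multi` must be <= 1")
  half_um <- min(dim) / 2 * pixel_size
  well_radius <- 0.85 * half_um
  # physical coordinates: pixel i maps to (i - 0.5) * pixel_size from the
  # frame origin, so the frame center is dim/2 * pixel_size
  well_center <- dim / 2 * pixel_size

  with_seed(seed, {
    objects <- list()
    truth <- data.frame(well_id = sprintf("W%03d", seq_len(n_wells)),
                        n_objects = 0L, single_round = FALSE)
    frames <- if (render) vector("list", n_wells) else NULL
    for (w in seq_len(n_wells)) {
      u <- runif(1)
      n_obj <- if (u < p_zero) 0L else if (u < p_zero + p_multi) sample(2:3, 1) else 1L
      truth$n_objects[w] <- n_obj
      mask <- matrix(FALSE, dim[1], dim[2])
      if (n_obj == 1L) {
        irregular <- runif(1) < p_irregular
        truth$single_round[w] <- !irregular
        r_um <- runif(1, 0.2, 0.35) * well_radius
        pos <- runif(2, -1, 1) * (well_radius - 1.2 * r_um) / sqrt(2)
        ctr_px <- (well_center + pos) / pixel_size + 0.5
        if (irregular) {
          aspect <- runif(1, 2.5, 3.5)
          b <- r_um / pixel_size / sqrt(aspect)
          mask <- mask | raster_ellipse(dim, ctr_px, a = b * aspect, b = b,
                                        theta = runif(1, 0, pi))
        } else {
          mask <- mask | raster_disk(dim, ctr_px, r_um / pixel_size)
        }
        objects[[length(objects) + 1L]] <- data.frame(
          well_id = truth$well_id[w], center_x_um = well_center[2] + pos[2],
          center_y_um = well_center[1] + pos[1], radius_um = r_um,
          class = if (irregular) "irregular" else "round")
      } else if (n_obj >= 2L) {
        ang <- runif(1, 0, 2 * pi) + 2 * pi * seq_len(n_obj) / n_obj
        for (j in seq_len(n_obj)) {
          r_um <- runif(1, 0.10, 0.16) * well_radius
          pos <- 0.5 * well_radius * c(sin(ang[j]), cos(ang[j]))
          ctr_px <- (well_center + pos) / pixel_size + 0.5
          mask <- mask | raster_disk(dim, ctr_px, r_um / pixel_size)
          objects[[length(objects) + 1L]] <- data.frame(
            well_id = truth$well_id[w], center_x_um = well_center[2] + pos[2],
            center_y_um = well_center[1] + pos[1], radius_um = r_um,
            class = "multi")
        }
      }
      if (render)
        frames[[w]] <- image_frame(
          render_intensity(mask, contrast, blur_sigma, noise_sd),
          pixel_size = pixel_size, timestamp = 0)
    }
    if (render) names(frames) <- truth$well_id
    list(truth = truth,
         objects = if (length(objects)) do.call(rbind, objects) else NULL,
         frames = frames,
         well_radius_um = well_radius, well_center_um = well_center)
  })
}
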