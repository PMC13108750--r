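# Shared fixture builders (everything is generated in code; no stored data).

# binary disk mask, via the package's rasterizer
disk_mask <- function(radius, pad = 11) {
  d <- 2 * radius + 2 * pad - 1
  spheroflux:::raster_disk(c(d, d), c(radius + pad, radius + pad), radius)
}

ellipse_mask <- function(a, b, pad = 11) {
  d <- 2 * ceiling(max(a, b)) + 2 * pad - 1
  ctr <- ceiling(max(a, b)) + pad
  spheroflux:::raster_ellipse(c(d, d), c(ctr, ctr), a, b)
}

# per-well shape tables built directly from a plate truth table (bypassing
# segmentation), with circularity 1 for round objects and 0.5 otherwise
shapes_from_truth <- function(truth) {
  out <- lapply(seq_len(nrow(truth)), function(i) {
    n <- truth$n_objects[i]
    if (n == 0L) return(data.frame(circularity = numeric(0)))
    c_val <- if (n == 1L && truth$single_round[i]) 1 else 0.5
    data.frame(circularity = rep(c_val, n))
  })
  names(out) <- truth$well_id
  out
}

# largest-object area of a segmented frame, in um^2
segmented_area <- function(frame, min_area_px = 50) {
  sh <- extract_shapes(morphological_cleanup(chan_vese_segment(frame), 3),
                       min_area_px = min_area_px)
  sh$area_um2[which.max(sh$area_um2)]
}

running_mean <- function(x, k) {
  stats::filter(x, rep(1 / k, k), sides = 2)
}
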