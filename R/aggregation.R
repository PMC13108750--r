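# Aggregation kinetics: per-frame morphometry of a time-lapse and detection of
# the equilibrium plateau where spheroids neither grow nor shrink.

#' Track spheroid aggregation over a time-lapse
#'
#' Runs segmentation, morphological cleanup and shape extraction on every
#' frame. Per frame, size is the total foreground area and circularity is that
#' of the largest object (ties broken by lower label). Frames whose
#' segmentation fails or finds no object are recorded as missing (`NA`), never
#' interpolated.
#'
#' @param frames list of [image_frame()]s with strictly increasing timestamps
#'   (>= 2 frames).
#' @param params segmentation parameters, see [cv_params()].
#' @param cleanup_radius structuring-element radius for
#'   [morphological_cleanup()] (pixels).
#' @param min_area_px minimum object size in pixels, see [extract_shapes()].
#' @return Data frame of class `aggregation_trajectory` with columns `time_h`,
#'   `size_um2`, `circularity`; attribute `n_missing` counts failed frames.
#' @export
track_aggregation <- function(frames, params = cv_params(), cleanup_radius = 3,
                              min_area_px = 9) {
  if (length(frames) < 2L) stop_sf("need >= 2 frames")
  times <- vapply(frames, function(f) as_frame(f)$timestamp, numeric(1))
  if (any(diff(times) <= 0)) stop_sf("frame timestamps must be strictly increasing")
  size <- circ <- rep(NA_real_, length(frames))
  for (k in seq_along(frames)) {
    sh <- tryCatch({
      m <- chan_vese_segment(frames[[k]], params)
      m <- morphological_cleanup(m, radius = cleanup_radius)
      extract_shapes(m, min_area_px = min_area_px)
    }, error = function(e) NULL)
    if (is.null(sh) || nrow(sh) == 0L) next
    size[k] <- sum(sh$area_um2)
    big <- which(sh$area_um2 == max(sh$area_um2))[1]  # tie: lower label wins
    circ[k] <- sh$circularity[big]
  }
  if (all(is.na(size))) stop_sf("segmentation failed on every frame")
  out <- data.frame(time_h = times, size_um2 = size, circularity = circ)
  attr(out, "n_missing") <- sum(is.na(size))
  class(out) <- c("aggregation_trajectory", "data.frame")
  out
}

#' Detect the aggregation equilibrium plateau
#'
#' Finds the earliest time `t*` such that over the window `[t*, t* + window]`
#' the least-squares slope of size versus time, divided by the window's mean
#' size, is below `slope_tol` in absolute value — i.e. the spheroid is neither
#' significantly growing nor shrinking.
#'
#' @param traj an `aggregation_trajectory` (see [track_aggregation()]); must
#'   span at least `2 * window`.
#' @param window plateau window length in hours.
#' @param slope_tol relative slope tolerance in fraction per hour.
#' @return A list: `reached` (logical), and when reached `time_h` (= `t*`),
#'   `mean_size_um2` and `rel_slope` over the detected window.
#' @export
detect_equilibrium <- function(traj, window = 10, slope_tol = 0.01) {
  stopifnot(is.data.frame(traj), all(c("time_h", "size_um2") %in% names(traj)))
  check_number(window, "window", lower = 0, strict_lower = TRUE)
  span <- diff(range(traj$time_h))
  if (span < 2 * window)
    stop_sf("trajectory spans ", span, " h; need >= 2 * window (", 2 * window, " h)")
  for (i in seq_len(nrow(traj))) {
    t0 <- traj$time_h[i]
    if (t0 + window > max(traj$time_h)) break
    win <- traj$time_h >= t0 & traj$time_h <= t0 + window & !is.na(traj$size_um2)
    if (sum(win) < 3L) next
    fit <- lm(size_um2 ~ time_h, data = traj[win, ])
    m <- mean(traj$size_um2[win])
    rel <- abs(coef(fit)[["time_h"]]) / m
    if (rel < slope_tol)
      return(list(reached = TRUE, time_h = t0, mean_size_um2 = m,
                  rel_slope = rel))
  }
  list(reached = FALSE)
}
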