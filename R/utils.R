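# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route randomness through this so they are pure functions of
# their arguments (seed included).
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

stop_sf <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_sf(sprintf("`%s` must be a single finite number", name))
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_sf(sprintf("`%s` = %g is outside the allowed range", name, x))
  invisible(x)
}

#' Construct an image frame
#'
#' A frame is the unit the morphometry functions consume: a numeric intensity
#' matrix plus the physical pixel size and an acquisition timestamp.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size physical pixel edge length in micrometers (> 0).
#' @param timestamp acquisition time in hours (>= 0).
#' @return An object of class `image_frame`: a list with elements `pixels`,
#'   `pixel_size` and `timestamp`.
#' @export
image_frame <- function(pixels, pixel_size, timestamp = 0) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_sf("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels))) stop_sf("frame intensities must all be finite")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  check_number(timestamp, "timestamp", lower = 0)
  structure(list(pixels = pixels, pixel_size = pixel_size, timestamp = timestamp),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %.3g um/px, t = %.2f h\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$timestamp))
  invisible(x)
}

as_frame <- function(x) {
  if (inherits(x, "image_frame")) return(x)
  stop_sf("expected an `image_frame` (see `image_frame()`)")
}

# Rasterize a filled disk into a logical matrix. Pixel centers at integer
# coordinates (1-based matrix indices); a pixel is inside when its center is
# within `radius` of `center` = c(row, col).
raster_disk <- function(dim, center, radius) {
  r <- matrix(seq_len(dim[1]), nrow = dim[1], ncol = dim[2])
  cc <- matrix(seq_len(dim[2]), nrow = dim[1], ncol = dim[2], byrow = TRUE)
  (r - center[1])^2 + (cc - center[2])^2 <= radius^2
}

# Rasterize a filled axis-aligned ellipse (optionally rotated by theta).
raster_ellipse <- function(dim, center, a, b, theta = 0) {
  r <- matrix(seq_len(dim[1]), nrow = dim[1], ncol = dim[2]) - center[1]
  cc <- matrix(seq_len(dim[2]), nrow = dim[1], ncol = dim[2], byrow = TRUE) - center[2]
  u <- cc * cos(theta) + r * sin(theta)
  v <- -cc * sin(theta) + r * cos(theta)
  (u / a)^2 + (v / b)^2 <= 1
}
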