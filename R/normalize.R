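# Normalization strategies for spheroid flux data: experiment-median scaling,
# seeded-cell-number scaling, projected-area scaling, and the 2D
# measured-count reference.

# metabolic endpoint columns a median factor applies to (ratios such as
# coupling efficiency are scale-invariant and left untouched)
METABOLIC_COLS <- c("ocr_baseline", "ocr_oligomycin", "ocr_fccp", "ocr_rotaa",
                    "non_mito", "basal", "atp_linked", "proton_leak",
                    "maximal", "spare")

#' Median normalization within experiment and cell line
#'
#' Removes multiplicative between-experiment (batch) effects. For each
#' experiment x cell line group: the median of maximal respiration is computed
#' for each distinct seeded cell number, the normalization factor `F` is the
#' arithmetic mean of those medians, and every metabolic value column of every
#' well in the group is divided by `F`. Because `F` is multiplicative, a batch
#' factor applied to a whole experiment cancels exactly; applying the
#' normalization twice is idempotent up to the second pass's factors being 1.
#'
#' @param set well table with columns `experiment_id`, `cell_line`,
#'   `cell_number`, `maximal`, plus the metabolic columns to scale.
#' @param value_cols columns to divide by the factor; defaults to all
#'   metabolic endpoint columns present in `set`.
#' @return A list: `data` (the normalized table) and `factors` (one row per
#'   experiment x cell line: `factor`, number of per-cell-number medians,
#'   `applied`). Groups with a non-positive factor are left unnormalized with
#'   a warning and `applied = FALSE`.
#' @export
median_normalize <- function(set, value_cols = NULL) {
  need <- c("experiment_id", "cell_line", "cell_number", "maximal")
  if (!all(need %in% names(set)))
    stop_sf("`set` needs columns: ", paste(need, collapse = ", "))
  if (is.null(value_cols)) value_cols <- intersect(METABOLIC_COLS, names(set))
  stopifnot(all(value_cols %in% names(set)), "maximal" %in% value_cols)
  out <- set
  factors <- list()
  for (e in unique(set$experiment_id)) {
    for (cl in unique(set$cell_line)) {
      idx <- which(set$experiment_id == e & set$cell_line == cl)
      if (!length(idx)) next
      medians <- tapply(set$maximal[idx], set$cell_number[idx], median)
      f <- mean(medians)
      applied <- is.finite(f) && f > 0
      if (applied) {
        out[idx, value_cols] <- out[idx, value_cols] / f
      } else {
        warning("experiment ", e, ", cell line ", cl,
                ": non-positive normalization factor; group left unnormalized",
                call. = FALSE)
      }
      factors[[length(factors) + 1L]] <- data.frame(
        experiment_id = e, cell_line = cl, n_medians = length(medians),
        factor = f, applied = applied)
    }
  }
  fac <- do.call(rbind, factors)
  rownames(fac) <- NULL
  list(data = out, factors = fac)
}

#' Scale values by seeded cell number
#'
#' `value * unit / N`, reported per `unit` cells (default 1e4).
#'
#' @param values numeric vector of metabolic values.
#' @param n seeded cell numbers (> 0), recycled against `values`.
#' @param unit reference cell number the result is expressed per.
#' @return Scaled values; entries with missing/non-positive `n` become `NA`
#'   with a warning.
#' @examples
#' scale_by_cellnumber(90, 30000)  # 30 per 1e4 cells
#' @export
scale_by_cellnumber <- function(values, n, unit = 1e4) {
  bad <- !is.finite(n) | n <= 0
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: missing or non-positive cell number",
            call. = FALSE)
    n[bad] <- NA_real_
  }
  values * unit / n
}

#' Scale values by projected spheroid area
#'
#' `value * unit_area / area`, reported per `unit_area` square micrometers
#' (default 1e5).
#'
#' @param values numeric vector of metabolic values.
#' @param area projected areas in um^2 (> 0).
#' @param unit_area reference area the result is expressed per.
#' @return Scaled values; missing/non-positive areas become `NA` with a
#'   warning.
#' @examples
#' scale_by_area(140, 2e5)  # 70 per 1e5 um^2
#' @export
scale_by_area <- function(values, area, unit_area = 1e5) {
  bad <- !is.finite(area) | area <= 0
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: missing or non-positive area",
            call. = FALSE)
    area[bad] <- NA_real_
  }
  values * unit_area / area
}

#' Normalize 2D reference data to the measured cell count
#'
#' `value / count * unit`, the standard monolayer normalization against a
#' Hoechst-derived cell count.
#'
#' @param values numeric vector (e.g. OCR).
#' @param count measured cell counts (> 0).
#' @param unit reference cell number.
#' @return Scaled values; non-positive counts become `NA` with a warning.
#' @export
normalize_2d_reference <- function(values, count, unit = 1e4) {
  bad <- !is.finite(count) | count <= 0
  if (any(bad)) {
    warning(sum(bad), " value(s) dropped: non-positive measured count",
            call. = FALSE)
    count[bad] <- NA_real_
  }
  values / count * unit
}
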