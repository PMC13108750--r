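# File formats and run configuration: trace tables (delimited text), image
# stacks (TIFF), result reports with a run manifest, and a validated YAML run
# configuration.

#' Read an OCR trace table
#'
#' Reads a delimited text export (comma or tab separated, header row, "."
#' decimal) into the canonical trace schema. Required columns: `well_id`,
#' `cycle`, `time_min`, `ocr`; optional: `ecar` and any grouping columns.
#' Vendor-style headers are mapped via `aliases`.
#'
#' @param path file path.
#' @param aliases named character vector mapping file headers to canonical
#'   names, e.g. `c("OCR (pmol/min)" = "ocr")`.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @return Data frame with typed columns; malformed numeric cells raise an
#'   error naming the file line.
#' @export
read_trace_table <- function(path, aliases = NULL, sep = NULL) {
  if (!file.exists(path)) stop_sf("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  d <- read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE,
                colClasses = "character")
  if (!is.null(aliases)) {
    hit <- names(d) %in% names(aliases)
    names(d)[hit] <- aliases[names(d)[hit]]
  }
  required <- c("well_id", "cycle", "time_min", "ocr")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop_sf("missing required column(s): ", paste(missing, collapse = ", "),
            "; columns found: ", paste(names(d), collapse = ", "))
  numeric_cols <- intersect(c("cycle", "time_min", "ocr", "ecar"), names(d))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !(d[[col]] %in% c("", "NA")))
    if (length(bad))
      stop_sf("non-numeric value in column `", col, "` at file line ",
              bad[1] + 1L, ": \"", d[[col]][bad[1]], "\"")
    d[[col]] <- v
  }
  d
}

#' Read a grayscale TIFF image stack
#'
#' Reads a single- or multi-page 8/16-bit grayscale TIFF into a list of
#' [image_frame()]s. The pixel size is never assumed: it must be supplied.
#'
#' @param path TIFF path.
#' @param pixel_size micrometers per pixel (required).
#' @param timestamps per-frame acquisition times in hours, or `NULL` to use
#'   uniform spacing `frame_interval_h`.
#' @param frame_interval_h uniform frame spacing in hours (default 0.5, the
#'   standard 30-minute capture interval).
#' @return List of [image_frame()]s.
#' @export
read_image_stack <- function(path, pixel_size = NULL, timestamps = NULL,
                             frame_interval_h = 0.5) {
  if (!file.exists(path)) stop_sf("file not found: ", path)
  if (is.null(pixel_size))
    stop_sf("`pixel_size` must be given; it is never assumed to be 1 um/px")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (any(vapply(pages, function(p) length(dim(p)) > 2L, logical(1))))
    stop_sf("RGB/multi-channel TIFF; convert to grayscale first")
  if (is.null(timestamps))
    timestamps <- frame_interval_h * (seq_along(pages) - 1L)
  if (length(timestamps) != length(pages))
    stop_sf(length(pages), " pages but ", length(timestamps), " timestamps")
  Map(function(p, t) image_frame(p, pixel_size = pixel_size, timestamp = t),
      pages, timestamps)
}

#' Write frames as a multi-page TIFF
#'
#' Intensities are linearly rescaled to `[0, 1]` over the whole stack before
#' writing (TIFF stores bounded values).
#'
#' @param frames list of [image_frame()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path) {
  mats <- lapply(frames, function(f) as_frame(f)$pixels)
  rng <- range(unlist(lapply(mats, range)))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  mats <- lapply(mats, function(m) (m - rng[1]) / scale)
  tiff::writeTIFF(mats, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write result tables and a run manifest
#'
#' Writes each table as a comma-separated file (header row, "." decimal) plus
#' a `manifest.txt` echoing the configuration, seed and package version.
#' Re-running with identical tables produces byte-identical CSV files (the
#' manifest carries the wall-clock timestamp).
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if absent).
#' @param config optional configuration list echoed into the manifest.
#' @param seed optional seed recorded in the manifest.
#' @param overwrite allow overwriting existing table files.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, dir, config = NULL, seed = NULL,
                         overwrite = FALSE) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(names(tables), ".csv"))
  clash <- files[file.exists(files)]
  if (length(clash) && !overwrite)
    stop_sf("output exists (use overwrite = TRUE): ",
            paste(basename(clash), collapse = ", "))
  for (i in seq_along(tables)) {
    if (nrow(tables[[i]]) == 0L)
      warning("table `", names(tables)[i], "` is empty; writing header only",
              call. = FALSE)
    write.csv(tables[[i]], files[i], row.names = FALSE)
  }
  manifest <- file.path(dir, "manifest.txt")
  lines <- c(paste0("spheroflux version: ",
                    as.character(utils::packageVersion("spheroflux"))),
             paste0("written: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
             paste0("seed: ", if (is.null(seed)) "not set" else seed),
             paste0("tables: ", paste(names(tables), collapse = ", ")))
  if (!is.null(config))
    lines <- c(lines, "config:", strsplit(yaml::as.yaml(config), "\n")[[1]])
  writeLines(lines, manifest)
  invisible(c(files, manifest))
}

CONFIG_KEYS <- c("paths", "generator", "segmentation", "protocol",
                 "summary_rules", "normalization", "seed")

#' Read and validate a run configuration
#'
#' A single YAML file drives all pipeline parameters. Known top-level keys:
#' `paths`, `generator`, `segmentation`, `protocol`, `summary_rules`,
#' `normalization`, `seed`. Unknown keys are rejected rather than silently
#' ignored.
#'
#' @param path YAML file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_sf("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), CONFIG_KEYS)
  if (length(unknown))
    stop_sf("unknown config key(s): ", paste(unknown, collapse = ", "),
            "; allowed: ", paste(CONFIG_KEYS, collapse = ", "))
  if (!is.null(cfg$protocol) && (length(cfg$protocol) != 4L || any(cfg$protocol < 1)))
    stop_sf("config `protocol` must list 4 per-phase cycle counts >= 1")
  if (!is.null(cfg$seed)) check_number(cfg$seed, "seed")
  cfg
}
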