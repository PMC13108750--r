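# Synthetic OCR-trace and experiment-set generators emulating a Mito Stress
# Test on a 96-well extracellular flux analyzer.

# Per-line phase plateaus (pmol O2/min) at the reference seeding of 25,000
# cells. Values are in the realistic instrument range and encode the
# qualitative phenotypes of the four glioblastoma lines the assay targets:
# LN229 high basal / low spare capacity, U138 quiescent with near-floor basal.
line_phase_levels <- function(cell_line) {
  switch(cell_line,
    LN229  = c(baseline = 140, oligomycin = 50, fccp = 200, rotaa = 15),
    U138   = c(baseline = 50,  oligomycin = 20, fccp = 150, rotaa = 10),
    GBM4   = c(baseline = 70,  oligomycin = 25, fccp = 160, rotaa = 10),
    GBM10  = c(baseline = 110, oligomycin = 40, fccp = 190, rotaa = 12),
    c(baseline = 100, oligomycin = 40, fccp = 150, rotaa = 10)
  )
}

#' Define ground-truth Mito Stress phase plateaus
#'
#' @param ocr_baseline,ocr_oligo,ocr_fccp,ocr_rotaa phase OCR levels in
#'   pmol O2/min (all >= 0).
#' @param noise_sd relative (multiplicative) per-cycle noise SD (>= 0).
#' @param allow_pathological if `FALSE` (default), the fully-functional-system
#'   ordering `rotaa <= oligo <= baseline <= fccp` is enforced; set `TRUE` to
#'   simulate pathological wells that violate it.
#' @return A list of class `mito_stress_truth`.
#' @export
mito_stress_truth <- function(ocr_baseline, ocr_oligo, ocr_fccp, ocr_rotaa,
                              noise_sd = 0, allow_pathological = FALSE) {
  lv <- c(ocr_baseline, ocr_oligo, ocr_fccp, ocr_rotaa)
  if (any(!is.finite(lv)) || any(lv < 0))
    stop_sf("phase OCR levels must be finite and >= 0")
  check_number(noise_sd, "noise_sd", lower = 0)
  ordered_ok <- ocr_rotaa <= ocr_oligo && ocr_oligo <= ocr_baseline &&
    ocr_baseline <= ocr_fccp
  if (!ordered_ok && !allow_pathological)
    stop_sf("phase levels violate the ordering rotaa <= oligo <= baseline <= fccp; ",
            "use `allow_pathological = TRUE` to simulate such wells")
  structure(list(ocr_baseline = ocr_baseline, ocr_oligo = ocr_oligo,
                 ocr_fccp = ocr_fccp, ocr_rotaa = ocr_rotaa,
                 noise_sd = noise_sd),
            class = "mito_stress_truth")
}

#' Simulate one Mito Stress OCR trace
#'
#' Produces a per-cycle OCR series with four plateaus (baseline, post-oligomycin,
#' post-FCCP, post-rotenone/antimycin A) and multiplicative Gaussian cycle
#' noise: `ocr = level * (1 + eps)`, `eps ~ N(0, noise_sd)`. Phase transitions
#' are instantaneous at the injection boundaries.
#'
#' @param truth a [mito_stress_truth()].
#' @param protocol cycles per phase, `c(baseline, oligomycin, fccp, rotaa)`,
#'   all >= 1; the default `c(5, 8, 5, 8)` mirrors the assay protocol
#'   (5 baseline and 5 post-FCCP cycles, 8 after oligomycin and 8 after
#'   rotenone/antimycin A).
#' @param seed integer RNG seed.
#' @param well_id well identifier carried into the trace table.
#' @param cycle_minutes spacing between measurement cycles (minutes).
#' @return A data frame (one row per cycle) with columns `well_id`, `cycle`,
#'   `time_min`, `ocr`, `phase`.
#' @export
make_ocr_trace <- function(truth, protocol = c(5, 8, 5, 8), seed = 1,
                           well_id = "A01", cycle_minutes = 6.5) {
  stopifnot(inherits(truth, "mito_stress_truth"))
  if (length(protocol) != 4L || any(protocol < 1))
    stop_sf("`protocol` must give >= 1 cycle for each of the 4 phases")
  levels <- c(truth$ocr_baseline, truth$ocr_oligo, truth$ocr_fccp, truth$ocr_rotaa)
  phase_names <- c("baseline", "oligomycin", "fccp", "rotaa")
  n <- sum(protocol)
  phase <- rep(phase_names, times = protocol)
  level <- rep(levels, times = protocol)
  ocr <- with_seed(seed, level * (1 + rnorm(n, sd = truth$noise_sd)))
  data.frame(well_id = well_id, cycle = seq_len(n),
             time_min = cycle_minutes * (seq_len(n) - 1L),
             ocr = ocr,
             phase = factor(phase, levels = phase_names))
}

#' Simulate a multi-experiment spheroid flux data set
#'
#' Emulates the design used to evaluate normalization strategies: several cell
#' lines, each seeded at several cell numbers with `reps` replicate wells, in
#' `n_experiments` independent experiments. Per well, the true OCR level of
#' every phase is `g_e * k_line(phase) * (N / 25000)^alpha * (1 + eps)` with a
#' per-experiment-and-line multiplicative batch factor
#' `g_e ~ LogNormal(0, batch_sd)` and well noise `eps ~ N(0, noise_sd)`.
#' Projected spheroid area scales as `N^area_exponent` (near-spherical
#' geometry: volume ~ N, projected area ~ N^(2/3)); the measured cell count
#' carries relative counting error `count_error_sd`.
#'
#' @param cell_lines character vector of cell-line labels.
#' @param cell_numbers seeded cell numbers (>= 2 distinct values).
#' @param reps replicate wells per line x number x experiment (>= 3).
#' @param n_experiments number of independent experiments.
#' @param batch_sd log-scale SD of the experiment batch factor.
#' @param noise_sd relative well-to-well noise SD.
#' @param alpha scaling exponent of OCR with seeded cell number; values
#'   outside `[0, 2]` are allowed with a warning.
#' @param count_error_sd relative error of the measured cell count.
#' @param area_exponent,area_noise_sd scaling exponent and relative noise of
#'   the projected area.
#' @param seed integer RNG seed.
#' @return A data frame with one row per well: identifiers (`experiment_id`,
#'   `cell_line`, `cell_number`, `well_id`), the four phase OCR levels, all
#'   derived Mito Stress parameters (see [derive_mito_stress()]), `area_um2`
#'   and `measured_count`. Attribute `truth` stores the batch factors and
#'   generator parameters.
#' @export
make_experiment_set <- function(cell_lines = c("LN229", "U138", "GBM4", "GBM10"),
                                cell_numbers = c(20000, 25000, 30000),
                                reps = 16, n_experiments = 3,
                                batch_sd = 0.2, noise_sd = 0.1, alpha = 1,
                                count_error_sd = 0.1,
                                area_exponent = 2 / 3, area_noise_sd = 0.05,
                                seed = 1) {
  if (length(unique(cell_numbers)) < 2) stop_sf("need >= 2 distinct cell numbers")
  if (reps < 3) stop_sf("`reps` must be >= 3")
  if (alpha < 0 || alpha > 2)
    warning("`alpha` = ", alpha, " lies outside [0, 2]; proceeding, flagged",
            call. = FALSE)
  n_ref <- 25000
  area_ref <- 1.25e5  # um^2, ~400 um diameter spheroid at the reference seeding

  with_seed(seed, {
    g <- array(rlnorm(n_experiments * length(cell_lines), 0, batch_sd),
               dim = c(n_experiments, length(cell_lines)),
               dimnames = list(NULL, cell_lines))
    rows <- list()
    for (e in seq_len(n_experiments)) {
      for (cl in cell_lines) {
        base <- line_phase_levels(cl)
        for (n_cells in cell_numbers) {
          scale_n <- (n_cells / n_ref)^alpha
          for (r in seq_len(reps)) {
            eps <- rnorm(1, sd = noise_sd)
            lv <- g[e, cl] * base * scale_n * (1 + eps)
            lv <- pmax(lv, 0)
            pars <- derive_mito_stress(c(ocr_baseline = lv[["baseline"]],
                                         ocr_oligomycin = lv[["oligomycin"]],
                                         ocr_fccp = lv[["fccp"]],
                                         ocr_rotaa = lv[["rotaa"]]))
            rows[[length(rows) + 1L]] <- data.frame(
              experiment_id = sprintf("E%d", e), cell_line = cl,
              cell_number = n_cells,
              well_id = sprintf("E%d_%s_%d_%02d", e, cl, n_cells, r),
              as.data.frame(unclass(pars)[setdiff(names(pars), "qc_flags")]),
              qc_flagged = length(pars$qc_flags) > 0,
              area_um2 = area_ref * (n_cells / n_ref)^area_exponent *
                (1 + rnorm(1, sd = area_noise_sd)),
              measured_count = n_cells * (1 + rnorm(1, sd = count_error_sd)))
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(batch_factors = g, alpha = alpha,
                               batch_sd = batch_sd, noise_sd = noise_sd,
                               n_ref = n_ref, area_exponent = area_exponent)
    out
  })
}

#' Simulate a 2D monolayer reference plate
#'
#' Emulates the 2D reference used to benchmark normalization: per-well OCR is
#' linear in the true cell count with multiplicative noise, and the
#' Hoechst-derived measured count carries relative error `count_error_sd`.
#'
#' @param n_wells number of wells.
#' @param count_range `c(min, max)` of true per-well cell counts.
#' @param count_error_sd relative error SD of the measured count.
#' @param noise_sd relative OCR noise SD.
#' @param ocr_per_cell OCR per cell (pmol O2/min).
#' @param seed integer RNG seed.
#' @return Data frame with columns `well_id`, `true_count`, `measured_count`,
#'   `ocr`.
#' @export
make_2d_reference <- function(n_wells = 96, count_range = c(15000, 35000),
                              count_error_sd = 0.1, noise_sd = 0.1,
                              ocr_per_cell = 0.004, seed = 1) {
  if (n_wells < 1) stop_sf("`n_wells` must be >= 1")
  if (length(count_range) != 2L || any(count_range <= 0) ||
      count_range[2] < count_range[1])
    stop_sf("`count_range` must be a positive increasing pair")
  check_number(count_error_sd, "count_error_sd", lower = 0)
  with_seed(seed, {
    true_count <- runif(n_wells, count_range[1], count_range[2])
    data.frame(
      well_id = sprintf("W%03d", seq_len(n_wells)),
      true_count = true_count,
      measured_count = true_count * (1 + rnorm(n_wells, sd = count_error_sd)),
      ocr = ocr_per_cell * true_count * (1 + rnorm(n_wells, sd = noise_sd)))
  })
}
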