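# Feature assembly for metabolic phenotyping: the nine Mito Stress read-outs
# per spheroid, their t-SNE embedding, and the baseline/post-FCCP energy map.

MITO_FEATURES <- c("spare", "maximal", "atp_linked", "basal", "proton_leak",
                   "ocr_fccp", "ocr_baseline", "ocr_oligomycin", "ocr_rotaa")

#' Assemble the per-spheroid metabolic feature matrix
#'
#' One row per spheroid, exactly the nine Mito Stress read-outs used for
#' clustering, in fixed order: spare capacity, maximal respiration, ATP-linked
#' respiration, basal respiration, proton leak, OCR FCCP, OCR baseline, OCR
#' oligomycin, OCR rotenone/antimycin A. Rows with missing or non-finite
#' features are dropped with a warning naming the wells; QC-flagged rows with
#' finite values are retained.
#'
#' @param params per-well parameter table ([mito_stress()] or
#'   [make_experiment_set()] output).
#' @param standardize center and scale each column; the choice is recorded in
#'   attribute `standardized`.
#' @return Numeric matrix with `well_id` rownames and attribute
#'   `standardized`.
#' @export
build_feature_matrix <- function(params, standardize = FALSE) {
  stopifnot(is.data.frame(params), nrow(params) > 0)
  missing_cols <- setdiff(MITO_FEATURES, names(params))
  if (length(missing_cols))
    stop_sf("parameter table lacks feature column(s): ",
            paste(missing_cols, collapse = ", "))
  m <- as.matrix(params[, MITO_FEATURES])
  ok <- apply(is.finite(m), 1L, all)
  if (!all(ok)) {
    ids <- if ("well_id" %in% names(params)) params$well_id[!ok] else which(!ok)
    warning("dropping ", sum(!ok), " row(s) with non-finite features: ",
            paste(head(ids, 5), collapse = ", "),
            if (sum(!ok) > 5) ", ..." else "", call. = FALSE)
    m <- m[ok, , drop = FALSE]
    params <- params[ok, , drop = FALSE]
  }
  if (nrow(m) == 0L) stop_sf("no complete rows left")
  rownames(m) <- if ("well_id" %in% names(params)) params$well_id else NULL
  if (standardize) m <- scale(m)
  attr(m, "standardized") <- standardize
  m
}

#' Embed the metabolic feature matrix in 2D with t-SNE
#'
#' Thin, seeded wrapper around \pkg{Rtsne}. Deterministic for a fixed seed.
#'
#' @param mat feature matrix (see [build_feature_matrix()]).
#' @param perplexity t-SNE perplexity; requires `nrow(mat) >= 3 * perplexity`.
#' @param seed integer RNG seed.
#' @param ... passed on to [Rtsne::Rtsne()].
#' @return Data frame with columns `tsne1`, `tsne2` and `well_id` rownames.
#' @export
embed_features <- function(mat, perplexity = 30, seed = 1, ...) {
  stopifnot(is.matrix(mat))
  if (nrow(mat) < 3 * perplexity)
    stop_sf(nrow(mat), " rows is too few for perplexity ", perplexity,
            "; need >= 3 * perplexity rows - use a smaller perplexity")
  fit <- with_seed(seed,
    Rtsne::Rtsne(mat, perplexity = perplexity, check_duplicates = FALSE,
                 pca = FALSE, ...))
  out <- data.frame(tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  rownames(out) <- rownames(mat)
  out
}

#' Baseline and post-FCCP energy-state table
#'
#' Per group (typically cell line), the mean and standard error of the per-well
#' OCR at baseline and after FCCP injection — the two corners of the energy
#' map. ECAR columns, when present in the traces, are summarized the same way
#' but are a trend indicator of glycolytic engagement only: uncorrected
#' extracellular acidification cannot quantify glycolytic ATP production.
#'
#' @param traces phase-labeled multi-well trace table (see [assign_phases()]);
#'   optional `ecar` column.
#' @param grouping named character/factor vector mapping `well_id` to group,
#'   or a data frame with columns `well_id` and `group`.
#' @param rule per-phase summary statistic for the per-well value
#'   (default `"mean"` of the phase's cycles).
#' @return Data frame with two rows per group (`state` = `"baseline"`,
#'   `"fccp"`): `group`, `state`, `ocr_mean`, `ocr_sem`, `n`, and `ecar_mean`,
#'   `ecar_sem` when ECAR is present (attribute `ecar_note` marks them as
#'   trend-only). Groups with fewer than 2 wells get `NA` SEM.
#' @export
energy_state_table <- function(traces, grouping, rule = "mean") {
  if (!"phase" %in% names(traces)) stop_sf("traces need phases; run assign_phases()")
  if (is.data.frame(grouping)) {
    stopifnot(all(c("well_id", "group") %in% names(grouping)))
    grouping <- setNames(as.character(grouping$group), grouping$well_id)
  }
  has_ecar <- "ecar" %in% names(traces)
  per_well <- do.call(rbind, lapply(split(traces, traces$well_id), function(d) {
    data.frame(well_id = d$well_id[1],
               ocr_baseline = summary_rule(d$ocr[d$phase == "baseline"], rule),
               ocr_fccp = summary_rule(d$ocr[d$phase == "fccp"], rule),
               ecar_baseline = if (has_ecar)
                 summary_rule(d$ecar[d$phase == "baseline"], rule) else NA_real_,
               ecar_fccp = if (has_ecar)
                 summary_rule(d$ecar[d$phase == "fccp"], rule) else NA_real_)
  }))
  per_well$group <- grouping[per_well$well_id]
  if (anyNA(per_well$group)) stop_sf("grouping is missing some well_ids")
  sem <- function(x) if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_
  rows <- list()
  for (g in unique(per_well$group)) {
    d <- per_well[per_well$group == g, ]
    for (state in c("baseline", "fccp")) {
      ocr <- d[[paste0("ocr_", state)]]
      row <- data.frame(group = g, state = state, ocr_mean = mean(ocr),
                        ocr_sem = sem(ocr), n = nrow(d))
      if (has_ecar) {
        ec <- d[[paste0("ecar_", state)]]
        row$ecar_mean <- mean(ec); row$ecar_sem <- sem(ec)
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (has_ecar)
    attr(out, "ecar_note") <-
      "ECAR columns indicate glycolytic trend only; not quantitative ATP flux"
  out
}
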