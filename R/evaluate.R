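# Evaluation of normalization strategies: Pearson correlation with the seeded
# cell number, relative standard deviation, the four-strategy comparison, and
# thin convenience wrappers for standard group tests.

#' Pearson correlation with seeded cell number, per group
#'
#' Standard Pearson r of value against seeded cell number within each group
#' (cell line), pooling all experiments and cell numbers. Zero variance in
#' either variable makes r undefined — reported as `NA` with
#' `r_defined = FALSE`, deliberately distinct from 0 (a constant is not
#' "perfectly de-correlated").
#'
#' @param values numeric vector of (possibly normalized) metabolic values.
#' @param n seeded cell number (or, for 2D data, measured count) per value.
#' @param groups group label per value (e.g. cell line).
#' @return Data frame: `group`, `r`, `r_defined`, `n` (wells used; rows with
#'   `NA` values are excluded pairwise).
#' @export
evaluate_correlation <- function(values, n, groups) {
  stopifnot(length(values) == length(n), length(values) == length(groups))
  rows <- lapply(unique(groups), function(g) {
    i <- which(groups == g & is.finite(values) & is.finite(n))
    if (length(i) < 3 || length(unique(n[i])) < 2)
      stop_sf("group ", g, ": need >= 3 wells and >= 2 distinct cell numbers")
    # variance at rounding-noise level counts as zero
    defined <- sd(values[i]) > 1e-12 * max(abs(mean(values[i])), 1e-300) &&
      sd(n[i]) > 0
    data.frame(group = g,
               r = if (defined) cor(values[i], n[i]) else NA_real_,
               r_defined = defined, n = length(i))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative standard deviation per group
#'
#' Sample standard deviation (n - 1 denominator) divided by the arithmetic
#' mean, per group, pooling all cell numbers and experiments — the criterion
#' used to rank normalization strategies.
#'
#' @param values numeric vector.
#' @param groups group label per value.
#' @return Data frame: `group`, `rel_sd` (`NA` when the group mean is 0), `n`.
#' @examples
#' evaluate_relative_variance(c(8, 12), c("a", "a"))  # 0.2828
#' @export
evaluate_relative_variance <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  rows <- lapply(unique(groups), function(g) {
    x <- values[groups == g & is.finite(values)]
    if (length(x) < 2) stop_sf("group ", g, ": need >= 2 values")
    m <- mean(x)
    data.frame(group = g,
               rel_sd = if (m != 0) sd(x) / m else NA_real_,
               n = length(x))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the four normalization strategies
#'
#' Runs `raw`, `median`, `median+area` and `median+cellnumber` on the basal
#' and maximal respiration endpoints of an experiment set, and evaluates each
#' by per-cell-line Pearson correlation with the seeded cell number and
#' relative standard deviation. Strategies: raw values; experiment-median
#' normalization ([median_normalize()]); median then projected-area scaling
#' ([scale_by_area()]); median then seeded-cell-number scaling
#' ([scale_by_cellnumber()]).
#'
#' @param set well table as produced by [make_experiment_set()] (or real data
#'   with the same columns: `experiment_id`, `cell_line`, `cell_number`,
#'   `basal`, `maximal`, `area_um2`).
#' @param endpoints endpoint columns to evaluate.
#' @param unit_cells,unit_area reporting units for the scaling strategies.
#' @param floor optional detection floor: wells whose endpoint value (raw
#'   scale) falls below it are counted per cell line in the report's
#'   `n_below_floor` column — flagged, not excluded (near-floor values are
#'   more error-prone).
#' @return A `normalization_report`: long data frame with columns `strategy`,
#'   `endpoint`, `cell_line`, `r`, `r_defined`, `rel_sd`, `n`
#'   (+ `n_below_floor` when `floor` is given). Attribute `ranking` orders
#'   strategies per endpoint by mean relative SD across cell lines; attribute
#'   `factors` carries the median factors for audit.
#' @export
compare_normalizations <- function(set, endpoints = c("basal", "maximal"),
                                   unit_cells = 1e4, unit_area = 1e5,
                                   floor = NULL) {
  stopifnot(all(endpoints %in% names(set)),
            all(c("cell_number", "cell_line", "area_um2") %in% names(set)))
  med <- median_normalize(set)
  strategies <- list(
    raw = function(ep) set[[ep]],
    median = function(ep) med$data[[ep]],
    `median+area` = function(ep)
      scale_by_area(med$data[[ep]], set$area_um2, unit_area),
    `median+cellnumber` = function(ep)
      scale_by_cellnumber(med$data[[ep]], set$cell_number, unit_cells))
  rows <- list()
  for (ep in endpoints) {
    for (snm in names(strategies)) {
      v <- strategies[[snm]](ep)
      rc <- evaluate_correlation(v, set$cell_number, set$cell_line)
      rv <- evaluate_relative_variance(v, set$cell_line)
      stopifnot(identical(rc$group, rv$group))
      row <- data.frame(strategy = snm, endpoint = ep, cell_line = rc$group,
                        r = rc$r, r_defined = rc$r_defined, rel_sd = rv$rel_sd,
                        n = rv$n)
      if (!is.null(floor)) {
        row$n_below_floor <- vapply(rc$group, function(g)
          sum(set[[ep]][set$cell_line == g] < floor), numeric(1))
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ranking <- do.call(rbind, lapply(endpoints, function(ep) {
    d <- out[out$endpoint == ep, ]
    msd <- tapply(d$rel_sd, d$strategy, mean)
    data.frame(endpoint = ep, strategy = names(sort(msd)),
               mean_rel_sd = as.numeric(sort(msd)),
               rank = seq_along(msd))
  }))
  rownames(ranking) <- NULL
  attr(out, "ranking") <- ranking
  attr(out, "factors") <- med$factors
  class(out) <- c("normalization_report", "data.frame")
  out
}

#' @export
print.normalization_report <- function(x, digits = 3, ...) {
  cat("<normalization_report>\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  cat("\nstrategy ranking by mean relative SD (lower is better):\n")
  print.data.frame(attr(x, "ranking"), digits = digits, row.names = FALSE)
  invisible(x)
}

#' Standard group-difference tests
#'
#' Thin convenience wrapper around base R: one-way ANOVA with
#' Bonferroni-adjusted pairwise t-tests, plus a plain two-sided t-test when
#' exactly two groups are supplied. Significance is flagged at p < 0.05.
#'
#' @param values numeric vector.
#' @param groups group label per value (>= 2 groups, each with >= 2 values).
#' @return A list: `anova_f`, `anova_p`, `pairwise` (data frame with
#'   Bonferroni-adjusted p and a `significant` flag), and `t_p` for the
#'   two-group case.
#' @export
group_difference_tests <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_sf("need >= 2 groups")
  if (any(table(groups) < 2)) stop_sf("every group needs >= 2 values")
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1]]
  pw <- pairwise.t.test(values, groups, p.adjust.method = "bonferroni")$p.value
  pairs <- which(!is.na(pw), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pw)[pairs[, 1]], group2 = colnames(pw)[pairs[, 2]],
    p_bonferroni = pw[pairs])
  pairwise$significant <- pairwise$p_bonferroni < 0.05
  out <- list(anova_f = s[["F value"]][1], anova_p = s[["Pr(>F)"]][1],
              pairwise = pairwise)
  if (nlevels(groups) == 2) {
    out$t_p <- t.test(values ~ groups)$p.value
    out$t_significant <- out$t_p < 0.05
  }
  out
}
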