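#' Aggregate per-cell statistics into per-condition summaries
#'
#' Takes one row per cell (with a `condition` column plus numeric metric
#' columns such as `self_clustering`, `eom_20`, `eom_200`,
#' `segregation_20`, `segregation_200`) and reports, per condition and
#' metric, the across-cell mean, SEM, and a two-sided test against the
#' reference condition (the off-target cell line in a targeting
#' experiment). Statistics are computed per cell and only then aggregated,
#' never pooled across cells first. Significance stars follow the usual
#' convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#'
#' @param cells A data.frame with a `condition` column and numeric metric
#'   columns.
#' @param reference Condition id to test every condition against.
#' @param metrics Metric columns to summarize; default all numeric
#'   columns.
#' @param test `"wilcoxon"` (Mann-Whitney U, default) or `"welch"`.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()] across the non-reference comparisons of each
#'   metric; `"none"` by default (per-comparison stars), `"BH"` available.
#' @return A `condition_summary` data.frame with columns `condition`,
#'   `metric`, `n`, `mean`, `sem`, `p_value`, `stars`. Conditions with a
#'   single cell carry `NA` SEM. The reference's own p-value is `NA`.
#' @export
aggregate_condition <- function(cells, reference, metrics = NULL,
                                test = c("wilcoxon", "welch"),
                                p_adjust = "none") {
  test <- match.arg(test)
  cells <- as.data.frame(cells)
  if (!"condition" %in% names(cells))
    stop("cells must have a 'condition' column")
  conditions <- unique(as.character(cells$condition))
  if (!reference %in% conditions)
    stop("unknown reference condition '", reference, "'")
  if (is.null(metrics))
    metrics <- names(cells)[vapply(cells, is.numeric, logical(1))]
  rows <- list()
  for (m in metrics) {
    ref_vals <- cells[[m]][cells$condition == reference]
    ref_vals <- ref_vals[is.finite(ref_vals)]
    p_raw <- stats::setNames(rep(NA_real_, length(conditions)), conditions)
    for (cond in conditions) {
      v <- cells[[m]][cells$condition == cond]
      v <- v[is.finite(v)]
      if (cond != reference && length(v) >= 1 && length(ref_vals) >= 1) {
        p_raw[cond] <- switch(test,
          wilcoxon = stats::wilcox.test(v, ref_vals, exact = FALSE)$p.value,
          welch = tryCatch(stats::t.test(v, ref_vals)$p.value,
                           error = function(e) NA_real_))
      }
    }
    nonref <- setdiff(conditions, reference)
    p_raw[nonref] <- stats::p.adjust(p_raw[nonref], method = p_adjust)
    for (cond in conditions) {
      v <- cells[[m]][cells$condition == cond]
      v <- v[is.finite(v)] # masked per-cell statistics drop out
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, metric = m, n = length(v),
        mean = if (length(v) >= 1) mean(v) else NA_real_,
        sem = if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else NA_real_,
        p_value = p_raw[[cond]],
        stars = p_stars(p_raw[[cond]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("condition_summary", "data.frame"),
            reference = reference, test = test, p_adjust = p_adjust)
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "NS"
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("Per-condition summary (reference '%s', %s test)\n",
              attr(x, "reference"), attr(x, "test")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Excess killing relative to a reference cell line
#'
#' Excess killing is the killing extent of each cell line minus the killing
#' of the reference (off-target) line, so the reference maps to 0 and
#' on-target lines to their specific killing above background.
#'
#' @param killing Named numeric vector of killing extents (names are cell
#'   lines).
#' @param reference Name of the reference line.
#' @return A named numeric vector of the same length.
#' @export
excess_killing <- function(killing, reference) {
  if (is.null(names(killing)) || !reference %in% names(killing))
    stop("reference '", reference, "' not found in killing values")
  killing - killing[[reference]]
}

#' Normalize cell-line parameters and compute their correlation matrix
#'
#' Scales every parameter column by the maximal value observed for any of
#' the cell lines (so each column's maximum becomes 1), then computes the
#' pairwise Pearson correlation of the columns across cell lines. Typical
#' columns: ligand-positive fraction, segregation at 20 and 200 nm,
#' self-clustering, calcium influx, excess killing.
#'
#' @param params A data.frame or matrix, rows = cell lines (rownames or a
#'   `cell_line` column), columns = numeric parameters; at least 3 rows.
#' @return A `parameter_matrix` with elements `normalized` (the scaled
#'   table), `correlation` (symmetric Pearson matrix, unit diagonal) and
#'   `cell_lines`.
#' @export
normalize_and_correlate <- function(params) {
  params <- as.data.frame(params)
  if ("cell_line" %in% names(params)) {
    rownames(params) <- params$cell_line
    params$cell_line <- NULL
  }
  num <- vapply(params, is.numeric, logical(1))
  params <- params[, num, drop = FALSE]
  if (nrow(params) < 3)
    stop("need at least 3 cell lines for a meaningful correlation")
  maxima <- vapply(params, function(v) max(v), numeric(1))
  zero <- names(maxima)[maxima == 0 | !is.finite(maxima)]
  if (length(zero) > 0)
    stop("column '", zero[1], "' has zero (or non-finite) maximum; ",
         "cannot normalize")
  normalized <- as.data.frame(mapply(function(v, m) v / m, params, maxima,
                                     SIMPLIFY = FALSE))
  rownames(normalized) <- rownames(params)
  correlation <- stats::cor(as.matrix(normalized), method = "pearson")
  structure(list(normalized = normalized, correlation = correlation,
                 cell_lines = rownames(params)),
            class = "parameter_matrix")
}

#' @export
print.parameter_matrix <- function(x, ...) {
  cat("Normalized parameters (column maxima = 1):\n")
  print(round(x$normalized, 3))
  cat("\nPearson correlations (lower triangle):\n")
  lt <- x$correlation
  lt[upper.tri(lt)] <- NA
  print(round(lt, 2), na.print = "")
  invisible(x)
}
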