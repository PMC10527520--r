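#' Axial (z) separation between the two channels
#'
#' Tests whether the two molecular species occupy different heights at the
#' cell-cell interface, e.g. receptors riding on membrane protrusions above
#' a bulky phosphatase. Works on merged molecules (not raw localizations)
#' to avoid counting one blinking fluorophore many times. Reports the
#' per-channel mean z, their difference `delta_z = mean z1 - mean z2`, and
#' a two-sided two-sample p-value: Mann-Whitney U by default (robust to the
#' skewed z profiles typical of 3D SMLM), Welch's t-test on request.
#'
#' @param table A [loc_table()] with a `z` column and both channels
#'   present.
#' @param roi Optional [roi()]; the table is cropped to it first.
#' @param test `"wilcoxon"` (Mann-Whitney U) or `"welch"`.
#' @return An `axial_summary` with per-channel `n`, `mean_z`, `sd_z`,
#'   `delta_z` (nm) and `p_value`.
#' @export
height_separation <- function(table, roi = NULL,
                              test = c("wilcoxon", "welch")) {
  stopifnot(inherits(table, "loc_table"))
  test <- match.arg(test)
  if (!"z" %in% names(table))
    stop("no z column: this table is 2D; use the planar (x, y) pipeline")
  if (!is.null(roi)) table <- crop_roi(table, roi)
  z1 <- table$z[table$channel == 1L]
  z2 <- table$z[table$channel == 2L]
  if (length(z1) < 2 || length(z2) < 2)
    stop("height_separation needs at least 2 molecules per channel")
  p <- switch(test,
    wilcoxon = stats::wilcox.test(z1, z2, exact = FALSE)$p.value,
    welch = stats::t.test(z1, z2)$p.value)
  structure(list(n1 = length(z1), n2 = length(z2),
                 mean_z1 = mean(z1), mean_z2 = mean(z2),
                 sd_z1 = stats::sd(z1), sd_z2 = stats::sd(z2),
                 delta_z = mean(z1) - mean(z2),
                 p_value = p, test = test),
            class = "axial_summary")
}

#' @export
print.axial_summary <- function(x, ...) {
  cat(sprintf("Axial separation (%s test):\n", x$test))
  cat(sprintf("  channel 1: n = %d, mean z = %.1f nm (sd %.1f)\n",
              x$n1, x$mean_z1, x$sd_z1))
  cat(sprintf("  channel 2: n = %d, mean z = %.1f nm (sd %.1f)\n",
              x$n2, x$mean_z2, x$sd_z2))
  cat(sprintf("  delta z = %.1f nm, p = %.3g\n", x$delta_z, x$p_value))
  invisible(x)
}

#' @export
as.data.frame.axial_summary <- function(x, ...) {
  data.frame(n1 = x$n1, n2 = x$n2, mean_z1 = x$mean_z1, mean_z2 = x$mean_z2,
             delta_z = x$delta_z, p_value = x$p_value, test = x$test)
}
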