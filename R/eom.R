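#' Extent of mixing (EOM) between two channels
#'
#' Normalizes the bivariate pair-correlation function so that the two
#' reference models of channel organization pin the scale:
#'
#' \deqn{EOM(r) = \frac{g_{12}(r) - 1}{g_{pool}(r) - 1}}
#'
#' where `g12` is the cross-channel PCF and `g_pool` the PCF of the pooled
#' two-channel pattern. Under random labelling (channel identity assigned
#' at random over one fixed pattern) relabelling preserves the pooled
#' pattern and `g12 = g_pool`, so EOM = 1 — the signature of close
#' association of the two molecular species. Under independence `g12 = 1`,
#' so EOM = 0 — no interaction. Segregation is quantified as `1 - EOM`.
#' Values are not clipped: attraction beyond random labelling can exceed 1,
#' and segregation below independence can go negative.
#'
#' Bins where the pooled pattern is indistinguishable from CSR
#' (`|g_pool - 1| < denom_floor`) leave the normalization undefined and are
#' masked invalid rather than returned as unstable ratios.
#'
#' @inheritParams cross_pcf
#' @param denom_floor Mask bins with `|g_pool - 1|` below this value.
#' @return An `eom_curve`: a data.frame with columns `r`, `eom`, `valid`,
#'   plus attributes `cross` and `pooled` holding the underlying
#'   `pcf_result`s. If every bin is masked the result is returned with a
#'   warning and an empty valid set.
#' @export
eom_curve <- function(points1, points2, roi, r_edges = seq(0, 500, by = 10),
                      correction = c("toroidal", "border"),
                      denom_floor = 0.05) {
  correction <- match.arg(correction)
  p1 <- as_points(points1); p2 <- as_points(points2)
  if (nrow(p1) < 2 || nrow(p2) < 2)
    stop("eom_curve needs at least 2 points in each channel")
  cross <- cross_pcf(p1, p2, roi, r_edges, correction)
  pooled <- pcf(rbind(p1, p2), roi, r_edges, correction)
  denom <- pooled$g - 1
  valid <- is.finite(denom) & abs(denom) >= denom_floor & is.finite(cross$g)
  eom <- ifelse(valid, (cross$g - 1) / denom, NA_real_)
  if (!any(valid))
    warning("every EOM bin is masked: pooled pattern is CSR-like at all radii")
  structure(data.frame(r = cross$r, eom = eom, valid = valid),
            class = c("eom_curve", "data.frame"),
            cross = cross, pooled = pooled,
            denom_floor = denom_floor, r_edges = attr(cross, "r_edges"))
}

#' Read EOM (and segregation) at chosen radii
#'
#' Looks up the bin containing each requested radius (left-closed bins) and
#' returns the EOM value there together with its segregation companion
#' `1 - EOM`. The conventional readouts are 20 nm (close molecular overlap)
#' and 200 nm (overlap of larger membrane features such as microvilli and
#' lamellar ridges).
#'
#' @param curve An [eom_curve()].
#' @param radii Radii in nm at which to read the curve (default 20 and 200).
#' @return A data.frame with columns `radius`, `eom`, `segregation`,
#'   `valid`.
#' @export
eom_at <- function(curve, radii = c(20, 200)) {
  stopifnot(inherits(curve, "eom_curve"))
  edges <- attr(curve, "r_edges")
  idx <- findInterval(radii, edges, left.open = FALSE)
  if (any(radii < edges[1] | radii >= edges[length(edges)]))
    stop("radius outside the curve's binning (",
         edges[1], "-", edges[length(edges)], " nm)")
  data.frame(radius = radii,
             eom = curve$eom[idx],
             segregation = 1 - curve$eom[idx],
             valid = curve$valid[idx])
}

#' Monte-Carlo random-labelling reference for the EOM normalization
#'
#' Cross-check for the analytic pooled-pattern denominator of [eom_curve()]:
#' pools the two channels, relabels the pooled points at random `n_relabel`
#' times preserving the channel counts, and averages the cross-PCF over
#' relabels. Under random labelling this average estimates the same
#' quantity as the pooled-pattern PCF, so
#' `(g12 - 1) / (g_rl - 1)` is an alternative EOM estimate.
#'
#' @inheritParams eom_curve
#' @param n_relabel Number of random relabellings (default 100).
#' @return An `eom_curve` whose `pooled` attribute holds the relabelling
#'   average in place of the pooled-pattern PCF.
#' @export
eom_curve_mc <- function(points1, points2, roi,
                         r_edges = seq(0, 500, by = 10),
                         correction = c("toroidal", "border"),
                         denom_floor = 0.05, n_relabel = 100) {
  correction <- match.arg(correction)
  p1 <- as_points(points1); p2 <- as_points(points2)
  if (nrow(p1) < 2 || nrow(p2) < 2)
    stop("eom_curve_mc needs at least 2 points in each channel")
  cross <- cross_pcf(p1, p2, roi, r_edges, correction)
  pool <- rbind(p1, p2)
  n1 <- nrow(p1)
  g_rl <- rowMeans(vapply(seq_len(n_relabel), function(k) {
    lab <- sample.int(nrow(pool), n1)
    cross_pcf(pool[lab, , drop = FALSE], pool[-lab, , drop = FALSE],
              roi, r_edges, correction)$g
  }, numeric(length(r_edges) - 1)))
  denom <- g_rl - 1
  valid <- is.finite(denom) & abs(denom) >= denom_floor & is.finite(cross$g)
  eom <- ifelse(valid, (cross$g - 1) / denom, NA_real_)
  rl <- new_pcf_result(r_edges, g_rl, rep(NA_integer_, length(g_rl)),
                       correction, roi_area(roi), nrow(pool))
  structure(data.frame(r = cross$r, eom = eom, valid = valid),
            class = c("eom_curve", "data.frame"),
            cross = cross, pooled = rl,
            denom_floor = denom_floor, r_edges = r_edges)
}

#' @export
print.eom_curve <- function(x, ...) {
  cat(sprintf("Extent-of-mixing curve: %d bins, %d valid\n",
              nrow(x), sum(x$valid)))
  edges <- attr(x, "r_edges")
  probe <- c(20, 200)
  probe <- probe[probe >= edges[1] & probe < edges[length(edges)]]
  if (length(probe) > 0 && any(x$valid)) {
    at <- eom_at(x, probe)
    for (i in seq_len(nrow(at)))
      cat(sprintf("  EOM(%g nm) = %.3f (segregation %.3f)%s\n",
                  at$radius[i], at$eom[i], at$segregation[i],
                  if (!at$valid[i]) " [masked]" else ""))
  }
  invisible(x)
}

#' @export
plot.eom_curve <- function(x, ..., xlab = "r (nm)", ylab = "EOM(r)",
                           main = "Extent of mixing") {
  graphics::plot(x$r[x$valid], x$eom[x$valid], type = "l",
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::abline(h = c(0, 1), lty = 2,
                   col = c("grey40", "grey40"))
  invisible(x)
}
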