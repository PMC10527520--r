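#' Pair-correlation function of a single-channel point pattern
#'
#' Estimates the (univariate) pair-correlation function g(r): the density of
#' point pairs at separation r relative to the expectation under complete
#' spatial randomness (CSR). For each annulus `[r_lo, r_hi)` the estimate is
#' the observed ordered-pair count divided by its CSR expectation
#' `n(n-1) * annulus_area / window_area`, so CSR patterns give g = 1, and
#' clustered patterns g > 1 at short range.
#'
#' Two edge corrections are available. `"toroidal"` wraps the rectangular
#' window into a torus (exact for stationary simulated processes; requires
#' `max(r_edges)` at most half the shorter window side). `"border"` restricts
#' the reference points of each annulus to the window eroded by the outer
#' radius, so every annulus is fully observed.
#'
#' @param points A two-column matrix of (x, y) positions in nm, or a
#'   single-channel [loc_table()].
#' @param roi The observation window, an [roi()].
#' @param r_edges Increasing radial bin edges in nm (default 0 to 500 by
#'   10 nm).
#' @param correction `"toroidal"` or `"border"`.
#' @return A `pcf_result`: a data.frame with columns `r_lo`, `r_hi`, `r`
#'   (bin centre), `g` and `pair_count` (ordered pairs), and attributes
#'   `n_points`, `window_area` and `correction`.
#' @examples
#' set.seed(1)
#' w <- roi(0, 4000, 0, 4000)
#' pts <- simulate_csr(100, w)
#' g <- pcf(pts, w)
#' mean(g$g[g$r > 20 & g$r < 200]) # ~ 1 under CSR
#' @export
pcf <- function(points, roi, r_edges = seq(0, 500, by = 10),
                correction = c("toroidal", "border")) {
  correction <- match.arg(correction)
  pts <- as_points(points)
  n <- nrow(pts)
  if (n < 2) stop("pcf is undefined for fewer than 2 points")
  check_bins(r_edges, roi, correction)
  area <- roi_area(roi)
  annuli <- pi * diff(r_edges^2)
  if (correction == "toroidal") {
    d <- torus_dist(pts, pts, roi, self = TRUE)
    counts <- bin_pair_counts(d, r_edges)
    expect <- n * (n - 1) * annuli / area
    g <- counts / expect
  } else {
    counts <- integer(length(annuli))
    g <- numeric(length(annuli))
    d <- plain_dist(pts, pts, self = TRUE)
    inner <- roi_margin_dist(pts, roi)
    for (k in seq_along(annuli)) {
      ref <- inner >= r_edges[k + 1]
      n_ref <- sum(ref)
      ck <- sum(d[ref, , drop = FALSE] >= r_edges[k] &
                  d[ref, , drop = FALSE] < r_edges[k + 1])
      counts[k] <- ck
      g[k] <- if (n_ref > 0) ck / (n_ref * (n - 1) * annuli[k] / area) else NA_real_
    }
  }
  new_pcf_result(r_edges, g, counts, correction,
                 window_area = area, n_points = n)
}

#' Bivariate (cross-channel) pair-correlation function
#'
#' Cross-channel analogue of [pcf()]: the density of channel-1/channel-2
#' pairs at separation r relative to the CSR expectation
#' `n1 * n2 * annulus_area / window_area`. Independent channels give
#' g12 = 1; co-clustered channels g12 > 1 at short range; segregated
#' channels g12 < 1. The estimate is symmetric in the two channels.
#'
#' @param points1,points2 Two-column matrices of positions in nm (or
#'   single-channel [loc_table()]s), one per channel.
#' @inheritParams pcf
#' @return A `pcf_result` with attributes `n1`, `n2`.
#' @export
cross_pcf <- function(points1, points2, roi, r_edges = seq(0, 500, by = 10),
                      correction = c("toroidal", "border")) {
  correction <- match.arg(correction)
  p1 <- as_points(points1); p2 <- as_points(points2)
  if (nrow(p1) == 0) stop("channel 1 is empty")
  if (nrow(p2) == 0) stop("channel 2 is empty")
  check_bins(r_edges, roi, correction)
  area <- roi_area(roi)
  annuli <- pi * diff(r_edges^2)
  n1 <- nrow(p1); n2 <- nrow(p2)
  if (correction == "toroidal") {
    d <- torus_dist(p1, p2, roi, self = FALSE)
    counts <- bin_pair_counts(d, r_edges)
    g <- counts / (n1 * n2 * annuli / area)
  } else {
    # symmetrised border correction: pool both erosion directions so that
    # cross_pcf(A, B) == cross_pcf(B, A) exactly
    d12 <- plain_dist(p1, p2, self = FALSE)
    in1 <- roi_margin_dist(p1, roi)
    in2 <- roi_margin_dist(p2, roi)
    counts <- integer(length(annuli))
    g <- numeric(length(annuli))
    for (k in seq_along(annuli)) {
      r1 <- in1 >= r_edges[k + 1]; r2 <- in2 >= r_edges[k + 1]
      inbin <- d12 >= r_edges[k] & d12 < r_edges[k + 1]
      ck <- sum(inbin[r1, , drop = FALSE]) + sum(inbin[, r2, drop = FALSE])
      denom <- (sum(r1) * n2 + sum(r2) * n1) * annuli[k] / area
      counts[k] <- ck
      g[k] <- if (denom > 0) ck / denom else NA_real_
    }
  }
  res <- new_pcf_result(r_edges, g, counts, correction,
                        window_area = area, n_points = n1 + n2)
  attr(res, "n1") <- n1
  attr(res, "n2") <- n2
  res
}

new_pcf_result <- function(r_edges, g, counts, correction, window_area,
                           n_points) {
  out <- data.frame(r_lo = r_edges[-length(r_edges)],
                    r_hi = r_edges[-1],
                    r = (r_edges[-length(r_edges)] + r_edges[-1]) / 2,
                    g = g,
                    pair_count = as.integer(counts))
  structure(out, class = c("pcf_result", "data.frame"),
            correction = correction, window_area = window_area,
            n_points = n_points, r_edges = r_edges)
}

as_points <- function(points) {
  if (inherits(points, "loc_table")) {
    if (length(unique(points$channel)) > 1)
      stop("expected a single channel; split or pass coordinates explicitly")
    return(loc_coords(points))
  }
  pts <- as.matrix(points)
  if (length(pts) == 0) return(matrix(numeric(0), ncol = 2,
                                      dimnames = list(NULL, c("x", "y"))))
  if (ncol(pts) < 2) stop("points must have x and y columns")
  pts[, 1:2, drop = FALSE]
}

check_bins <- function(r_edges, roi, correction) {
  stopifnot(inherits(roi, "roi"))
  if (length(r_edges) < 2 || any(diff(r_edges) <= 0) || r_edges[1] < 0)
    stop("r_edges must be non-negative and strictly increasing")
  sides <- roi_sides(roi)
  if (correction == "toroidal" && max(r_edges) > min(sides) / 2)
    stop("toroidal correction requires max(r_edges) <= half the shorter ",
         "window side (", min(sides) / 2, " nm)")
  if (correction == "border" && max(r_edges) >= min(sides) / 2)
    stop("border correction requires max(r_edges) < half the shorter ",
         "window side; no reference points remain otherwise")
}

# pairwise distances with toroidal wrap on the window; self = TRUE drops
# the diagonal by setting it to Inf (so it falls outside every bin)
torus_dist <- function(p1, p2, roi, self = FALSE) {
  sides <- roi_sides(roi)
  dx <- abs(outer(p1[, 1], p2[, 1], "-"))
  dx <- pmin(dx, sides[["width"]] - dx)
  dy <- abs(outer(p1[, 2], p2[, 2], "-"))
  dy <- pmin(dy, sides[["height"]] - dy)
  d <- sqrt(dx^2 + dy^2)
  if (self) diag(d) <- Inf
  d
}

plain_dist <- function(p1, p2, self = FALSE) {
  d <- sqrt(outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2)
  if (self) diag(d) <- Inf
  d
}

# distance of each point to the nearest window edge
roi_margin_dist <- function(pts, roi) {
  pmin(pts[, 1] - roi$x_min, roi$x_max - pts[, 1],
       pts[, 2] - roi$y_min, roi$y_max - pts[, 2])
}

# ordered-pair counts per radial bin [r_lo, r_hi)
bin_pair_counts <- function(d, r_edges) {
  idx <- findInterval(d, r_edges, left.open = FALSE)
  idx <- idx[idx >= 1 & idx <= length(r_edges) - 1 & d < max(r_edges)]
  tabulate(idx, nbins = length(r_edges) - 1)
}

#' @export
print.pcf_result <- function(x, ...) {
  cat(sprintf("Pair-correlation estimate (%s correction): %d bins, %g-%g nm\n",
              attr(x, "correction"), nrow(x), min(x$r_lo), max(x$r_hi)))
  cat(sprintf("  n = %d points, window %.3g um^2, total pairs counted %d\n",
              attr(x, "n_points"), attr(x, "window_area") / 1e6,
              sum(x$pair_count)))
  invisible(x)
}

#' @export
plot.pcf_result <- function(x, ..., xlab = "r (nm)", ylab = "g(r)",
                            main = "Pair-correlation function") {
  graphics::plot(x$r, x$g, type = "l", xlab = xlab, ylab = ylab,
                 main = main, ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}
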