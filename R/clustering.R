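#' Density-based nanocluster identification (DBSCAN)
#'
#' Runs DBSCAN on a single-channel set of molecular positions to partition
#' them into monomers, dimers and larger nanoclusters. The defaults
#' (`eps = 45` nm, `minpts = 2`) follow standard practice for
#' membrane-receptor SMLM cluster analysis; with those settings every
#' in-cluster point is a core point and clusters are exactly the connected
#' components (of size >= 2) of the eps-neighbourhood graph, while isolated
#' points are monomers.
#'
#' `minpts` counts the point itself by default (a point with one true
#' neighbour within eps has neighbourhood size 2), so `minpts = 2`
#' recognises dimers as clusters. Set `count_self = FALSE` for the
#' exclusive convention. For `minpts > 2` classic DBSCAN border points are
#' assigned deterministically: clusters are grown from core points in
#' ascending index order, and a border point joins the first cluster that
#' reaches it.
#'
#' Only x and y enter the distance; z is ignored even when present, as
#' cluster analysis is performed on the 2D interface projection.
#'
#' @param points A two-column matrix of positions in nm or a single-channel
#'   [loc_table()].
#' @param eps Neighbourhood search radius in nm (> 0); neighbours satisfy
#'   `distance <= eps`.
#' @param minpts Minimum neighbourhood size of a core point (>= 1).
#' @param count_self Does the neighbourhood of a point include the point
#'   itself? Default `TRUE`.
#' @return A `cluster_result` with elements `labels` (integer per point;
#'   cluster ids `1, 2, ...`, or `0` for noise/monomers), `sizes` (integer
#'   vector of cluster cardinalities, in cluster-id order), `n_monomers`,
#'   `n_points`, and the parameters used.
#' @examples
#' pts <- rbind(c(0, 0), c(30, 0), c(500, 500))
#' dbscan_clusters(pts) # one dimer + one monomer
#' @export
dbscan_clusters <- function(points, eps = 45, minpts = 2, count_self = TRUE) {
  pts <- as_points(points)
  if (eps <= 0) stop("eps must be > 0")
  if (minpts < 1) stop("minpts must be >= 1")
  n <- nrow(pts)
  labels <- integer(n)
  if (n > 0) {
    nb <- eps_neighbours(pts, eps)
    need <- if (count_self) minpts - 1L else minpts
    core <- vapply(nb, length, integer(1)) >= need
    cluster_id <- 0L
    for (i in seq_len(n)) {
      if (labels[i] != 0L || !core[i]) next
      cluster_id <- cluster_id + 1L
      labels[i] <- cluster_id
      queue <- nb[[i]]
      while (length(queue) > 0) {
        j <- queue[1]
        queue <- queue[-1]
        if (labels[j] == 0L) {
          labels[j] <- cluster_id
          if (core[j]) queue <- c(queue, nb[[j]][labels[nb[[j]]] == 0L])
        }
      }
    }
  }
  sizes <- if (max(labels, 0L) > 0) as.integer(tabulate(labels)) else integer(0)
  structure(list(labels = labels, sizes = sizes,
                 n_monomers = sum(labels == 0L), n_points = n,
                 eps = eps, minpts = minpts, count_self = count_self),
            class = "cluster_result")
}

# list of eps-neighbour indices (excluding self) per point
eps_neighbours <- function(pts, eps) {
  n <- nrow(pts)
  if (n == 1) return(list(integer(0)))
  d <- plain_dist(pts, pts, self = TRUE)
  apply(d <= eps, 1, which, simplify = FALSE)
}

#' Cluster-size distribution and monomer/dimer/oligomer fractions
#'
#' Summarizes a [dbscan_clusters()] result as class fractions and the
#' cumulative distribution of cluster sizes. Because it is ambiguous
#' whether "fraction of dimers" counts objects (clusters) or molecules,
#' both conventions are reported.
#'
#' @param result A `cluster_result`.
#' @return A `size_distribution` with elements:
#'   \describe{
#'   \item{molecule_fractions}{fractions of molecules that sit in monomers,
#'     dimers, clusters of >= 3 (sums to 1).}
#'   \item{cluster_fractions}{fractions of objects (monomers counted as
#'     size-1 objects) that are monomers / dimers / >= 3-mers (sums to 1).}
#'   \item{cluster_only_fractions}{fractions among clusters of size >= 2
#'     (dimers / trimers / >= 4; `NA` when no clusters).}
#'   \item{cumulative}{data.frame `size`, `frac`: fraction of clusters
#'     (size >= 2) of size <= s; non-decreasing, ends at 1.}
#'   \item{degenerate}{`TRUE` when the pattern contains no cluster at all
#'     (all monomers).}
#'   }
#' @export
size_distribution <- function(result) {
  stopifnot(inherits(result, "cluster_result"))
  sizes <- result$sizes
  n_mono <- result$n_monomers
  n <- result$n_points
  n_obj <- n_mono + length(sizes)
  molecule_fractions <- c(
    monomer = if (n > 0) n_mono / n else NA_real_,
    dimer = if (n > 0) sum(sizes[sizes == 2]) / n else NA_real_,
    multimer = if (n > 0) sum(sizes[sizes >= 3]) / n else NA_real_)
  cluster_fractions <- c(
    monomer = if (n_obj > 0) n_mono / n_obj else NA_real_,
    dimer = if (n_obj > 0) sum(sizes == 2) / n_obj else NA_real_,
    multimer = if (n_obj > 0) sum(sizes >= 3) / n_obj else NA_real_)
  k <- length(sizes)
  cluster_only_fractions <- c(
    dimer = if (k > 0) sum(sizes == 2) / k else NA_real_,
    trimer = if (k > 0) sum(sizes == 3) / k else NA_real_,
    larger = if (k > 0) sum(sizes >= 4) / k else NA_real_)
  degenerate <- k == 0
  cumulative <- if (degenerate) {
    data.frame(size = integer(0), frac = numeric(0))
  } else {
    s <- sort(unique(sizes))
    data.frame(size = s,
               frac = vapply(s, function(u) mean(sizes <= u), numeric(1)))
  }
  structure(list(molecule_fractions = molecule_fractions,
                 cluster_fractions = cluster_fractions,
                 cluster_only_fractions = cluster_only_fractions,
                 cumulative = cumulative, degenerate = degenerate,
                 n_points = n, n_monomers = n_mono, sizes = sizes),
            class = "size_distribution")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "DBSCAN (eps = %g nm, minpts = %d%s): %d points -> %d clusters, %d monomers\n",
    x$eps, x$minpts, if (x$count_self) ", self-counting" else "",
    x$n_points, length(x$sizes), x$n_monomers))
  if (length(x$sizes) > 0) {
    tb <- table(x$sizes)
    cat("  cluster sizes:",
        paste(sprintf("%sx%s", tb, names(tb)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.size_distribution <- function(x, ...) {
  if (x$degenerate) {
    cat("Cluster-size distribution: degenerate (all monomers)\n")
    return(invisible(x))
  }
  mf <- x$molecule_fractions
  cf <- x$cluster_only_fractions
  cat(sprintf("Cluster-size distribution over %d molecules:\n", x$n_points))
  cat(sprintf("  molecules in monomers %.1f%%, dimers %.1f%%, >=3-mers %.1f%%\n",
              100 * mf[["monomer"]], 100 * mf[["dimer"]], 100 * mf[["multimer"]]))
  cat(sprintf("  clusters (>=2): dimers %.1f%%, trimers %.1f%%, larger %.1f%%\n",
              100 * cf[["dimer"]], 100 * cf[["trimer"]], 100 * cf[["larger"]]))
  invisible(x)
}

#' @export
plot.size_distribution <- function(x, ..., xlab = "cluster size s",
                                   ylab = "fraction of clusters <= s",
                                   main = "Cumulative cluster-size distribution") {
  if (x$degenerate) stop("no clusters to plot (all monomers)")
  graphics::plot(x$cumulative$size, x$cumulative$frac, type = "s",
                 log = "x", ylim = c(0, 1), xlab = xlab, ylab = ylab,
                 main = main, ...)
  invisible(x)
}
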