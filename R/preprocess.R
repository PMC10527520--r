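#' Crop a localization table to a region of interest
#'
#' Keeps records whose (x, y) fall inside the half-open rectangle
#' `[x_min, x_max) x [y_min, y_max)` and replaces the table's window
#' metadata by the ROI. An ROI disjoint from the data yields an empty
#' table, not an error.
#'
#' @param table A [loc_table()].
#' @param roi An [roi()] in nm.
#' @return A `loc_table` restricted to the ROI.
#' @export
crop_roi <- function(table, roi) {
  stopifnot(inherits(table, "loc_table"), inherits(roi, "roi"))
  keep <- roi_contains(roi, table$x, table$y)
  loc_rewrap(as.data.frame(table)[keep, , drop = FALSE], table, window = roi)
}

#' Merge blinking localizations into molecules
#'
#' Corrects blinking over-counting by linking localizations of one
#' fluorophore that recur close in space and time, and collapsing each
#' linked group to a single molecule record. Two localizations are linkable
#' when their separation is at most `distance_nm` and the number of frames
#' skipped between them is at most `ceiling(gap_ms/1000 * frame_rate)`;
#' molecules are the connected components of this linkage graph, so the
#' result does not depend on record order. Each molecule is placed at the
#' intensity-weighted mean of its localizations (unweighted when intensity
#' is absent) and carries the first participating frame. The defaults (20 nm,
#' 50 ms) are the standard fixed-cell dSTORM settings.
#'
#' A `distance_nm` of 0 disables linking entirely, so merging with both
#' thresholds zero is the identity.
#'
#' @param table A single-channel [loc_table()] (merge each fluorophore
#'   separately; mixed channels raise an error).
#' @param distance_nm Linking radius in nm.
#' @param gap_ms Maximal temporal gap in milliseconds; converted to skipped
#'   frames via the table's `frame_rate`.
#' @return A `loc_table` of molecules with an added `n_merged` column
#'   (number of localizations collapsed into each record). Never has more
#'   rows than the input.
#' @export
merge_localizations <- function(table, distance_nm = 20, gap_ms = 50) {
  stopifnot(inherits(table, "loc_table"))
  if (distance_nm < 0 || gap_ms < 0)
    stop("thresholds must be non-negative")
  if (length(unique(table$channel)) > 1)
    stop("merge_localizations expects a single channel; split by channel first")
  n <- nrow(table)
  if (n == 0) return(loc_rewrap(cbind(as.data.frame(table),
                                      n_merged = integer(0)), table))
  frame_rate <- attr(table, "frame_rate")
  gap_frames <- ceiling(gap_ms / 1000 * frame_rate) # allowed skipped frames
  max_df <- gap_frames + 1                          # linkable frame difference

  ord <- order(table$frame)
  df <- as.data.frame(table)[ord, , drop = FALSE]
  comp <- merge_components(df$x, df$y, df$frame, distance_nm, max_df)

  w <- if ("intensity" %in% names(df) && all(is.finite(df$intensity)) &&
           all(df$intensity > 0)) df$intensity else rep(1, n)
  agg <- function(v) vapply(split(seq_len(n), comp), function(i)
    sum(v[i] * w[i]) / sum(w[i]), numeric(1))
  out <- data.frame(
    frame = vapply(split(df$frame, comp), min, numeric(1)),
    x = agg(df$x), y = agg(df$y))
  if ("z" %in% names(df)) out$z <- agg(df$z)
  if ("intensity" %in% names(df))
    out$intensity <- vapply(split(df$intensity, comp), sum, numeric(1))
  for (field in c("sigma", "uncertainty")) {
    if (field %in% names(df))
      out[[field]] <- vapply(split(df[[field]], comp), mean, numeric(1))
  }
  out$channel <- df$channel[1]
  out$n_merged <- as.integer(table(comp))
  out <- out[order(out$frame, out$x), , drop = FALSE]
  rownames(out) <- NULL
  loc_rewrap(out, table)
}

# connected components of the spatiotemporal linkage graph; points are
# linkable when dist <= eps (eps > 0) and frame difference <= max_df.
# frames must be sorted ascending. Returns component id per point.
merge_components <- function(x, y, frame, eps, max_df) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) { # path halving
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (eps > 0 && n > 1) {
    eps2 <- eps^2
    j0 <- 1
    for (i in 2:n) {
      while (frame[i] - frame[j0] > max_df) j0 <- j0 + 1
      if (j0 < i) {
        js <- j0:(i - 1)
        hit <- js[(x[js] - x[i])^2 + (y[js] - y[i])^2 <= eps2]
        for (j in hit) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Accumulate an SMLM movie into a live-imaging sequence
#'
#' Partitions a movie's raw frames into consecutive blocks of
#' `frames_per_image` frames; each block becomes one accumulated
#' localization table carrying the frame time of its first participating
#' frame. With `alternating_channels = TRUE`, channel identity is assigned
#' from frame parity (even frames to `even_parity_channel`, odd frames to
#' the other channel), matching alternating two-color excitation. In the
#' standard live protocol 50 frames at 50 fps make each accumulated image
#' represent one second of acquisition.
#'
#' @param movie A [loc_table()] covering the whole movie.
#' @param frames_per_image Number of raw frames per accumulated image
#'   (>= 1).
#' @param alternating_channels Assign channels from frame parity?
#' @param even_parity_channel Channel for even frames when alternating.
#' @return A list of `loc_table` blocks; each has attributes `timestamp`
#'   (seconds, time of first participating frame) and `partial` (`TRUE` on
#'   a trailing block with fewer than `frames_per_image` frames). The
#'   blocks jointly contain every input record exactly once.
#' @export
accumulate_live_frames <- function(movie, frames_per_image,
                                   alternating_channels = FALSE,
                                   even_parity_channel = 1L) {
  stopifnot(inherits(movie, "loc_table"))
  if (frames_per_image < 1) stop("frames_per_image must be >= 1")
  frame_rate <- attr(movie, "frame_rate")
  df <- as.data.frame(movie)
  if (alternating_channels) {
    even <- as.integer(even_parity_channel)
    df$channel <- ifelse(df$frame %% 2 == 0, even, 3L - even)
  }
  if (nrow(df) == 0) return(list())
  n_frames <- max(df$frame) + 1
  block <- df$frame %/% frames_per_image
  n_blocks <- max(block) + 1
  lapply(seq_len(n_blocks) - 1, function(b) {
    tab <- loc_rewrap(df[block == b, , drop = FALSE], movie)
    attr(tab, "timestamp") <- b * frames_per_image / frame_rate
    attr(tab, "partial") <- (b == n_blocks - 1) &&
      (n_frames - b * frames_per_image < frames_per_image)
    tab
  })
}
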