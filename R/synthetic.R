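#' Simulate complete spatial randomness (CSR)
#'
#' Draws a homogeneous Poisson pattern: the number of points is Poisson
#' with mean `intensity x area`, positions uniform over the window.
#'
#' @param intensity Points per square micrometre.
#' @param window An [roi()] in nm.
#' @param seed Optional integer; when given the draw is reproducible.
#' @return A two-column matrix of (x, y) positions in nm.
#' @export
simulate_csr <- function(intensity, window, seed = NULL) {
  stopifnot(inherits(window, "roi"))
  if (intensity < 0) stop("intensity must be non-negative")
  if (roi_area(window) <= 0) stop("window has zero area")
  if (!is.null(seed)) set.seed(seed)
  n <- stats::rpois(1, intensity * roi_area(window) / 1e6)
  cbind(x = stats::runif(n, window$x_min, window$x_max),
        y = stats::runif(n, window$y_min, window$y_max))
}

#' Simulate a Thomas (Neyman-Scott) clustered process
#'
#' Poisson-distributed parents, each with a Poisson(`mean_offspring`)
#' number of children displaced isotropically by a Gaussian of standard
#' deviation `cluster_sigma`. This is the standard clustered stand-in for
#' receptor nanoclusters. Children falling outside the window are wrapped
#' toroidally by default (consistent with the toroidal edge correction of
#' [pcf()]); set `wrap = FALSE` to discard them instead.
#'
#' @param parent_intensity Parents per square micrometre.
#' @param mean_offspring Mean children per parent.
#' @param cluster_sigma Gaussian cluster spread in nm.
#' @param window An [roi()] in nm.
#' @param wrap Wrap out-of-window children toroidally (default) or drop
#'   them.
#' @param seed Optional integer for reproducibility.
#' @return A two-column matrix of positions in nm with attributes
#'   `parent` (integer parent id per point) and `parents` (parent
#'   positions).
#' @export
simulate_thomas <- function(parent_intensity, mean_offspring, cluster_sigma,
                            window, wrap = TRUE, seed = NULL) {
  stopifnot(inherits(window, "roi"))
  if (parent_intensity <= 0 || mean_offspring <= 0 || cluster_sigma <= 0)
    stop("parent_intensity, mean_offspring and cluster_sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  parents <- simulate_csr(parent_intensity, window)
  thomas_offspring(parents, mean_offspring, cluster_sigma, window, wrap)
}

# children for given parent positions (shared by the two-color couplings)
thomas_offspring <- function(parents, mean_offspring, cluster_sigma, window,
                             wrap = TRUE) {
  n_par <- nrow(parents)
  counts <- if (n_par > 0) stats::rpois(n_par, mean_offspring) else integer(0)
  total <- sum(counts)
  parent_id <- rep(seq_len(n_par), counts)
  pts <- cbind(
    x = rep(parents[, 1], counts) + stats::rnorm(total, 0, cluster_sigma),
    y = rep(parents[, 2], counts) + stats::rnorm(total, 0, cluster_sigma))
  if (wrap) {
    pts <- wrap_points(pts, window)
  } else {
    keep <- roi_contains(window, pts[, 1], pts[, 2])
    pts <- pts[keep, , drop = FALSE]
    parent_id <- parent_id[keep]
  }
  attr(pts, "parent") <- parent_id
  attr(pts, "parents") <- parents
  pts
}

wrap_points <- function(pts, window) {
  w <- roi_sides(window)
  pts[, 1] <- window$x_min + (pts[, 1] - window$x_min) %% w[["width"]]
  pts[, 2] <- window$y_min + (pts[, 2] - window$y_min) %% w[["height"]]
  pts
}

#' Simulate a two-color localization pattern with known coupling
#'
#' Generates ground-truth molecular positions for two channels under one of
#' the reference couplings used to interpret extent-of-mixing statistics:
#'
#' * `"independent"` — two separate draws of the same process; EOM
#'   expectation 0 (no interaction).
#' * `"random_label"` — one draw, each point assigned to channel 1 with
#'   probability `p`; EOM expectation 1 (random labelling).
#' * `"co_clustered"` — both channels share the same parents, offspring
#'   drawn independently per channel; strong mixing.
#' * `"segregated"` — shared parents, but channel-2 parents displaced by
#'   `displacement` nm in a random direction per parent; mixing decreases
#'   as the displacement grows. `displacement = 0` reduces to
#'   `"co_clustered"`.
#'
#' The underlying process is Thomas (clustered) unless
#' `process = "csr"`, in which case only `"independent"` and
#' `"random_label"` are meaningful.
#'
#' @param mode Coupling mode (see above).
#' @param window An [roi()] in nm.
#' @param process `"thomas"` or `"csr"`.
#' @param intensity CSR intensity, points per square micrometre (used when
#'   `process = "csr"`).
#' @param parent_intensity,mean_offspring,cluster_sigma Thomas parameters
#'   (parents per square micrometre; children per parent; nm). Defaults (5,
#'   10, 30) emulate receptor nanocluster fields of realistic density.
#' @param p Channel-1 probability under `"random_label"`.
#' @param displacement Channel-2 parent displacement in nm under
#'   `"segregated"`.
#' @param wrap Toroidal wrapping of out-of-window points.
#' @param seed Optional integer for reproducibility.
#' @return A list with `ch1`, `ch2` (position matrices) and `truth` (a list
#'   carrying the mode, parameters and, where applicable, parent
#'   bookkeeping and the pooled-pattern labels).
#' @export
simulate_two_color <- function(mode = c("independent", "random_label",
                                        "co_clustered", "segregated"),
                               window, process = c("thomas", "csr"),
                               intensity = 100,
                               parent_intensity = 5, mean_offspring = 10,
                               cluster_sigma = 30, p = 0.5,
                               displacement = 0, wrap = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  process <- match.arg(process)
  stopifnot(inherits(window, "roi"))
  if (mode == "random_label" && (p <= 0 || p >= 1))
    stop("p must be in (0, 1)")
  if (mode == "segregated" && displacement < 0)
    stop("displacement must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  draw <- function() {
    if (process == "csr") simulate_csr(intensity, window)
    else simulate_thomas(parent_intensity, mean_offspring, cluster_sigma,
                         window, wrap = wrap)
  }
  truth <- list(mode = mode, process = process)
  if (mode == "independent") {
    ch1 <- draw(); ch2 <- draw()
  } else if (mode == "random_label") {
    pool <- draw()
    lab1 <- stats::rbinom(nrow(pool), 1, p) == 1
    ch1 <- pool[lab1, , drop = FALSE]
    ch2 <- pool[!lab1, , drop = FALSE]
    truth$pool <- pool
    truth$label <- ifelse(lab1, 1L, 2L)
  } else { # co_clustered / segregated share parents
    if (process == "csr")
      stop("co-clustered/segregated couplings require the Thomas process")
    parents <- simulate_csr(parent_intensity, window)
    ch1 <- thomas_offspring(parents, mean_offspring, cluster_sigma, window,
                            wrap)
    parents2 <- parents
    if (mode == "segregated" && displacement > 0 && nrow(parents) > 0) {
      theta <- stats::runif(nrow(parents), 0, 2 * pi)
      parents2 <- parents + displacement * cbind(cos(theta), sin(theta))
      if (wrap) parents2 <- wrap_points(parents2, window)
    }
    ch2 <- thomas_offspring(parents2, mean_offspring, cluster_sigma, window,
                            wrap)
    truth$parents <- parents
    truth$parents2 <- parents2
    truth$displacement <- if (mode == "segregated") displacement else 0
  }
  list(ch1 = ch1, ch2 = ch2, truth = truth)
}

#' Emulate fluorophore blinking over an SMLM acquisition
#'
#' Expands ground-truth molecular positions into a localization table with
#' blinking-induced over-counting and localization error. Each molecule
#' emits a geometric number of localizations (mean `mean_emissions`,
#' support >= 1, memoryless blinking), starting at a uniformly chosen
#' frame; successive emissions are separated by `1 + Geometric(gap_mean)`
#' frames (consecutive frames when `gap_mean = 0`). Every localization is
#' jittered by an isotropic Gaussian of standard deviation
#' `localization_sigma`; the default 8.5 nm corresponds to ~20 nm
#' resolution (FWHM = 2.355 sigma), typical of dSTORM.
#'
#' With `mean_emissions = 1` and `localization_sigma = 0` the output
#' reproduces the input positions exactly (one frame each).
#'
#' @param molecules A two-column matrix of true molecular positions in nm.
#' @param mean_emissions Mean localizations per molecule (>= 1).
#' @param gap_mean Mean number of dark frames between successive emissions
#'   of one molecule.
#' @param localization_sigma Per-axis localization error in nm.
#' @param n_frames Number of acquisition frames.
#' @param frame_rate Frames per second (13.4 for typical fixed-cell
#'   dSTORM).
#' @param channel Channel id stamped on every record.
#' @param window Optional [roi()] stored as the table's window.
#' @param seed Optional integer for reproducibility.
#' @return A [loc_table()] sorted by frame, with a `molecule` column
#'   carrying the ground-truth molecule id of every localization.
#' @export
emulate_blinking <- function(molecules, mean_emissions = 4, gap_mean = 0,
                             localization_sigma = 8.5, n_frames = 1000,
                             frame_rate = 13.4, channel = 1L, window = NULL,
                             seed = NULL) {
  mols <- as_points(molecules)
  if (mean_emissions < 1) stop("mean_emissions must be >= 1")
  if (gap_mean < 0 || localization_sigma < 0) stop("negative blinking parameter")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(mols)
  # geometric with support {1, 2, ...} and mean mean_emissions
  k <- stats::rgeom(n, prob = 1 / mean_emissions) + 1L
  total <- sum(k)
  mol_id <- rep(seq_len(n), k)
  start <- rep(sample.int(n_frames, n, replace = TRUE) - 1L, k)
  gaps <- if (gap_mean > 0)
    stats::rgeom(total, prob = 1 / (1 + gap_mean)) else integer(total)
  # cumulative frame offset within each molecule's burst
  offset <- stats::ave(1L + gaps, mol_id, FUN = cumsum) - (1L + gaps)
  frame <- pmin(start + offset, n_frames - 1L)
  df <- data.frame(
    frame = frame,
    x = rep(mols[, 1], k) + stats::rnorm(total, 0, localization_sigma),
    y = rep(mols[, 2], k) + stats::rnorm(total, 0, localization_sigma),
    channel = as.integer(channel),
    molecule = mol_id)
  df <- df[order(df$frame, df$molecule), , drop = FALSE]
  rownames(df) <- NULL
  loc_table(df, frame_rate = frame_rate, window = window)
}
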