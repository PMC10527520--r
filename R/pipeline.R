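#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' analysis default filled in: 20 nm / 50 ms merging, 10 nm PCF bins to
#' 500 nm, EOM readouts at 20 and 200 nm, DBSCAN at eps = 45 nm with
#' minpts = 2. User-supplied values override by name.
#'
#' @param ... Named overrides, possibly nested lists (e.g.
#'   `merge = list(distance_nm = 25)`).
#' @return A named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    window = list(x_min = 0, x_max = 4000, y_min = 0, y_max = 4000),
    merge = list(distance_nm = 20, gap_ms = 50),
    pcf = list(r_max = 500, bin_width = 10, correction = "toroidal"),
    eom_radii = c(20, 200),
    dbscan = list(eps = 45, minpts = 2),
    blinking = list(mean_emissions = 4, gap_mean = 0,
                    localization_sigma = 8.5, n_frames = 2000,
                    frame_rate = 13.4),
    z_model = NULL,
    conditions = list(),
    reference = NULL,
    scalars = NULL)
  over <- list(...)
  for (nm in names(over)) {
    named_list <- function(v) is.list(v) && !is.data.frame(v) &&
      length(v) > 0 && !is.null(names(v)) && all(names(v) != "")
    cfg[[nm]] <- if (named_list(cfg[[nm]]) && named_list(over[[nm]]))
      modifyList(cfg[[nm]], over[[nm]])
    else over[[nm]]
  }
  cfg
}

#' Run the full two-color SMLM analysis pipeline
#'
#' Executes simulate (or read) -> merge -> per-cell spatial statistics ->
#' cohort aggregation and writes every result table plus a JSON manifest
#' to `out_dir`. Each condition in `config$conditions` is a list with
#' `name`, `n_cells`, a coupling `mode` for [simulate_two_color()]
#' (optionally `displacement`, `p`) and optionally its own Thomas
#' parameters; alternatively a condition may carry `files`, a vector of
#' localization CSV paths (one per cell, both channels in one file).
#'
#' Per cell the pipeline computes: the channel-1 self-clustering g(20 nm),
#' EOM and segregation at the configured radii, DBSCAN monomer/dimer/
#' oligomer fractions for channel 1, and (when a `z_model` is configured
#' or z data present) the axial separation summary. Identical config and
#' seed give identical outputs.
#'
#' @param config A list from [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with `cells` (per-cell data.frame), `summary`
#'   (a [aggregate_condition()] result or NULL), `parameters` (a
#'   [normalize_and_correlate()] result or NULL) and `files` (paths
#'   written).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- config
  if (length(cfg$conditions) == 0)
    stop("validation error: config$conditions is empty")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  window <- do.call(roi, cfg$window)
  r_edges <- seq(0, cfg$pcf$r_max, by = cfg$pcf$bin_width)
  cells <- list()
  for (cond in cfg$conditions) {
    n_cells <- if (is.null(cond$files)) cond$n_cells else length(cond$files)
    for (i in seq_len(n_cells)) {
      cell_id <- sprintf("%s_%02d", cond$name, i)
      row <- tryCatch(
        pipeline_cell(cond, i, cfg, window, r_edges),
        error = function(e) stop("stage failure in cell ", cell_id, ": ",
                                 conditionMessage(e), call. = FALSE))
      row$condition <- cond$name
      row$cell <- cell_id
      cells[[length(cells) + 1]] <- row
    }
  }
  cells <- do.call(rbind, cells)
  files <- character(0)
  f <- file.path(out_dir, "cells.csv")
  utils::write.csv(cells, f, row.names = FALSE)
  files <- c(files, f)

  summary <- NULL
  if (!is.null(cfg$reference) && length(unique(cells$condition)) > 1) {
    summary <- aggregate_condition(cells, cfg$reference)
    f <- file.path(out_dir, "condition_summary.csv")
    utils::write.csv(as.data.frame(summary), f, row.names = FALSE)
    files <- c(files, f)
  }

  parameters <- NULL
  if (!is.null(cfg$scalars) && !is.null(cfg$reference)) {
    sc <- as.data.frame(cfg$scalars)
    spatial_cols <- c("segregation_20", "segregation_200", "self_clustering")
    # a column whose EOM bin was masked for some cell carries NAs; it
    # cannot enter the correlation matrix
    spatial_cols <- spatial_cols[vapply(spatial_cols, function(cl)
      all(is.finite(cells[[cl]])), logical(1))]
    per_cond <- stats::aggregate(
      cells[, spatial_cols, drop = FALSE],
      by = list(cell_line = cells$condition), FUN = mean)
    merged <- merge(per_cond, sc, by = "cell_line")
    if ("killing" %in% names(merged)) {
      kill <- stats::setNames(merged$killing, merged$cell_line)
      merged$excess_killing <- as.numeric(
        excess_killing(kill, cfg$reference)[merged$cell_line])
      merged$killing <- NULL
    }
    if (nrow(merged) >= 3) {
      parameters <- normalize_and_correlate(merged)
      f <- file.path(out_dir, "correlation_matrix.csv")
      utils::write.csv(parameters$correlation, f)
      f2 <- file.path(out_dir, "normalized_parameters.csv")
      utils::write.csv(parameters$normalized, f2)
      files <- c(files, f, f2)
    }
  }

  manifest <- list(
    package = "smlmpp",
    version = as.character(utils::packageVersion("smlmpp")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "scalars")],
    outputs = basename(files))
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  files <- c(files, f)
  invisible(list(cells = cells, summary = summary, parameters = parameters,
                 files = files))
}

# analyze one cell: simulate (or read), blink+merge, spatial stats
pipeline_cell <- function(cond, i, cfg, window, r_edges) {
  bl <- cfg$blinking
  if (!is.null(cond$files)) {
    tab <- read_localizations(cond$files[i], frame_rate = bl$frame_rate,
                              window = window)
    ch <- lapply(1:2, function(c) {
      sub <- tab[tab$channel == c, , drop = FALSE]
      loc_rewrap(as.data.frame(sub), tab)
    })
  } else {
    sim_args <- list(mode = cond$mode, window = window)
    for (nm in c("parent_intensity", "mean_offspring", "cluster_sigma",
                 "p", "displacement", "process", "intensity"))
      if (!is.null(cond[[nm]])) sim_args[[nm]] <- cond[[nm]]
    sim <- do.call(simulate_two_color, sim_args)
    ch <- lapply(1:2, function(c) {
      mols <- if (c == 1) sim$ch1 else sim$ch2
      emulate_blinking(mols, mean_emissions = bl$mean_emissions,
                       gap_mean = bl$gap_mean,
                       localization_sigma = bl$localization_sigma,
                       n_frames = bl$n_frames, frame_rate = bl$frame_rate,
                       channel = c, window = window)
    })
    if (!is.null(cfg$z_model)) {
      zm <- cfg$z_model
      ch <- lapply(1:2, function(c) {
        tab <- ch[[c]]
        mu <- if (c == 1) zm$mean1 else zm$mean2
        tab$z <- stats::rnorm(nrow(tab), mu, zm$sd)
        tab
      })
    }
  }
  merged <- lapply(ch, function(tab)
    merge_localizations(crop_roi(tab, window),
                        distance_nm = cfg$merge$distance_nm,
                        gap_ms = cfg$merge$gap_ms))
  p1 <- loc_coords(merged[[1]]); p2 <- loc_coords(merged[[2]])
  g1 <- pcf(p1, window, r_edges, correction = cfg$pcf$correction)
  self_cl <- g1$g[findInterval(20, attr(g1, "r_edges"))]
  eom <- eom_curve(p1, p2, window, r_edges, correction = cfg$pcf$correction)
  at <- eom_at(eom, cfg$eom_radii)
  cl <- size_distribution(dbscan_clusters(p1, eps = cfg$dbscan$eps,
                                          minpts = cfg$dbscan$minpts))
  row <- data.frame(
    n1 = nrow(p1), n2 = nrow(p2),
    self_clustering = self_cl,
    eom_20 = at$eom[1], eom_200 = at$eom[2],
    segregation_20 = at$segregation[1], segregation_200 = at$segregation[2],
    monomer_frac = cl$molecule_fractions[["monomer"]],
    dimer_frac = cl$molecule_fractions[["dimer"]],
    multimer_frac = cl$molecule_fractions[["multimer"]])
  if ("z" %in% names(merged[[1]]) && "z" %in% names(merged[[2]])) {
    both <- loc_rewrap(rbind(as.data.frame(merged[[1]]),
                             as.data.frame(merged[[2]])), merged[[1]])
    ax <- height_separation(both)
    row$delta_z <- ax$delta_z
    row$z_p_value <- ax$p_value
  }
  row
}
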