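#' Localization tables
#'
#' A `loc_table` holds one record per localization (a single fitted emission
#' event) with coordinates in nanometres. It is a plain `data.frame` with
#' mandatory columns `frame` (non-negative integer), `x`, `y` (nm) and
#' `channel` (1 or 2), optional columns `z` (nm), `intensity` (photons),
#' `sigma` (nm), `uncertainty` (nm), and metadata attributes `frame_rate`
#' (frames/s), `pixel_size` (nm, 160 by default for a typical EMCCD setup)
#' and `window` (an [roi()] describing the field the records live in).
#'
#' @param df A data.frame with at least `frame`, `x`, `y` columns; `channel`
#'   defaults to 1 when absent.
#' @param frame_rate Acquisition frame rate in frames/s (13.4 for typical
#'   fixed-cell dSTORM, 50 for the live protocol).
#' @param pixel_size Camera pixel size at the sample, nm.
#' @param window Optional [roi()]; computed from the data range when `NULL`.
#' @return A `data.frame` of class `loc_table`.
#' @export
loc_table <- function(df, frame_rate = 13.4, pixel_size = 160, window = NULL) {
  df <- as.data.frame(df)
  for (col in c("frame", "x", "y")) {
    if (!col %in% names(df))
      stop("loc_table requires column '", col, "'")
  }
  if (!"channel" %in% names(df)) df$channel <- 1L
  df$frame <- as.integer(df$frame)
  df$channel <- as.integer(df$channel)
  if (nrow(df) > 0) {
    if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
      stop("all coordinates must be finite")
    if (any(df$frame < 0)) stop("frame indices must be non-negative")
    if (!all(df$channel %in% c(1L, 2L)))
      stop("channel must be 1 or 2")
    if ("z" %in% names(df) && any(!is.finite(df$z)))
      stop("all z coordinates must be finite")
  }
  if (is.null(window)) {
    window <- if (nrow(df) > 0)
      roi(min(df$x), max(df$x) + 1e-9, min(df$y), max(df$y) + 1e-9)
    else
      roi(0, 1, 0, 1)
  }
  structure(df,
            class = c("loc_table", "data.frame"),
            frame_rate = frame_rate,
            pixel_size = pixel_size,
            window = window)
}

loc_meta <- function(x) {
  list(frame_rate = attr(x, "frame_rate"),
       pixel_size = attr(x, "pixel_size"),
       window = attr(x, "window"))
}

# rebuild a loc_table around new rows, keeping metadata (optionally a new window)
loc_rewrap <- function(df, template, window = NULL) {
  loc_table(df,
            frame_rate = attr(template, "frame_rate"),
            pixel_size = attr(template, "pixel_size"),
            window = if (is.null(window)) attr(template, "window") else window)
}

#' Extract coordinates as a two-column matrix
#'
#' @param x A `loc_table`.
#' @param channel Optional channel filter (1 or 2).
#' @return A numeric matrix with columns `x`, `y`.
#' @export
loc_coords <- function(x, channel = NULL) {
  stopifnot(inherits(x, "loc_table"))
  if (!is.null(channel)) x <- x[x$channel == channel, , drop = FALSE]
  cbind(x = x$x, y = x$y)
}

#' @export
print.loc_table <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("Localization table: %d records, channels {%s}\n",
              nrow(x), paste(sort(unique(x$channel)), collapse = ",")))
  cat(sprintf("  frame rate %g fps, pixel %g nm, window %s nm\n",
              attr(x, "frame_rate"), attr(x, "pixel_size"), format(w)))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 4))
  invisible(x)
}

#' Column-mapping dialect for localization CSV files
#'
#' Describes how a localization CSV maps onto `loc_table` fields. The default
#' is the ThunderSTORM export dialect: headers `frame`, `"x [nm]"`,
#' `"y [nm]"`, optional `"z [nm]"`, `"intensity [photon]"`, `"sigma [nm]"`,
#' `"uncertainty [nm]"`. Channel identity is taken from a column, derived
#' from frame parity (alternating-excitation acquisitions), or fixed at 1.
#'
#' @param frame,x,y,z,intensity,sigma,uncertainty,channel Column names in the
#'   file; set an optional one to `NA` if absent. `channel` is only consulted
#'   when `channel_from = "column"`.
#' @param unit Unit of the coordinate columns: `"nm"` or `"um"` (µm values
#'   are converted to nm on read).
#' @param channel_from One of `"none"` (all records channel 1), `"column"`,
#'   or `"frame_parity"` (alternating channels frame by frame).
#' @param even_parity_channel Channel assigned to even frames (0, 2, ...)
#'   under `channel_from = "frame_parity"`; the other parity gets the other
#'   channel. Default 1 (green acquired first).
#' @return A `loc_dialect` list.
#' @export
loc_dialect <- function(frame = "frame", x = "x [nm]", y = "y [nm]",
                        z = "z [nm]", intensity = "intensity [photon]",
                        sigma = "sigma [nm]", uncertainty = "uncertainty [nm]",
                        channel = "channel",
                        unit = c("nm", "um"),
                        channel_from = c("none", "column", "frame_parity"),
                        even_parity_channel = 1L) {
  structure(list(frame = frame, x = x, y = y, z = z, intensity = intensity,
                 sigma = sigma, uncertainty = uncertainty, channel = channel,
                 unit = match.arg(unit),
                 channel_from = match.arg(channel_from),
                 even_parity_channel = as.integer(even_parity_channel)),
            class = "loc_dialect")
}

#' Read a localization table from CSV
#'
#' Reads a localization CSV (ThunderSTORM dialect by default) into a
#' [loc_table()]. Mandatory columns are `frame`, `x`, `y` under the dialect's
#' names; optional columns are picked up when present. Coordinates given in
#' µm (dialect `unit = "um"`) are converted to nm.
#'
#' @param path Path to a CSV file.
#' @param dialect A [loc_dialect()].
#' @param frame_rate,pixel_size,window Metadata passed to [loc_table()].
#' @return A `loc_table`.
#' @export
read_localizations <- function(path, dialect = loc_dialect(),
                               frame_rate = 13.4, pixel_size = 160,
                               window = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("frame", "x", "y")) {
    nm <- dialect[[col]]
    if (!nm %in% names(raw))
      stop("missing mandatory column '", nm, "' in ", path)
  }
  scale <- if (dialect$unit == "um") 1000 else 1
  num <- function(field, mandatory = FALSE) {
    nm <- dialect[[field]]
    if (is.na(nm) || !nm %in% names(raw)) return(NULL)
    v <- suppressWarnings(as.numeric(raw[[nm]]))
    bad <- which(is.na(v) & !is.na(raw[[nm]]) & raw[[nm]] != "")
    if (mandatory) bad <- union(bad, which(is.na(v)))
    if (length(bad) > 0)
      stop("non-numeric value in column '", nm, "' at row ", bad[1])
    v
  }
  df <- data.frame(frame = num("frame", mandatory = TRUE),
                   x = num("x", mandatory = TRUE) * scale,
                   y = num("y", mandatory = TRUE) * scale)
  if (nrow(raw) == 0)
    df <- data.frame(frame = integer(), x = numeric(), y = numeric())
  for (field in c("z", "intensity", "sigma", "uncertainty")) {
    v <- num(field)
    if (!is.null(v)) df[[field]] <- if (field == "z") v * scale else v
  }
  df$channel <- switch(dialect$channel_from,
    none = rep(1L, nrow(df)),
    column = {
      v <- num("channel")
      if (is.null(v)) stop("missing mandatory column '", dialect$channel,
                           "' in ", path)
      as.integer(v)
    },
    frame_parity = {
      even <- dialect$even_parity_channel
      ifelse(df$frame %% 2 == 0, even, 3L - even)
    })
  loc_table(df, frame_rate = frame_rate, pixel_size = pixel_size,
            window = window)
}

#' Write a localization table to CSV
#'
#' Writes the same dialect [read_localizations()] reads (always in nm).
#'
#' @param table A `loc_table`.
#' @param path Output CSV path.
#' @param dialect A [loc_dialect()] providing the header names.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path, dialect = loc_dialect()) {
  stopifnot(inherits(table, "loc_table"))
  out <- data.frame(frame = table$frame, check.names = FALSE)
  out[[dialect$x]] <- table$x
  out[[dialect$y]] <- table$y
  for (field in c("z", "intensity", "sigma", "uncertainty")) {
    if (field %in% names(table)) out[[dialect[[field]]]] <- table[[field]]
  }
  out[[dialect$channel]] <- table$channel
  names(out)[1] <- dialect$frame
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
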