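#' Define a latitude-longitude grid
#'
#' A global grid of square latitude-longitude cells anchored at
#' (-90, -180), in the spirit of the c-squares spatial indexing scheme.
#' Cells are identified by an integer row (counted from the south) and
#' column (counted from the west), written canonically as `"r{row}c{col}"`.
#'
#' @param resolution Cell size in degrees. Must divide both 180 and 360
#'   evenly; typical values are 10, 5 and 1.
#' @return An object of class `grid_spec` with fields `resolution`,
#'   `n_rows`, `n_cols`.
#' @examples
#' g <- grid_spec(5)
#' g$n_rows  # 36
#' g$n_cols  # 72
#' @export
grid_spec <- function(resolution = 5) {
  resolution <- as.numeric(resolution)
  if (length(resolution) != 1L || !is.finite(resolution) || resolution <= 0)
    stop("`resolution` must be a single positive number", call. = FALSE)
  if (180 %% resolution != 0 || 360 %% resolution != 0)
    stop("`resolution` must divide 180 and 360 evenly", call. = FALSE)
  structure(
    list(resolution = resolution,
         n_rows = as.integer(180 / resolution),
         n_cols = as.integer(360 / resolution)),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g deg cells: %d rows x %d cols = %d cells\n",
              x$resolution, x$n_rows, x$n_cols, x$n_rows * x$n_cols))
  invisible(x)
}

cell_id <- function(row, col) sprintf("r%dc%d", as.integer(row), as.integer(col))

#' Decompose canonical cell ids into row and column indices
#'
#' @param ids Character vector of canonical ids (`"r{row}c{col}"`).
#' @return A data.frame with integer columns `row` and `col`.
#' @export
cell_rowcol <- function(ids) {
  m <- regmatches(ids, regexec("^r([0-9]+)c([0-9]+)$", ids))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop("malformed cell id(s): ", paste(head(ids[bad], 3), collapse = ", "),
         call. = FALSE)
  data.frame(row = as.integer(vapply(m, `[`, "", 2L)),
             col = as.integer(vapply(m, `[`, "", 3L)))
}

#' Assign coordinates to grid cells
#'
#' Half-open binning `[edge, edge + resolution)` on both axes. Latitude 90
#' is clamped into the top row; longitude is normalized to `[-180, 180)`
#' first, so 180 wraps to -180.
#'
#' @param lat,lon Numeric vectors of decimal degrees (equal length).
#' @param spec A [grid_spec()].
#' @return Character vector of canonical cell ids; `NA` where a coordinate
#'   is non-finite or latitude is outside `[-90, 90]`.
#' @examples
#' cell_of(0, 0, grid_spec(5))     # "r18c36"
#' cell_of(-90, -180, grid_spec(5)) # "r0c0"
#' cell_of(90, 180, grid_spec(5))   # "r35c0"
#' @export
cell_of <- function(lat, lon, spec = grid_spec()) {
  stopifnot(inherits(spec, "grid_spec"))
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) != length(lon))
    stop("`lat` and `lon` must have the same length", call. = FALSE)
  ok <- is.finite(lat) & is.finite(lon) & lat >= -90 & lat <= 90
  res <- spec$resolution
  lonn <- ((lon + 180) %% 360) - 180          # [-180, 180)
  row <- floor((lat + 90) / res)
  row <- pmin(row, spec$n_rows - 1L)          # lat = 90 -> top row
  col <- floor((lonn + 180) / res)
  out <- rep(NA_character_, length(lat))
  out[ok] <- cell_id(row[ok], col[ok])
  out
}

#' Human-readable cell labels from the lower-left corner
#'
#' @param ids Canonical cell ids.
#' @param spec A [grid_spec()].
#' @return Labels such as `"50N_10W"` (corner latitude then longitude).
#' @export
cell_label <- function(ids, spec = grid_spec()) {
  rc <- cell_rowcol(ids)
  lat0 <- rc$row * spec$resolution - 90
  lon0 <- rc$col * spec$resolution - 180
  lat_s <- ifelse(lat0 < 0, paste0(abs(lat0), "S"), paste0(lat0, "N"))
  lon_s <- ifelse(lon0 < 0, paste0(abs(lon0), "W"), paste0(lon0, "E"))
  paste0(lat_s, "_", lon_s)
}

#' Cell centre coordinates
#'
#' @inheritParams cell_label
#' @return data.frame with `cell`, `lat`, `lon` (centres).
#' @export
cell_center <- function(ids, spec = grid_spec()) {
  rc <- cell_rowcol(ids)
  data.frame(cell = ids,
             lat = rc$row * spec$resolution - 90 + spec$resolution / 2,
             lon = rc$col * spec$resolution - 180 + spec$resolution / 2,
             stringsAsFactors = FALSE)
}

#' Preset of anomalous cells excluded from the global analysis
#'
#' A small set of cells whose aggregated records are dominated by imprecise
#' georeferencing in the source database: the cell at latitude-longitude
#' (0, 0) in the Gulf of Guinea, one Alboran Sea cell at the 0-degree
#' meridian, and two Gulf of California cells. Intended for real OBIS-style
#' extracts; synthetic data needs no exclusions.
#'
#' @param spec A [grid_spec()].
#' @return Character vector of cell ids.
#' @export
default_cell_exclusions <- function(spec = grid_spec(5)) {
  pts <- rbind(c(0, 0),            # Gulf of Guinea: records georeferenced to (0, 0)
               c(37.5, -2.5),      # Alboran Sea, cell abutting 0 longitude
               c(27.5, -112.5),    # Gulf of California (north)
               c(22.5, -107.5))    # Gulf of California (south)
  unique(cell_of(pts[, 1], pts[, 2], spec))
}
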