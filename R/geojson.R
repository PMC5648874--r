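#' Export a realm partition as GeoJSON
#'
#' Each realm becomes one Feature with a MultiPolygon geometry built from
#' its grid cells (horizontally contiguous cells in the same row are
#' merged into rectangles). Cells never cross the antimeridian, so all
#' polygons stay within [-180, 180].
#'
#' @param partition Named vector cell id -> realm label (`NA` skipped).
#' @param spec A [grid_spec()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
realms_to_geojson <- function(partition, spec, path) {
  part <- partition[!is.na(partition)]
  res <- spec$resolution
  features <- lapply(sort(unique(as.character(part))), function(r) {
    cells <- names(part)[part == r]
    rc <- cell_rowcol(cells)
    rc <- rc[order(rc$row, rc$col), ]
    polys <- list()
    for (row in unique(rc$row)) {
      cols <- sort(rc$col[rc$row == row])
      runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
      lat0 <- row * res - 90
      for (run in runs) {
        lon0 <- run[1] * res - 180
        lon1 <- (run[length(run)] + 1) * res - 180
        ring <- list(c(lon0, lat0), c(lon1, lat0), c(lon1, lat0 + res),
                     c(lon0, lat0 + res), c(lon0, lat0))
        polys[[length(polys) + 1L]] <- list(ring)
      }
    }
    list(type = "Feature",
         properties = list(realm = r, n_cells = length(cells)),
         geometry = list(type = "MultiPolygon", coordinates = polys))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
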