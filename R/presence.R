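#' Build a binary species-by-cell presence matrix
#'
#' Bins cleaned occurrence records into grid cells and records each
#' species once per cell regardless of how many times it was observed
#' there. Cells listed in `excluded_cells` are dropped, as are species
#' occupying fewer than `min_cells_per_species` cells and cells left with
#' no species.
#'
#' @param records data.frame with `species`, `lat`, `lon`.
#' @param spec A [grid_spec()].
#' @param excluded_cells Character vector of cell ids to drop (possibly
#'   empty); see [default_cell_exclusions()].
#' @param min_cells_per_species Minimum number of occupied cells for a
#'   species to be retained (default 1: keep all).
#' @return A sparse pattern matrix (`Matrix::ngCMatrix`) with species as
#'   rows and cells as columns, both axes labeled.
#' @examples
#' r <- data.frame(species = "Calanus finmarchicus",
#'                 lat = c(1, 2, 2), lon = c(1, 1, 1.2))
#' m <- build_presence_matrix(r, grid_spec(5))
#' sum(m)  # 1 cell: all three records fall in the same 5-degree cell
#' @export
build_presence_matrix <- function(records, spec = grid_spec(),
                                  excluded_cells = character(),
                                  min_cells_per_species = 1L) {
  stopifnot(is.data.frame(records), inherits(spec, "grid_spec"))
  cells <- cell_of(records$lat, records$lon, spec)
  ok <- !is.na(cells)
  sp <- as.character(records$species)[ok]
  cells <- cells[ok]
  if (length(excluded_cells)) {
    keep <- !(cells %in% excluded_cells)
    sp <- sp[keep]; cells <- cells[keep]
  }
  if (!length(sp)) stop("empty presence matrix after filtering", call. = FALSE)
  pairs <- !duplicated(paste(sp, cells, sep = "\r"))
  sp <- sp[pairs]; cells <- cells[pairs]

  if (min_cells_per_species > 1L) {
    n_per_sp <- table(sp)
    keep <- sp %in% names(n_per_sp)[n_per_sp >= min_cells_per_species]
    sp <- sp[keep]; cells <- cells[keep]
  }
  if (!length(sp)) stop("empty presence matrix after filtering", call. = FALSE)

  sp_lev <- sort(unique(sp))
  cell_lev <- sort(unique(cells))
  m <- Matrix::sparseMatrix(i = match(sp, sp_lev), j = match(cells, cell_lev),
                            dims = c(length(sp_lev), length(cell_lev)),
                            dimnames = list(sp_lev, cell_lev))
  m[, Matrix::colSums(m) > 0, drop = FALSE]  # cells emptied by species filtering
}

#' Aggregate a presence matrix from cells to named regions
#'
#' A region records a species if any of its member cells does. Cells
#' absent from the mapping are dropped (with a message giving the count).
#'
#' @param matrix Species-by-cell presence matrix.
#' @param cell_to_region Named character vector: names are cell ids,
#'   values are region labels.
#' @return Species-by-region presence matrix.
#' @export
aggregate_to_regions <- function(matrix, cell_to_region) {
  if (!length(cell_to_region)) stop("empty cell-to-region mapping", call. = FALSE)
  cells <- colnames(matrix)
  mapped <- cells %in% names(cell_to_region)
  if (!all(mapped))
    message(sum(!mapped), " cell(s) not in the region mapping were dropped")
  if (!any(mapped)) stop("no matrix cell is covered by the mapping", call. = FALSE)
  m <- matrix[, mapped, drop = FALSE]
  region <- as.character(cell_to_region[colnames(m)])
  lev <- sort(unique(region))
  # indicator: cells x regions
  ind <- Matrix::sparseMatrix(i = seq_along(region), j = match(region, lev),
                              dims = c(length(region), length(lev)),
                              dimnames = list(colnames(m), lev))
  out <- (m %*% ind) > 0
  keep_sp <- Matrix::rowSums(out) > 0
  as(out[keep_sp, , drop = FALSE], "nMatrix")
}

#' Aggregate a presence matrix from species to genus rank
#'
#' A genus is present in a cell if any member species is. Species missing
#' from the mapping fall back to the first token of their binomial.
#'
#' @param matrix Species-by-cell presence matrix.
#' @param species_to_genus Optional named character vector mapping species
#'   to genus.
#' @return Genus-by-cell presence matrix.
#' @export
aggregate_by_rank <- function(matrix, species_to_genus = NULL) {
  sp <- rownames(matrix)
  genus <- vapply(strsplit(sp, "[[:space:]]+"), `[`, "", 1L)
  if (!is.null(species_to_genus)) {
    hit <- sp %in% names(species_to_genus)
    genus[hit] <- as.character(species_to_genus[sp[hit]])
  }
  lev <- sort(unique(genus))
  ind <- Matrix::sparseMatrix(i = match(genus, lev), j = seq_along(genus),
                              dims = c(length(lev), length(sp)),
                              dimnames = list(lev, sp))
  as((ind %*% matrix) > 0, "nMatrix")
}

#' Export a presence matrix as sparse text files
#'
#' Writes a triplet CSV (`cell_id, species, 1`) and, alongside it, a
#' MatrixMarket sparse export with separate row/column label files.
#'
#' @param matrix Species-by-cell presence matrix.
#' @param prefix Output path prefix; files `<prefix>.triplets.csv`,
#'   `<prefix>.mtx`, `<prefix>.rows.txt`, `<prefix>.cols.txt` are written.
#' @return Invisibly, the vector of paths written.
#' @export
write_presence_matrix <- function(matrix, prefix) {
  tm <- as(as(matrix, "dMatrix"), "TsparseMatrix")
  trip <- data.frame(cell_id = colnames(matrix)[tm@j + 1L],
                     species = rownames(matrix)[tm@i + 1L],
                     present = 1L)
  trip <- trip[order(trip$cell_id, trip$species), ]
  paths <- paste0(prefix, c(".triplets.csv", ".mtx", ".rows.txt", ".cols.txt"))
  write.csv(trip, paths[1], row.names = FALSE, quote = FALSE)
  Matrix::writeMM(as(matrix, "dMatrix"), paths[2])
  writeLines(rownames(matrix), paths[3])
  writeLines(colnames(matrix), paths[4])
  invisible(paths)
}
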