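#' Delineate nested biogeographic realms from a presence matrix
#'
#' The central fitting function. Cells are clustered by group-average
#' linkage on a presence-absence dissimilarity, then progressively
#' delimited into spatially coherent realms at a ladder of low
#' percent-similarity thresholds (default 1-6%): the dendrogram is cut at
#' the coarsest threshold; cluster groups are filtered for spatial
#' contiguity (non-adjacent fragments of a group are released) and small
#' enclaves are absorbed; each resulting realm is then re-examined at the
#' next threshold and subdivided further while subdivision is supported.
#' A subdivision is accepted only if it produces at least two
#' post-absorption realms and, when `simprof_gate` is on, the parent
#' realm's cells show significant multivariate structure under SIMPROF.
#'
#' Cells released from fragments that no enclave absorbs remain assigned
#' to the parent realm; a top-level unclassified residue is reported
#' rather than forced into a realm.
#'
#' @param matrix Species-by-cell presence matrix; column names must be
#'   canonical cell ids on `grid`.
#' @param grid A [grid_spec()].
#' @param thresholds Increasing percent-similarity levels at which realms
#'   are progressively delimited.
#' @param index Dissimilarity index (see [dissimilarity()]).
#' @param simprof_gate Gate subdivisions on a SIMPROF test of the parent
#'   realm's cells.
#' @param n_permutations,alpha,simprof_max_cells SIMPROF settings (the
#'   test subsamples at most `simprof_max_cells` cells of large realms).
#' @param min_enclave_cells Enclave-absorption size rule: connected
#'   groups of fewer than this many cells surrounded by another group are
#'   subsumed into it.
#' @param nested If `FALSE`, perform independent global cuts at each
#'   threshold instead of the nested subdivision (comparison mode); the
#'   per-threshold partitions are then stored in `$independent_cuts`.
#' @param seed Integer seed for the SIMPROF permutations.
#' @return An object of class `realm_hierarchy` with components
#'   `cell_realm` (named vector: cell -> most-derived realm label),
#'   `hierarchy` (data.frame: realm, parent, threshold, n_cells,
#'   n_species), `dendrogram`, `simprof_log`, `unassigned`, and the call.
#'   Methods: `print`, `summary`, `plot`, [realm_partition()],
#'   [compare_partitions()].
#' @examples
#' sim <- simulate_occurrence_dataset(simulation_config(
#'   n_realms = 2, endemics_per_realm = 60, cosmopolitan_count = 5,
#'   gradient_species_count = 0, seed = 1))
#' m <- build_presence_matrix(sim$records, grid_spec(10))
#' fit <- delineate_realms(m, grid_spec(10), seed = 1)
#' fit
#' @export
delineate_realms <- function(matrix, grid, thresholds = 1:6,
                             index = "jaccard", simprof_gate = TRUE,
                             n_permutations = 199, alpha = 0.05,
                             simprof_max_cells = 100,
                             min_enclave_cells = 4, nested = TRUE,
                             seed = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  thresholds <- sort(thresholds)
  cells <- colnames(matrix)
  if (length(cells) < 2) {
    part <- stats::setNames(rep("1", length(cells)), cells)
    return(structure(list(cell_realm = part,
                          hierarchy = data.frame(realm = "1", parent = NA,
                                                 threshold = NA_real_,
                                                 n_cells = length(cells),
                                                 n_species = nrow(matrix)),
                          realm_cells = list(`1` = cells),
                          thresholds = thresholds, index = index, grid = grid,
                          dendrogram = NULL, simprof_log = list(),
                          unassigned = character(), call = match.call()),
                     class = "realm_hierarchy"))
  }
  d <- pairwise_dissimilarity(matrix, index)
  dend <- upgma(d)
  adj <- grid_adjacency(grid, cells = cells)
  cuts <- lapply(thresholds, function(s) cut_at_similarity(dend, s))
  names(cuts) <- as.character(thresholds)

  simprof_log <- list()

  # refine one parent realm's cell set at threshold position ti
  refine <- function(parent_cells, ti) {
    glab <- cuts[[ti]][parent_cells]
    if (length(unique(glab)) < 2) return(NULL)
    lab <- stats::setNames(as.character(glab), parent_cells)
    sub_adj <- lapply(adj[parent_cells],
                      function(v) v[v %in% parent_cells])
    lab <- drop_disjoint_fragments(lab, sub_adj)
    lab <- absorb_small_enclaves(lab, sub_adj, min_cells = min_enclave_cells)
    kept <- unique(lab[!is.na(lab)])
    if (length(kept) < 2) return(NULL)
    lab
  }

  if (!nested) {
    indep <- lapply(seq_along(thresholds), function(ti) {
      lab <- refine(cells, ti)
      if (is.null(lab))
        lab <- stats::setNames(rep("1", length(cells)), cells)
      lab
    })
    names(indep) <- as.character(thresholds)
    lab <- indep[[1]]
  }

  hierarchy <- data.frame(realm = "1", parent = NA_character_,
                          threshold = NA_real_,
                          n_cells = length(cells),
                          n_species = nrow(matrix),
                          stringsAsFactors = FALSE)
  realm_cells <- list(`1` = cells)
  assignment <- stats::setNames(rep("1", length(cells)), cells)
  unassigned <- character()
  next_realm <- 1L

  if (nested) {
    # queue of (realm id, threshold position to try next)
    queue <- list(list(id = "1", ti = 1L))
    si <- 0L
    while (length(queue)) {
      task <- queue[[1]]; queue <- queue[-1]
      pc <- realm_cells[[task$id]]
      if (length(pc) < 2) next
      gate_ok <- TRUE
      if (simprof_gate) {
        si <- si + 1L
        sp <- simprof_test(matrix[, pc, drop = FALSE],
                           n_permutations = n_permutations, index = index,
                           max_cells = simprof_max_cells,
                           seed = if (is.null(seed)) NULL else seed + si)
        simprof_log[[task$id]] <- sp
        gate_ok <- sp$p_value <= alpha
      }
      if (!gate_ok) next     # homogeneous realm: no further subdivision
      for (ti in task$ti:length(thresholds)) {
        lab <- refine(pc, ti)
        if (is.null(lab)) next
        kids <- unique(lab[!is.na(lab)])
        for (k in kids) {
          next_realm <- next_realm + 1L
          kid_id <- as.character(next_realm)
          kcells <- names(lab)[!is.na(lab) & lab == k]
          realm_cells[[kid_id]] <- kcells
          assignment[kcells] <- kid_id
          hierarchy <- rbind(hierarchy, data.frame(
            realm = kid_id, parent = task$id, threshold = thresholds[ti],
            n_cells = length(kcells),
            n_species = sum(Matrix::rowSums(matrix[, kcells, drop = FALSE]) > 0),
            stringsAsFactors = FALSE))
          if (ti < length(thresholds))
            queue <- c(queue, list(list(id = kid_id, ti = ti + 1L)))
        }
        # residual cells stay with the parent realm
        break
      }
    }
    unassigned <- if (nrow(hierarchy) > 1)
      names(assignment)[assignment == "1"] else character()
  } else {
    assignment <- lab
    unassigned <- names(lab)[is.na(lab)]
    hierarchy <- data.frame(realm = unique(lab[!is.na(lab)]),
                            parent = NA_character_,
                            threshold = thresholds[1],
                            n_cells = as.integer(table(lab)[unique(lab[!is.na(lab)])]),
                            n_species = NA_integer_,
                            stringsAsFactors = FALSE)
  }

  out <- list(cell_realm = assignment, hierarchy = hierarchy,
              realm_cells = realm_cells, thresholds = thresholds,
              index = index, grid = grid, dendrogram = dend,
              simprof_log = simprof_log, unassigned = unassigned,
              call = match.call())
  if (!nested) out$independent_cuts <- indep
  class(out) <- "realm_hierarchy"
  out
}

#' Extract the flat realm partition at a hierarchy depth
#'
#' Depth 1 is the partition created by the first accepted subdivision of
#' the world (the "top-level realms"); deeper levels refine it. Cells
#' whose most-derived realm is shallower than `depth` keep that realm's
#' label. `depth = Inf` (default) gives the most-derived (leaf) realm for
#' every cell, the analogue of the final realm map.
#'
#' @param fit A `realm_hierarchy` from [delineate_realms()].
#' @param depth Hierarchy depth (1 = top level).
#' @return Named character vector: cell -> realm label.
#' @export
realm_partition <- function(fit, depth = Inf) {
  stopifnot(inherits(fit, "realm_hierarchy"))
  h <- fit$hierarchy
  dep <- stats::setNames(rep(0L, nrow(h)), h$realm)
  for (i in seq_len(nrow(h)))
    if (!is.na(h$parent[i])) dep[h$realm[i]] <- dep[h$parent[i]] + 1L
  anc <- function(r) {                     # ancestor at the requested depth
    if (is.na(r)) return(NA_character_)
    while (dep[r] > depth) r <- h$parent[h$realm == r]
    r
  }
  out <- vapply(fit$cell_realm, anc, "")
  names(out) <- names(fit$cell_realm)
  out
}

#' Pelagic-style overlay: realms from the most widespread species only
#'
#' Retains the top `widespread_fraction` of species by occupied-cell
#' count (ties at the cutoff are all retained) and re-runs the
#' delineation on that subset. Widespread species are predominantly
#' pelagic, so this mirrors a pelagic-only analysis and yields a coarser
#' set of realms within which the full-data realms nest. Cells left with
#' no retained species are unassigned in the overlay.
#'
#' @inheritParams delineate_realms
#' @param widespread_fraction Fraction of species to retain.
#' @param ... Passed to [delineate_realms()].
#' @return A `realm_hierarchy` for the overlay, with an extra
#'   `overlay_dropped_cells` component.
#' @export
pelagic_realm_overlay <- function(matrix, grid, widespread_fraction = 0.10,
                                  thresholds = 1:6, seed = NULL, ...) {
  if (nrow(matrix) < 10) stop("need at least 10 species", call. = FALSE)
  counts <- Matrix::rowSums(matrix)
  k <- max(1L, floor(widespread_fraction * nrow(matrix)))
  cutoff <- sort(counts, decreasing = TRUE)[k]
  keep <- counts >= cutoff                     # ties at the cutoff retained
  m <- matrix[keep, , drop = FALSE]
  occ <- Matrix::colSums(m) > 0
  dropped <- colnames(m)[!occ]
  if (length(dropped))
    message(length(dropped), " cell(s) have no widespread species and are unassigned")
  m <- m[, occ, drop = FALSE]
  fit <- delineate_realms(m, grid, thresholds = thresholds, seed = seed, ...)
  fit$overlay_dropped_cells <- dropped
  fit
}

#' @export
print.realm_hierarchy <- function(x, ...) {
  leaves <- setdiff(x$hierarchy$realm, x$hierarchy$parent)
  cat(sprintf("Realm hierarchy: %d cells, %d realms (%d leaf) at thresholds %s%% (%s)\n",
              length(x$cell_realm), nrow(x$hierarchy), length(leaves),
              paste(x$thresholds, collapse = ","), x$index))
  if (length(x$unassigned))
    cat(sprintf("  %d cell(s) unclassified at the top level\n", length(x$unassigned)))
  invisible(x)
}

#' @export
summary.realm_hierarchy <- function(object, ...) {
  h <- object$hierarchy
  tab <- table(object$cell_realm)
  h$n_cells_final <- as.integer(tab[h$realm])
  h$n_cells_final[is.na(h$n_cells_final)] <- 0L
  cat("Realm hierarchy\n")
  print(h, row.names = FALSE)
  invisible(h)
}

#' Map a realm partition on the latitude-longitude grid
#'
#' @param x A `realm_hierarchy`.
#' @param depth Hierarchy depth to map (default: leaf realms).
#' @param ... Passed to [graphics::image()].
#' @export
plot.realm_hierarchy <- function(x, depth = Inf, ...) {
  part <- realm_partition(x, depth)
  rc <- cell_rowcol(names(part))
  z <- matrix(NA_integer_, x$grid$n_cols, x$grid$n_rows)
  z[cbind(rc$col + 1L, rc$row + 1L)] <- as.integer(factor(part))
  res <- x$grid$resolution
  graphics::image(x = seq(-180, 180, by = res), y = seq(-90, 90, by = res),
                  z = z, xlab = "Longitude", ylab = "Latitude",
                  col = grDevices::hcl.colors(max(1L, max(z, na.rm = TRUE)), "Spectral"),
                  ...)
  invisible(x)
}
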