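#' Neighbor relation over grid cells
#'
#' Rook adjacency (shared edge) on the latitude-longitude lattice.
#' Columns wrap across the antimeridian; rows do not wrap across the
#' poles. Queen (corner-touching) adjacency is available behind a flag.
#'
#' @param spec A [grid_spec()].
#' @param cells Optional character vector of cell ids: the universe over
#'   which neighbors are reported (neighbors outside it are dropped).
#'   Default: all grid cells.
#' @param queen If `TRUE`, include diagonal neighbors.
#' @return Named list: cell id -> character vector of neighboring ids.
#' @export
grid_adjacency <- function(spec, cells = NULL, queen = FALSE) {
  stopifnot(inherits(spec, "grid_spec"))
  if (is.null(cells)) {
    rc <- expand.grid(row = 0:(spec$n_rows - 1L), col = 0:(spec$n_cols - 1L))
    cells <- cell_id(rc$row, rc$col)
  } else {
    rc <- cell_rowcol(cells)
  }
  off <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (queen) off <- rbind(off, c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  nb <- vector("list", length(cells))
  names(nb) <- cells
  universe <- cells
  for (k in seq_len(nrow(off))) {
    r <- rc$row + off[k, 1L]
    c <- (rc$col + off[k, 2L]) %% spec$n_cols     # antimeridian wrap
    ok <- r >= 0L & r < spec$n_rows                # no pole wrap
    cand <- rep(NA_character_, length(cells))
    cand[ok] <- cell_id(r[ok], c[ok])
    cand[!(cand %in% universe)] <- NA
    hit <- !is.na(cand)
    for (i in which(hit)) nb[[i]] <- c(nb[[i]], cand[i])
  }
  nb
}

#' Connected components within each label class
#'
#' Components are computed separately for each label: two cells belong to
#' the same component iff they share a label and are connected through
#' same-labeled neighbors. `NA` labels form their own ("unassigned")
#' class.
#'
#' @param labels Named vector (names = cell ids) of group labels; may
#'   contain `NA`.
#' @param adjacency Neighbor list from [grid_adjacency()] covering the
#'   labeled cells.
#' @return data.frame with `cell`, `label`, `component` (label-qualified
#'   component id) and `component_size`.
#' @export
contiguous_components <- function(labels, adjacency) {
  cells <- names(labels)
  if (is.null(cells)) stop("`labels` must be named by cell id", call. = FALSE)
  lab <- as.character(labels)
  lab[is.na(lab)] <- ".unassigned"
  nbr_idx <- lapply(adjacency[cells], function(v) {
    j <- match(v, cells); j[!is.na(j)]
  })
  comp <- rep(NA_integer_, length(cells))
  next_id <- 0L
  stack <- integer(length(cells))
  for (i in seq_along(cells)) {
    if (!is.na(comp[i])) next
    next_id <- next_id + 1L
    comp[i] <- next_id
    stack[1L] <- i; top <- 1L
    while (top > 0L) {
      cur <- stack[top]; top <- top - 1L
      for (j in nbr_idx[[cur]]) {
        if (is.na(comp[j]) && lab[j] == lab[cur]) {
          comp[j] <- next_id
          top <- top + 1L; stack[top] <- j
        }
      }
    }
  }
  sizes <- table(comp)
  out <- data.frame(cell = cells,
                    label = ifelse(lab == ".unassigned", NA_character_, lab),
                    component = as.integer(comp),
                    component_size = as.integer(sizes[as.character(comp)]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Release spatially disjoint fragments of each group
#'
#' Cells with the same cluster-group label that are not spatially
#' connected cannot jointly delimit a realm: for each label, only the
#' largest connected component keeps the label (ties broken towards the
#' component containing the lexicographically smallest cell id); cells of
#' the other components are marked unassigned (`NA`) for the enclave
#' absorption step.
#'
#' @inheritParams contiguous_components
#' @return Named label vector with minor fragments set to `NA`.
#' @export
drop_disjoint_fragments <- function(labels, adjacency) {
  cc <- contiguous_components(labels, adjacency)
  out <- labels
  for (lb in unique(cc$label[!is.na(cc$label)])) {
    sub <- cc[!is.na(cc$label) & cc$label == lb, ]
    comps <- unique(sub$component)
    if (length(comps) < 2) next
    sizes <- vapply(comps, function(k) sum(sub$component == k), 1L)
    best <- comps[sizes == max(sizes)]
    if (length(best) > 1) {
      # tie: keep the component holding the lexicographically smallest cell
      mins <- vapply(best, function(k) min(sub$cell[sub$component == k]), "")
      best <- best[order(mins)[1]]
    } else best <- best[[1]]
    out[names(out) %in% sub$cell[sub$component != best]] <- NA
  }
  out
}

# boundary contacts of a component: labels of differently-labeled rook
# neighbors with contact counts (shared edges)
.boundary_contacts <- function(cells_in, labels, adjacency) {
  contacts <- character()
  for (cell in cells_in)
    for (nbr in adjacency[[cell]])
      if (!(nbr %in% cells_in)) contacts <- c(contacts, labels[[nbr]])
  table(contacts[!is.na(contacts)])
}

#' Absorb small enclaves into their surrounding realm
#'
#' Connected components of fewer than `min_cells` cells that are
#' fragments of a larger group, or unassigned, are subsumed into a
#' neighboring realm: the unique bordering label if there is only one,
#' otherwise the label with the longest shared boundary (ties towards the
#' larger realm, then the lexicographically smaller label). A small
#' component that constitutes its entire cluster group (an isolated
#' little sea with its own biota) is retained, as are enclosed islands of
#' `min_cells` or more cells. Iterates to a fixpoint and is idempotent.
#'
#' @inheritParams contiguous_components
#' @param min_cells Components strictly smaller than this are absorbed
#'   (default 4).
#' @return Named label vector with enclaves relabeled; an attribute
#'   `absorption_log` records each relabeling.
#' @export
absorb_small_enclaves <- function(labels, adjacency, min_cells = 4) {
  out <- labels
  log <- list()
  repeat {
    cc <- contiguous_components(out, adjacency)
    class_sizes <- table(out, useNA = "no")
    changed <- FALSE
    for (k in unique(cc$component)) {
      sub <- cc[cc$component == k, ]
      sz <- sub$component_size[[1]]
      lb <- sub$label[[1]]
      if (sz >= min_cells) next
      # same-label contacts cannot occur (they would be in this component)
      contacts <- .boundary_contacts(sub$cell, out, adjacency)
      if (!length(contacts)) next
      whole_class <- !is.na(lb) && sz == class_sizes[[lb]]
      # a small component that is its entire cluster group and is not
      # enclosed by a single realm is a genuine small realm (isolated
      # seas with their own biota) and is retained
      if (whole_class && length(contacts) > 1) next
      best <- names(contacts)[contacts == max(contacts)]
      if (length(best) > 1) {
        rs <- class_sizes[best]
        best <- best[rs == max(rs)]
        best <- sort(best)[[1]]
      }
      out[names(out) %in% sub$cell] <- best
      log[[length(log) + 1L]] <- data.frame(
        cells = paste(sub$cell, collapse = ";"),
        from = if (is.na(lb)) "unassigned" else lb, to = best, size = sz)
      changed <- TRUE
    }
    if (!changed) break
  }
  attr(out, "absorption_log") <-
    if (length(log)) do.call(rbind, log) else NULL
  out
}
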