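#' Per-realm endemic species and richness
#'
#' A species is endemic to realm R iff every assigned cell it occupies
#' lies in R and it occupies at least `min_cells` cells (species recorded
#' in a single cell are too poorly known to characterise a realm and are
#' never counted as endemic). Cells without a realm assignment are
#' excluded (with a message).
#'
#' @param matrix Species-by-cell presence matrix.
#' @param partition Named vector cell -> realm label (e.g. from
#'   [realm_partition()]); may contain `NA`.
#' @param min_cells Minimum occupied cells for endemic status (default 2,
#'   i.e. "more than one cell").
#' @param denominator Either `"all"` (per-realm richness counts every
#'   species recorded in the realm) or `"min_cells"` (only species in at
#'   least `min_cells` cells enter the denominator).
#' @return Object of class `endemicity_table`: data.frame with one row
#'   per realm (`realm`, `n_cells`, `n_species`, `n_unique`,
#'   `pct_endemicity`) and a `unique_species` attribute (named list of
#'   per-realm endemic species).
#' @export
unique_species_per_realm <- function(matrix, partition, min_cells = 2,
                                     denominator = c("all", "min_cells")) {
  denominator <- match.arg(denominator)
  cells <- colnames(matrix)
  part <- partition[cells]
  names(part) <- cells
  drop <- is.na(part) | !(cells %in% names(partition))
  if (any(drop))
    message(sum(drop), " cell(s) without realm assignment excluded")
  m <- matrix[, !drop, drop = FALSE]
  part <- part[!drop]
  realms <- sort(unique(as.character(part)))
  occ_cells <- Matrix::rowSums(m)

  # per species: number of distinct realms occupied, and which
  lev <- realms
  ind <- Matrix::sparseMatrix(i = seq_along(part), j = match(part, lev),
                              dims = c(length(part), length(lev)),
                              dimnames = list(colnames(m), lev))
  per_realm_cells <- m %*% ind                       # species x realm cell counts
  in_realm <- per_realm_cells > 0
  n_realms_occupied <- Matrix::rowSums(in_realm)

  endemic_realm <- rep(NA_character_, nrow(m))
  one <- n_realms_occupied == 1 & occ_cells >= min_cells
  if (any(one)) {
    w <- apply(as.matrix(in_realm[one, , drop = FALSE]), 1, which)
    endemic_realm[one] <- lev[as.integer(w)]
  }

  rich <- if (denominator == "all") Matrix::colSums(in_realm)
          else Matrix::colSums(in_realm[occ_cells >= min_cells, , drop = FALSE])
  n_unique <- vapply(lev, function(r) sum(endemic_realm == r, na.rm = TRUE), 1L)
  tab <- data.frame(realm = lev,
                    n_cells = as.integer(table(part)[lev]),
                    n_species = as.integer(rich[lev]),
                    n_unique = as.integer(n_unique),
                    pct_endemicity = ifelse(rich[lev] > 0,
                                            100 * n_unique / as.numeric(rich[lev]),
                                            NA_real_),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  uniq <- lapply(lev, function(r) rownames(m)[!is.na(endemic_realm) & endemic_realm == r])
  names(uniq) <- lev
  structure(tab, unique_species = uniq, min_cells = min_cells,
            class = c("endemicity_table", "data.frame"))
}

#' @rdname unique_species_per_realm
#' @export
endemicity_table <- unique_species_per_realm

#' Percent endemicity summary across realms
#'
#' Mean percent endemicity with a 95% t-interval across realms (the
#' conventional "mean plus or minus 95% confidence limits"), and the
#' range. Realms with zero recorded species are excluded with a warning.
#'
#' @param table An `endemicity_table`.
#' @return List with `per_realm` (named percents), `mean`, `ci_halfwidth`,
#'   `ci` (two-sided 95% t-interval), `range`.
#' @export
percent_endemicity <- function(table) {
  pct <- stats::setNames(table$pct_endemicity, table$realm)
  bad <- is.na(pct)
  if (any(bad)) {
    warning(sum(bad), " realm(s) with no species excluded from the summary")
    pct <- pct[!bad]
  }
  n <- length(pct)
  m <- mean(pct)
  hw <- if (n > 1) qt(0.975, n - 1) * sd(pct) / sqrt(n) else NA_real_
  list(per_realm = pct, mean = m, ci_halfwidth = hw,
       ci = c(m - hw, m + hw), range = range(pct))
}

#' Rank species by number of occupied cells
#'
#' @param matrix Species-by-cell presence matrix.
#' @param top_fraction Retain the top fraction of species (ties at the
#'   cutoff included); mutually exclusive with `top_n`.
#' @param top_n Retain this many top species (ties included).
#' @return data.frame `species`, `n_cells`, `frac_cells` (fraction of all
#'   cells), `rank`; sorted by occupancy descending, ties by name.
#' @export
widespread_ranking <- function(matrix, top_fraction = NULL, top_n = NULL) {
  if (nrow(matrix) == 0) stop("empty matrix", call. = FALSE)
  counts <- Matrix::rowSums(matrix)
  ord <- order(-counts, rownames(matrix))
  df <- data.frame(species = rownames(matrix)[ord],
                   n_cells = as.integer(counts[ord]),
                   frac_cells = as.numeric(counts[ord]) / ncol(matrix),
                   stringsAsFactors = FALSE)
  df$rank <- seq_len(nrow(df))
  k <- nrow(df)
  if (!is.null(top_fraction)) k <- max(1L, floor(top_fraction * nrow(df)))
  if (!is.null(top_n)) k <- min(top_n, nrow(df))
  cutoff <- df$n_cells[k]
  df[df$n_cells >= cutoff, , drop = FALSE]
}

#' Per-realm, per-phylum breakdown of endemic species
#'
#' @param table An `endemicity_table`.
#' @param species_traits data.frame with `species` and `phylum` columns;
#'   endemics missing from it are binned as `"other"`.
#' @return List with `counts` (realm x phylum matrix), `row_percents`
#'   (percent of each realm's endemics per phylum) and `column_means`.
#' @export
taxon_breakdown <- function(table, species_traits) {
  uniq <- attr(table, "unique_species")
  phyla <- stats::setNames(as.character(species_traits$phylum), species_traits$species)
  lev <- sort(unique(c(phyla[unlist(uniq)], "other")), na.last = NA)
  lev <- unique(c(setdiff(lev, "other"), "other"))
  counts <- t(vapply(uniq, function(sp) {
    ph <- phyla[sp]
    ph[is.na(ph)] <- "other"
    as.integer(base::table(factor(ph, levels = lev)))
  }, integer(length(lev))))
  colnames(counts) <- lev
  rs <- rowSums(counts)
  pct <- 100 * counts / ifelse(rs > 0, rs, 1)
  pct[rs == 0, ] <- 0
  list(counts = counts, row_percents = pct, column_means = colMeans(pct))
}

#' Range-size spread of pelagic versus benthic species
#'
#' For each trait class, the fraction of its species occupying more than
#' `cell_threshold` cells. Pelagic species typically range much more
#' widely than benthic ones.
#'
#' @param matrix Species-by-cell presence matrix.
#' @param species_traits data.frame with `species` and `pelagic`
#'   (logical/0-1); species with missing flags are classed `"unknown"`.
#' @param cell_threshold Occupancy threshold in cells.
#' @return Named numeric vector of fractions per class (`pelagic`,
#'   `benthic`, and `unknown` when present).
#' @export
pelagic_benthic_spread <- function(matrix, species_traits, cell_threshold = 50) {
  counts <- Matrix::rowSums(matrix)
  flag <- stats::setNames(species_traits$pelagic, species_traits$species)[rownames(matrix)]
  cls <- ifelse(is.na(flag), "unknown", ifelse(as.logical(flag), "pelagic", "benthic"))
  wide <- counts > cell_threshold
  out <- tapply(wide, cls, mean)
  out[order(names(out))]
}
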