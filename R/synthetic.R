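#' Configuration for the synthetic occurrence generator
#'
#' Describes a toy ocean with planted biogeographic structure: a grid of
#' cells partitioned into `n_realms` contiguous realms, realm-endemic
#' benthic species with modest ranges, near-cosmopolitan pelagic species
#' with very large ranges, "gradient" species straddling two adjacent
#' realms, heterogeneous per-cell sampling effort, and optionally
#' brackish realms whose species pool is disjoint from the open ocean.
#'
#' @param grid_resolution Cell size in degrees (default 10: an 18 x 36
#'   toy world; use 5 for the full-scale 36 x 72 world).
#' @param lat_range,lon_range Extent of the simulated world in degrees.
#' @param n_realms Number of planted contiguous realms.
#' @param endemics_per_realm Endemic species per realm.
#' @param cosmopolitan_count Number of very widespread species.
#' @param gradient_species_count Species spanning two adjacent realms.
#' @param occupancy_fraction Fraction of its realm's cells an endemic
#'   truly occupies.
#' @param detection_prob Baseline probability that a truly present
#'   (species, cell) pair is recorded at least once.
#' @param effort_dispersion Log-normal sigma of the per-cell sampling
#'   effort multiplier (0 = uniform effort).
#' @param brackish_realms Number of realms treated as brackish seas:
#'   cosmopolitan and gradient species avoid their cells.
#' @param pelagic_fraction_of_cosmopolitans Fraction of cosmopolitans
#'   flagged pelagic (endemics are benthic).
#' @param cosmopolitan_min_occupancy Lower bound of a cosmopolitan's
#'   occupancy as a fraction of (non-brackish) cells.
#' @param seed Integer seed; the whole generation is reproducible.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(grid_resolution = 10,
                              lat_range = c(-90, 90), lon_range = c(-180, 180),
                              n_realms = 8, endemics_per_realm = 200,
                              cosmopolitan_count = 40,
                              gradient_species_count = 20,
                              occupancy_fraction = 0.6, detection_prob = 0.9,
                              effort_dispersion = 0.5, brackish_realms = 0,
                              pelagic_fraction_of_cosmopolitans = 0.9,
                              cosmopolitan_min_occupancy = 0.3, seed = 1) {
  cfg <- list(grid_resolution = grid_resolution, lat_range = lat_range,
              lon_range = lon_range, n_realms = as.integer(n_realms),
              endemics_per_realm = as.integer(endemics_per_realm),
              cosmopolitan_count = as.integer(cosmopolitan_count),
              gradient_species_count = as.integer(gradient_species_count),
              occupancy_fraction = occupancy_fraction,
              detection_prob = detection_prob,
              effort_dispersion = effort_dispersion,
              brackish_realms = as.integer(brackish_realms),
              pelagic_fraction_of_cosmopolitans = pelagic_fraction_of_cosmopolitans,
              cosmopolitan_min_occupancy = cosmopolitan_min_occupancy,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_realms >= 1, endemics_per_realm >= 0, cosmopolitan_count >= 0,
              gradient_species_count >= 0, brackish_realms >= 0,
              brackish_realms <= n_realms,
              occupancy_fraction > 0, occupancy_fraction <= 1,
              detection_prob >= 0, detection_prob <= 1,
              effort_dispersion >= 0,
              pelagic_fraction_of_cosmopolitans >= 0,
              pelagic_fraction_of_cosmopolitans <= 1,
              lat_range[1] < lat_range[2], lon_range[1] < lon_range[2])
  })
  spec <- grid_spec(grid_resolution)
  if (length(.world_cells(cfg)) < cfg$n_realms)
    stop("grid contains fewer cells than `n_realms`", call. = FALSE)
  structure(cfg, class = "simulation_config")
}

# cells of the simulated world (grid cells inside the lat/lon ranges)
.world_cells <- function(config) {
  spec <- grid_spec(config$grid_resolution)
  res <- spec$resolution
  rows <- which(seq(-90, 90 - res, by = res) >= config$lat_range[1] &
                  seq(-90 + res, 90, by = res) <= config$lat_range[2]) - 1L
  cols <- which(seq(-180, 180 - res, by = res) >= config$lon_range[1] &
                  seq(-180 + res, 180, by = res) <= config$lon_range[2]) - 1L
  rc <- expand.grid(row = rows, col = cols)
  sort(cell_id(rc$row, rc$col))
}

.alpha_code <- function(i) {
  i <- as.integer(i) - 1L
  a <- letters[i %% 26L + 1L]; i <- i %/% 26L
  b <- letters[i %% 26L + 1L]; i <- i %/% 26L
  d <- letters[i %% 26L + 1L]; i <- i %/% 26L
  e <- letters[i %% 26L + 1L]
  paste0(e, d, b, a)
}

#' Plant contiguous realm footprints on the grid
#'
#' Multi-source region growing: `n_realms` seed cells are drawn at
#' random, then unassigned cells adjacent to a realm are attached to a
#' uniformly chosen neighboring realm, round by round, until the world is
#' covered. Realms are connected under rook adjacency (with antimeridian
#' wrap) by construction. Deterministic given the config seed.
#'
#' @param config A [simulation_config()].
#' @return Named character vector cell id -> realm label (`"R1"`,
#'   `"R2"`, ...), with attribute `brackish` listing brackish realm
#'   labels.
#' @export
make_realm_footprints <- function(config) {
  spec <- grid_spec(config$grid_resolution)
  cells <- .world_cells(config)
  if (config$n_realms < 1) stop("n_realms must be >= 1", call. = FALSE)
  if (config$n_realms > length(cells))
    stop("more realms than grid cells", call. = FALSE)
  adj <- grid_adjacency(spec, cells = cells)
  lab <- stats::setNames(rep(NA_character_, length(cells)), cells)
  realms <- paste0("R", seq_len(config$n_realms))
  with_seed(config$seed, {
    lab[sample(cells, config$n_realms)] <- realms
    repeat {
      un <- names(lab)[is.na(lab)]
      if (!length(un)) break
      grew <- FALSE
      # synchronous round: attach each frontier cell to a random
      # already-assigned neighbor realm (state from the previous round)
      snapshot <- lab
      for (cell in un) {
        nb <- snapshot[adj[[cell]]]
        nb <- nb[!is.na(nb)]
        if (!length(nb)) next
        lab[[cell]] <- if (length(nb) == 1) nb[[1]] else sample(nb, 1)
        grew <- TRUE
      }
      if (!grew) stop("world grid is not connected; cannot grow realms",
                      call. = FALSE)
    }
  })
  attr(lab, "brackish") <- realms[seq_len(config$brackish_realms)]
  lab
}

#' Draw true species ranges over the planted realms
#'
#' Endemics occupy `round(occupancy_fraction x realm size)` cells of
#' their realm (an error is raised if that is fewer than 2 cells, since
#' an endemic must be recordable in more than one cell); cosmopolitans
#' occupy a uniform 30-100% (configurable lower bound) of all
#' non-brackish cells; gradient species straddle exactly two adjacent
#' non-brackish realms; species of brackish realms occur only there.
#'
#' @param config A [simulation_config()].
#' @param footprints Output of [make_realm_footprints()].
#' @return List with `ranges` (named list species -> true cell set),
#'   `origin` (named vector: realm label, `"cosmopolitan"` or
#'   `"gradient"`), and `traits` (data.frame `species`, `genus`,
#'   `phylum`, `pelagic`).
#' @export
simulate_species_pools <- function(config, footprints) {
  cells <- names(footprints)
  if (!length(cells)) stop("footprints must cover the grid", call. = FALSE)
  realms <- sort(unique(as.character(footprints)))
  brackish <- attr(footprints, "brackish") %||% character()
  open_cells <- cells[!(footprints %in% brackish)]
  realm_cells <- split(cells, as.character(footprints))

  benthic_phyla <- c("Arthropoda", "Mollusca", "Annelida", "Echinodermata",
                     "Cnidaria", "Bryozoa", "Porifera")
  benthic_w <- c(30, 25, 12, 10, 10, 7, 6)
  pelagic_phyla <- c("Foraminifera", "Chordata", "Ochrophyta", "Cnidaria")

  ranges <- list(); origin <- character(); genus <- character()
  phylum <- character(); pelagic <- logical()
  idx <- 0L
  new_species <- function(stem, gid) {
    idx <<- idx + 1L
    paste0(stem, .alpha_code(gid), " ", .alpha_code(idx))
  }

  with_seed(config$seed + 1000L, {
    for (r in realms) {
      rc <- realm_cells[[r]]
      if (config$endemics_per_realm == 0) next
      k <- round(config$occupancy_fraction * length(rc))
      if (k < 2)
        stop("occupancy_fraction gives endemic ranges of fewer than 2 cells ",
             "in realm ", r, call. = FALSE)
      for (j in seq_len(config$endemics_per_realm)) {
        gid <- match(r, realms) * 1000L + (j - 1L) %/% 4L
        sp <- new_species("Benthus", gid)
        ranges[[sp]] <- sort(sample(rc, k))
        origin[sp] <- r
        genus[sp] <- paste0("Benthus", .alpha_code(gid))
        phylum[sp] <- sample(benthic_phyla, 1, prob = benthic_w)
        pelagic[sp] <- FALSE
      }
    }
    if (config$cosmopolitan_count > 0) {
      for (j in seq_len(config$cosmopolitan_count)) {
        gid <- 50000L + (j - 1L) %/% 4L
        sp <- new_species("Oceanus", gid)
        u <- runif(1, config$cosmopolitan_min_occupancy, 1)
        k <- max(2L, round(u * length(open_cells)))
        ranges[[sp]] <- sort(sample(open_cells, k))
        origin[sp] <- "cosmopolitan"
        genus[sp] <- paste0("Oceanus", .alpha_code(gid))
        is_pel <- runif(1) < config$pelagic_fraction_of_cosmopolitans
        phylum[sp] <- if (is_pel) sample(pelagic_phyla, 1)
                      else sample(benthic_phyla, 1, prob = benthic_w)
        pelagic[sp] <- is_pel
      }
    }
    if (config$gradient_species_count > 0) {
      open_realms <- setdiff(realms, brackish)
      pairs <- .adjacent_realm_pairs(footprints, config)
      pairs <- pairs[pairs[, 1] %in% open_realms & pairs[, 2] %in% open_realms, ,
                     drop = FALSE]
      if (!nrow(pairs))
        stop("no adjacent non-brackish realm pair for gradient species",
             call. = FALSE)
      for (j in seq_len(config$gradient_species_count)) {
        gid <- 60000L + (j - 1L) %/% 4L
        sp <- new_species("Gradus", gid)
        pr <- pairs[sample.int(nrow(pairs), 1), ]
        c1 <- realm_cells[[pr[[1]]]]; c2 <- realm_cells[[pr[[2]]]]
        k <- max(2L, round(config$occupancy_fraction * (length(c1) + length(c2)) / 2))
        base <- c(sample(c1, 1), sample(c2, 1))
        rest <- setdiff(c(c1, c2), base)
        extra <- if (k > 2 && length(rest)) sample(rest, min(k - 2L, length(rest)))
                 else character()
        ranges[[sp]] <- sort(c(base, extra))
        origin[sp] <- "gradient"
        genus[sp] <- paste0("Gradus", .alpha_code(gid))
        phylum[sp] <- sample(benthic_phyla, 1, prob = benthic_w)
        pelagic[sp] <- FALSE
      }
    }
  })
  traits <- data.frame(species = names(ranges), genus = genus[names(ranges)],
                       phylum = phylum[names(ranges)],
                       pelagic = pelagic[names(ranges)],
                       stringsAsFactors = FALSE)
  rownames(traits) <- NULL
  list(ranges = ranges, origin = origin, traits = traits)
}

# realm pairs sharing at least one rook-adjacent cell pair
.adjacent_realm_pairs <- function(footprints, config) {
  spec <- grid_spec(config$grid_resolution)
  cells <- names(footprints)
  adj <- grid_adjacency(spec, cells = cells)
  seen <- character()
  out <- list()
  for (cell in cells) {
    for (nbr in adj[[cell]]) {
      a <- footprints[[cell]]; b <- footprints[[nbr]]
      if (a == b) next
      key <- paste(min(a, b), max(a, b))
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- c(min(a, b), max(a, b))
    }
  }
  do.call(rbind, out)
}

#' Sample occurrence records from true ranges
#'
#' Each true (species, cell) pair is recorded with probability
#' `detection_prob x effort[cell]` (clipped to 1), where per-cell effort
#' is log-normal with sigma `effort_dispersion`; a detected pair emits
#' 1-3 duplicate point records (to exercise deduplication) with
#' coordinates uniform inside the cell.
#'
#' @param config A [simulation_config()].
#' @param pools Output of [simulate_species_pools()].
#' @return data.frame of occurrence records (`species`, `genus`,
#'   `phylum`, `pelagic`, `lat`, `lon`) with attribute `detected_pairs`
#'   (data.frame of the deduplicated truth actually emitted).
#' @export
sample_occurrences <- function(config, pools) {
  ranges <- pools$ranges
  if (!length(ranges)) stop("ranges are empty", call. = FALSE)
  spec <- grid_spec(config$grid_resolution)
  sp <- rep(names(ranges), lengths(ranges))
  cell <- unlist(ranges, use.names = FALSE)
  cells <- sort(unique(cell))
  with_seed(config$seed + 2000L, {
    effort <- stats::setNames(rlnorm(length(cells), 0, config$effort_dispersion),
                              cells)
    p <- pmin(1, config$detection_prob * effort[cell])
    det <- runif(length(sp)) < p
    sp_d <- sp[det]; cell_d <- cell[det]
    copies <- sample.int(3L, length(sp_d), replace = TRUE)
    i <- rep(seq_along(sp_d), copies)
    rc <- cell_rowcol(cell_d[i])
    res <- spec$resolution
    lat <- rc$row * res - 90 + runif(length(i)) * res
    lon <- rc$col * res - 180 + runif(length(i)) * res
    tr <- pools$traits[match(sp_d[i], pools$traits$species), ]
    rec <- data.frame(species = sp_d[i], genus = tr$genus, phylum = tr$phylum,
                      pelagic = as.integer(tr$pelagic), lat = lat, lon = lon,
                      stringsAsFactors = FALSE)
    rownames(rec) <- NULL
    attr(rec, "detected_pairs") <- data.frame(species = sp_d, cell = cell_d,
                                              stringsAsFactors = FALSE)
    rec
  })
}

#' Generate a full synthetic occurrence dataset with ground truth
#'
#' Convenience wrapper running [make_realm_footprints()],
#' [simulate_species_pools()] and [sample_occurrences()]; byte-identical
#' output for identical config (including seed).
#'
#' @param config A [simulation_config()].
#' @return List with `records` (occurrence data.frame), `truth` (list:
#'   `cell_realm`, `species_origin`, `traits`, `ranges`, `brackish`) and
#'   `config`.
#' @export
simulate_occurrence_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  fp <- make_realm_footprints(config)
  pools <- simulate_species_pools(config, fp)
  rec <- sample_occurrences(config, pools)
  list(records = rec,
       truth = list(cell_realm = stats::setNames(as.character(fp), names(fp)),
                    species_origin = pools$origin,
                    traits = pools$traits,
                    ranges = pools$ranges,
                    brackish = attr(fp, "brackish")),
       config = config)
}

#' Write simulation ground truth as delimited files
#'
#' @param truth The `truth` component of [simulate_occurrence_dataset()].
#' @param prefix Path prefix; writes `<prefix>.cell_realm.csv`
#'   (`cell_id, realm`) and `<prefix>.species_origin.csv`
#'   (`species, origin, pelagic`).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(truth, prefix) {
  paths <- paste0(prefix, c(".cell_realm.csv", ".species_origin.csv"))
  write.csv(data.frame(cell_id = names(truth$cell_realm),
                       realm = as.character(truth$cell_realm)),
            paths[1], row.names = FALSE, quote = FALSE)
  pel <- stats::setNames(truth$traits$pelagic, truth$traits$species)
  write.csv(data.frame(species = names(truth$species_origin),
                       origin = as.character(truth$species_origin),
                       pelagic = as.integer(pel[names(truth$species_origin)])),
            paths[2], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
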