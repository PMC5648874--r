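# Shared fixtures, built in code. Expensive ones are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# tiny presence matrix from explicit species sets per cell
presence_from_sets <- function(sets) {
  species <- sort(unique(unlist(sets)))
  m <- Matrix::Matrix(0, length(species), length(sets), sparse = TRUE,
                      dimnames = list(species, names(sets)))
  for (cl in names(sets)) m[sets[[cl]], cl] <- 1
  as(m, "nMatrix")
}

# independent set-arithmetic oracle for pairwise dissimilarity
oracle_dissim <- function(m, index) {
  cols <- colnames(m)
  out <- matrix(0, length(cols), length(cols), dimnames = list(cols, cols))
  for (i in seq_along(cols)) for (j in seq_along(cols)) {
    if (i == j) next
    si <- rownames(m)[as.logical(m[, i])]
    sj <- rownames(m)[as.logical(m[, j])]
    a <- length(intersect(si, sj))
    b <- length(setdiff(si, sj))
    cc <- length(setdiff(sj, si))
    out[i, j] <- switch(index,
      jaccard = 1 - a / (a + b + cc),
      sorensen = ,
      braycurtis_binary = 1 - 2 * a / (2 * a + b + cc),
      betasim = if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc)))
  }
  out
}

# brute-force group-average agglomeration: recompute the mean of all
# between-cluster leaf pairs at every step (no Lance-Williams update)
oracle_upgma_heights <- function(d) {
  m <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(m[clusters[[i]], clusters[[j]]])
      if (h < best) { best <- h; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# a two-block world: two groups of cells with disjoint species pools
two_block_matrix <- function(n_per_block = 10, n_species = 50, seed = 42) {
  set.seed(seed)
  cells <- c(sprintf("r1c%d", seq_len(n_per_block)),
             sprintf("r2c%d", seq_len(n_per_block)))
  code <- function(k) paste0(letters[(k - 1) %/% 26 + 1], letters[(k - 1) %% 26 + 1])
  sets <- list()
  for (i in seq_len(n_per_block)) {
    sets[[cells[i]]] <- sprintf("Ablock %s", code(sample.int(n_species, 30)))
    sets[[cells[n_per_block + i]]] <- sprintf("Bblock %s", code(sample.int(n_species, 30)))
  }
  presence_from_sets(sets[cells])   # columns ordered block-wise
}

# small planted world shared by several tests
toy_world <- function() cached("toy_world", {
  cfg <- simulation_config(n_realms = 4, endemics_per_realm = 60,
                           cosmopolitan_count = 8, gradient_species_count = 4,
                           seed = 3)
  sim <- simulate_occurrence_dataset(cfg)
  m <- build_presence_matrix(sim$records, grid_spec(10))
  list(cfg = cfg, sim = sim, matrix = m, grid = grid_spec(10))
})

# the full-scale planted world used by the acceptance-style checks
standard_world <- function() cached("standard_world", {
  cfg <- simulation_config(grid_resolution = 5, n_realms = 8,
                           endemics_per_realm = 200, cosmopolitan_count = 40,
                           gradient_species_count = 20,
                           occupancy_fraction = 0.6, detection_prob = 0.9,
                           seed = 20090727)
  sim <- simulate_occurrence_dataset(cfg)
  m <- build_presence_matrix(sim$records, grid_spec(5))
  fit <- delineate_realms(m, grid_spec(5), seed = 1)
  list(cfg = cfg, sim = sim, matrix = m, grid = grid_spec(5), fit = fit)
})
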