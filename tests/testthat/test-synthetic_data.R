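small_cfg <- function(...) {
  args <- list(n_realms = 3, endemics_per_realm = 20, cosmopolitan_count = 4,
               gradient_species_count = 2, seed = 5)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}

test_that("generation is deterministic given the config seed", {
  a <- simulate_occurrence_dataset(small_cfg())
  b <- simulate_occurrence_dataset(small_cfg())
  expect_identical(a$records, b$records)
  expect_identical(a$truth$cell_realm, b$truth$cell_realm)
  c <- simulate_occurrence_dataset(small_cfg(seed = 6))
  expect_false(identical(a$records, c$records))
})

test_that("realm footprints partition the grid into contiguous realms", {
  cfg <- small_cfg()
  fp <- make_realm_footprints(cfg)
  g <- grid_spec(cfg$grid_resolution)
  expect_equal(length(fp), g$n_rows * g$n_cols)
  expect_false(anyNA(fp))
  adj <- grid_adjacency(g, cells = names(fp))
  cc <- contiguous_components(stats::setNames(as.character(fp), names(fp)), adj)
  n_comp <- tapply(cc$component, cc$label, function(x) length(unique(x)))
  expect_true(all(n_comp == 1))
  expect_equal(length(unique(as.character(fp))), 3)
})

test_that("footprint edge cases: one realm, and one realm per cell", {
  cfg1 <- simulation_config(n_realms = 1, endemics_per_realm = 5,
                            lat_range = c(0, 30), lon_range = c(0, 30),
                            grid_resolution = 10, seed = 1)
  fp1 <- make_realm_footprints(cfg1)
  expect_equal(unique(as.character(fp1)), "R1")
  cfgN <- simulation_config(n_realms = 9, endemics_per_realm = 0,
                            cosmopolitan_count = 2,
                            lat_range = c(0, 30), lon_range = c(0, 30),
                            grid_resolution = 10, seed = 1)
  fpN <- make_realm_footprints(cfgN)
  expect_equal(length(unique(as.character(fpN))), 9)
  expect_equal(length(fpN), 9)
  expect_error(simulation_config(n_realms = 10, lat_range = c(0, 30),
                                 lon_range = c(0, 30), grid_resolution = 10),
               "fewer cells")
})

test_that("species ranges respect realm membership and occupancy", {
  cfg <- small_cfg(occupancy_fraction = 1, cosmopolitan_min_occupancy = 1)
  fp <- make_realm_footprints(cfg)
  pools <- simulate_species_pools(cfg, fp)
  realm_cells <- split(names(fp), as.character(fp))
  for (sp in names(pools$ranges)) {
    org <- pools$origin[[sp]]
    if (grepl("^R", org)) {
      # full-occupancy endemic covers its realm exactly, nothing else
      expect_setequal(pools$ranges[[sp]], realm_cells[[org]])
    } else if (org == "cosmopolitan") {
      expect_setequal(pools$ranges[[sp]], names(fp))
    }
  }
  # error when occupancy leaves endemics with < 2 cells
  cfg_bad <- simulation_config(n_realms = 60, endemics_per_realm = 2,
                               occupancy_fraction = 0.01, grid_resolution = 10,
                               seed = 2)
  fp_bad <- make_realm_footprints(cfg_bad)
  expect_error(simulate_species_pools(cfg_bad, fp_bad), "fewer than 2")
})

test_that("gradient species straddle exactly two adjacent realms", {
  cfg <- small_cfg(gradient_species_count = 6)
  fp <- make_realm_footprints(cfg)
  pools <- simulate_species_pools(cfg, fp)
  grad <- names(pools$origin)[pools$origin == "gradient"]
  expect_length(grad, 6)
  for (sp in grad) {
    realms <- unique(as.character(fp[pools$ranges[[sp]]]))
    expect_length(realms, 2)
  }
})

test_that("detection is Bernoulli per true pair with effort-scaled probability", {
  cfg <- small_cfg(detection_prob = 1, effort_dispersion = 0)
  sim <- simulate_occurrence_dataset(cfg)
  truth_pairs <- sum(lengths(sim$truth$ranges))
  det <- attr(sim$records, "detected_pairs")
  expect_equal(nrow(det), truth_pairs)      # every pair appears at least once

  cfg0 <- small_cfg(detection_prob = 0)
  sim0 <- simulate_occurrence_dataset(cfg0)
  expect_equal(nrow(sim0$records), 0)

  # detection 0.5: recovered fraction within the binomial envelope
  cfg5 <- simulation_config(n_realms = 4, endemics_per_realm = 100,
                            cosmopolitan_count = 10, gradient_species_count = 0,
                            detection_prob = 0.5, effort_dispersion = 0, seed = 9)
  sim5 <- simulate_occurrence_dataset(cfg5)
  n_true <- sum(lengths(sim5$truth$ranges))
  expect_gt(n_true, 10000)
  frac <- nrow(attr(sim5$records, "detected_pairs")) / n_true
  half <- 3 * sqrt(0.25 / n_true)
  expect_gt(frac, 0.5 - half)
  expect_lt(frac, 0.5 + half)
})

test_that("no endemic record falls outside its realm, and names survive cleaning", {
  sim <- simulate_occurrence_dataset(small_cfg())
  g <- grid_spec(sim$config$grid_resolution)
  cells <- cell_of(sim$records$lat, sim$records$lon, g)
  org <- sim$truth$species_origin[sim$records$species]
  endemic <- grepl("^R", org)
  expect_true(all(sim$truth$cell_realm[cells[endemic]] == org[endemic]))
  # every generated name passes the cleaning filter
  out <- clean_names(sim$records)
  expect_equal(nrow(out$rejected), 0)
})

test_that("ground-truth files round-trip", {
  sim <- simulate_occurrence_dataset(small_cfg())
  paths <- write_ground_truth(sim$truth, tempfile())
  cr <- read.csv(paths[1])
  expect_equal(nrow(cr), length(sim$truth$cell_realm))
  so <- read.csv(paths[2])
  expect_setequal(so$origin, unique(as.character(sim$truth$species_origin)))
  expect_true(all(so$pelagic %in% 0:1))
})
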