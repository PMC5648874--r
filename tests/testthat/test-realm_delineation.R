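# small helper: labels over a rectangular block of cells
block_labels <- function(rows, cols, label) {
  rc <- expand.grid(row = rows, col = cols)
  stats::setNames(rep(label, nrow(rc)), cell_id(rc$row, rc$col))
}

test_that("rook adjacency wraps the antimeridian but not the poles", {
  g <- grid_spec(10)
  adj <- grid_adjacency(g)
  expect_true(cell_id(10, g$n_cols - 1) %in% adj[[cell_id(10, 0)]])
  expect_length(adj[[cell_id(g$n_rows - 1, 5)]], 3)   # top row: no pole wrap
  expect_length(adj[[cell_id(0, 5)]], 3)
  expect_length(adj[[cell_id(9, 5)]], 4)              # interior
  adjq <- grid_adjacency(g, queen = TRUE)
  expect_length(adjq[[cell_id(9, 5)]], 8)
})

test_that("components are computed per label with wrap-around connectivity", {
  g <- grid_spec(10)
  # L-shaped block of one label: one component
  lab <- c(block_labels(5, 1:3, "A"), block_labels(6, 1, "A"))
  adj <- grid_adjacency(g, cells = names(lab))
  cc <- contiguous_components(lab, adj)
  expect_equal(length(unique(cc$component)), 1)
  # two islands of one label
  lab2 <- c(block_labels(5, 1:2, "A"), block_labels(5, 10:11, "A"))
  cc2 <- contiguous_components(lab2, grid_adjacency(g, cells = names(lab2)))
  expect_equal(length(unique(cc2$component)), 2)
  # block straddling the antimeridian is one component
  lab3 <- block_labels(5, c(35, 0), "A")
  cc3 <- contiguous_components(lab3, grid_adjacency(g, cells = names(lab3)))
  expect_equal(length(unique(cc3$component)), 1)
})

test_that("disjoint fragments are released, largest component keeps the label", {
  g <- grid_spec(10)
  lab <- c(block_labels(5:6, 1:4, "A"),        # 8 cells
           block_labels(10, 10:11, "A"),       # 2-cell fragment
           block_labels(8, 1:4, "B"))
  adj <- grid_adjacency(g, cells = names(lab))
  out <- drop_disjoint_fragments(lab, adj)
  expect_true(all(is.na(out[names(block_labels(10, 10:11, "A"))])))
  expect_true(all(out[names(block_labels(5:6, 1:4, "A"))] == "A"))
  expect_true(all(out[names(block_labels(8, 1:4, "B"))] == "B"))
  # tie on size: the component holding the smallest cell id wins
  lab2 <- c(block_labels(2, 1:3, "C"), block_labels(9, 8:10, "C"))
  out2 <- drop_disjoint_fragments(lab2, grid_adjacency(g, cells = names(lab2)))
  expect_true(all(out2[names(block_labels(2, 1:3, "C"))] == "C"))   # holds r2c1
  expect_true(all(is.na(out2[names(block_labels(9, 8:10, "C"))])))
})

test_that("small enclaves are absorbed; the boundary case is retained", {
  g <- grid_spec(10)
  # a 5 x 5 block of A with a 2-cell island of B inside
  world <- block_labels(5:9, 5:9, "A")
  world[cell_id(7, c(6, 7))] <- "B"
  adj <- grid_adjacency(g, cells = names(world))
  out <- absorb_small_enclaves(world, adj, min_cells = 4)
  expect_true(all(out == "A"))
  # a 4-cell island survives: the rule is strictly "fewer than four"
  world4 <- block_labels(4:9, 4:9, "A")
  world4[cell_id(6:7, c(6, 6, 7, 7))] <- "B"
  out4 <- absorb_small_enclaves(world4, grid_adjacency(g, cells = names(world4)),
                                min_cells = 4)
  expect_equal(sum(out4 == "B"), 4)
  # idempotence
  out4b <- absorb_small_enclaves(out4, grid_adjacency(g, cells = names(world4)),
                                 min_cells = 4)
  expect_equal(unname(out4b[names(out4)]), unname(out4[names(out4)]))
})

test_that("unassigned fragments go to the label with the longest shared boundary", {
  g <- grid_spec(10)
  world <- c(block_labels(5:6, 1:6, "A"), block_labels(7, 1:6, "B"))
  world[cell_id(6, 2:4)] <- NA           # 3-cell hole: 3 edges to A above+sides, 3 below to B?
  adj <- grid_adjacency(g, cells = names(world))
  out <- absorb_small_enclaves(world, adj, min_cells = 4)
  expect_true(all(!is.na(out)))
  # boundary: A touches the hole on north+west+east (5 edges), B south (3)
  expect_true(all(out[cell_id(6, 2:4)] == "A"))
})

test_that("a small isolated group bordering two realms is kept as its own realm", {
  g <- grid_spec(10)
  world <- c(block_labels(5, 1:5, "A"), block_labels(7, 1:5, "B"),
             block_labels(6, 1:5, "C"))
  world[cell_id(6, 2:3)] <- "D"          # tiny sea wedged between A and B... via C
  adj <- grid_adjacency(g, cells = names(world))
  out <- absorb_small_enclaves(world, adj, min_cells = 4)
  expect_equal(sum(out == "D"), 2)       # whole cluster group, 2 borders: retained
})

test_that("delineation recovers a planted two-realm world exactly", {
  cfg <- simulation_config(n_realms = 2, endemics_per_realm = 80,
                           cosmopolitan_count = 6, gradient_species_count = 0,
                           seed = 11)
  sim <- simulate_occurrence_dataset(cfg)
  m <- build_presence_matrix(sim$records, grid_spec(10))
  fit <- delineate_realms(m, grid_spec(10), seed = 2)
  part <- realm_partition(fit, depth = 1)
  expect_equal(length(unique(part)), 2)
  cmp <- compare_partitions(part, sim$truth$cell_realm)
  expect_gte(cmp$ari, 0.9)
})

test_that("an exchangeable world yields a single realm under the SIMPROF gate", {
  set.seed(21)
  g <- grid_spec(10)
  pool <- sprintf("Aus %s%s", letters[(0:199) %/% 26 + 1], letters[(0:199) %% 26 + 1])
  rc <- expand.grid(row = 6:9, col = 1:5)
  sets <- lapply(seq_len(nrow(rc)), function(i) sample(pool, 30))
  names(sets) <- cell_id(rc$row, rc$col)
  m <- presence_from_sets(sets)
  fit <- delineate_realms(m, g, seed = 5)
  expect_equal(length(unique(fit$cell_realm)), 1)
})

test_that("the hierarchy is a tree and realms stay contiguous", {
  w <- toy_world()
  fit <- delineate_realms(w$matrix, w$grid, seed = 4)
  h <- fit$hierarchy
  # every child's cells are a subset of its parent's
  for (i in which(!is.na(h$parent))) {
    kid <- fit$realm_cells[[h$realm[i]]]
    par <- fit$realm_cells[[h$parent[i]]]
    expect_true(all(kid %in% par))
  }
  # every leaf realm is one connected component
  part <- realm_partition(fit)
  adj <- grid_adjacency(w$grid, cells = names(part))
  cc <- contiguous_components(part, adj)
  n_comp <- tapply(cc$component, cc$label, function(x) length(unique(x)))
  expect_true(all(n_comp == 1))
  # a single-threshold run has depth one
  fit1 <- delineate_realms(w$matrix, w$grid, thresholds = 6, seed = 4)
  expect_true(all(is.na(fit1$hierarchy$parent) |
                    fit1$hierarchy$parent == "1"))
})

test_that("widespread-species overlay is identical at fraction 1 and coarser otherwise", {
  w <- toy_world()
  full <- delineate_realms(w$matrix, w$grid, seed = 9)
  all_sp <- pelagic_realm_overlay(w$matrix, w$grid, widespread_fraction = 1,
                                  seed = 9)
  expect_equal(realm_partition(all_sp), realm_partition(full))
  ov <- suppressMessages(pelagic_realm_overlay(w$matrix, w$grid,
                                               widespread_fraction = 0.10,
                                               seed = 9))
  expect_lte(length(unique(realm_partition(ov))),
             length(unique(realm_partition(full))))
})

test_that("realm maps export as valid GeoJSON cell polygons", {
  w <- toy_world()
  fit <- delineate_realms(w$matrix, w$grid, thresholds = 6, seed = 1)
  f <- tempfile(fileext = ".geojson")
  realms_to_geojson(realm_partition(fit), w$grid, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features),
               length(unique(realm_partition(fit))))
  ring <- gj$features[[1]]$geometry$coordinates[[1]][[1]]
  expect_equal(ring[[1]], ring[[length(ring)]])   # closed ring
})
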