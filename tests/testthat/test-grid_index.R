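test_that("coordinates bin into half-open cells with stated boundary conventions", {
  g5 <- grid_spec(5)
  expect_equal(cell_of(0, 0, g5), "r18c36")
  expect_equal(cell_of(-90, -180, g5), "r0c0")
  expect_equal(cell_of(90, 180, g5), "r35c0")   # lat 90 clamped, lon 180 wraps
  expect_equal(cell_of(89.999, 179.999, g5), "r35c71")
  expect_true(is.na(cell_of(NaN, 0, g5)))
  expect_true(is.na(cell_of(95, 0, g5)))
})

test_that("cell_of inverts lower-left corner plus interior offset at any resolution", {
  set.seed(7)
  for (res in c(10, 5, 1)) {
    g <- grid_spec(res)
    ids <- cell_id <- cell_of(runif(200, -90, 90), runif(200, -360, 360), g)
    rc <- cell_rowcol(ids)
    off <- runif(200, 0, res * 0.999)
    back <- cell_of(rc$row * res - 90 + off, rc$col * res - 180 + off, g)
    expect_equal(back, ids)
  }
})

test_that("cell labels read as lower-left corner coordinates", {
  g5 <- grid_spec(5)
  expect_equal(cell_label(cell_of(52, -7.3, g5), g5), "50N_10W")
  expect_equal(cell_label("r18c36", g5), "0N_0E")
})

test_that("incomplete species names are rejected with reasons", {
  r <- data.frame(species = c("Calanus finmarchicus", "Calanus sp.",
                              "Calanus spp.", "Calanus a", "Diatoms",
                              "Calanus cf. finmarchicus", "Species 12",
                              "Mus musculus domesticus"))
  out <- clean_names(r)
  expect_setequal(out$kept$species,
                  c("Calanus finmarchicus", "Mus musculus domesticus"))
  expect_equal(out$report$sp_qualifier, 2)
  expect_equal(out$report$single_letter_epithet, 1)
  expect_equal(out$report$single_word, 1)
  expect_equal(out$report$cf_aff_qualifier, 1)
  expect_equal(out$report$contains_digits, 1)
})

test_that("presence matrix deduplicates, filters, and is idempotent under duplication", {
  g <- grid_spec(5)
  rec <- data.frame(species = c(rep("Aus bus", 3), "Cus dus"),
                    lat = c(1, 1, 7, 1), lon = c(1, 1.4, 1, 12))
  m <- build_presence_matrix(rec, g)
  expect_equal(dim(m), c(2L, 3L))
  # two records in one cell collapse to a single entry
  expect_equal(sum(m["Aus bus", ]), 2)
  m2 <- build_presence_matrix(rbind(rec, rec), g)
  expect_equal(as.matrix(m2), as.matrix(m))

  expect_error(build_presence_matrix(rec, g, excluded_cells = colnames(m)),
               "empty")
  m3 <- build_presence_matrix(rec, g, min_cells_per_species = 2)
  expect_error(print(m3), NA)  # single row survives
  expect_false("Cus dus" %in% rownames(m3))
})

test_that("default exclusion preset flags the anomalous cells", {
  ex <- default_cell_exclusions(grid_spec(5))
  expect_true(cell_of(0, 0, grid_spec(5)) %in% ex)
  expect_length(ex, 4)
})

test_that("region aggregation is binary and label-driven", {
  m <- presence_from_sets(list(c1 = c("Aus bus", "Cus dus"),
                               c2 = c("Eus fus"),
                               c3 = c("Aus bus", "Eus fus")))
  mp <- c(c1 = "North", c2 = "North", c3 = "South")
  agg <- aggregate_to_regions(m, mp)
  expect_equal(sort(colnames(agg)), c("North", "South"))
  expect_equal(Matrix::colSums(agg)[["North"]], 3)   # disjoint cells: sum
  expect_equal(max(agg), 1)
  # identity mapping returns the same incidence
  idm <- stats::setNames(colnames(m), colnames(m))
  expect_equal(as.matrix(aggregate_to_regions(m, idm))[rownames(m), colnames(m)],
               as.matrix(m))
  # shared species across merged cells stays a single binary entry
  m2 <- presence_from_sets(list(c1 = "Aus bus", c2 = "Aus bus"))
  agg2 <- aggregate_to_regions(m2, c(c1 = "R", c2 = "R"))
  expect_equal(as.numeric(agg2["Aus bus", "R"]), 1)
  expect_error(aggregate_to_regions(m, character()), "empty")
})

test_that("genus aggregation uses binomial fallback and never increases richness", {
  m <- presence_from_sets(list(c1 = c("Calanus finmarchicus", "Calanus glacialis",
                                      "Metridia longa"),
                               c2 = c("Calanus glacialis")))
  g <- aggregate_by_rank(m)
  expect_equal(sort(rownames(g)), c("Calanus", "Metridia"))
  expect_equal(as.numeric(g["Calanus", "c1"]), 1)
  expect_true(all(Matrix::colSums(g) <= Matrix::colSums(m)))
  # all-monotypic genera: structure preserved
  m2 <- presence_from_sets(list(c1 = c("Aus bus", "Cus dus"), c2 = "Cus dus"))
  g2 <- aggregate_by_rank(m2)
  expect_equal(unname(as.matrix(g2)), unname(as.matrix(m2)))
})

test_that("aggregation commutes with species-subset filtering", {
  w <- toy_world()
  m <- w$matrix[1:80, 1:30]
  m <- m[Matrix::rowSums(m) > 0, Matrix::colSums(m) > 0]
  keep <- rownames(m)[seq(1, nrow(m), by = 2)]
  mp <- stats::setNames(rep(c("A", "B"), length.out = ncol(m)), colnames(m))
  a <- aggregate_to_regions(m[keep, , drop = FALSE], mp)
  b <- aggregate_to_regions(m, mp)
  b <- b[intersect(rownames(b), keep), , drop = FALSE]
  common <- intersect(rownames(a), rownames(b))
  expect_equal(as.matrix(a[common, colnames(b)]), as.matrix(b[common, ]))
})

test_that("occurrence files round-trip through the reader and writer", {
  w <- toy_world()
  rec <- head(w$sim$records, 50)
  f <- tempfile(fileext = ".csv")
  write_occurrences(rec, f)
  back <- read_occurrences(f)
  expect_equal(back$species, rec$species)
  expect_equal(back$lat, rec$lat, tolerance = 1e-12)
  expect_equal(as.integer(back$pelagic), rec$pelagic)
})
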