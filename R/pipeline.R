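#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (max - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param x,y Label vectors over the same items (same length/order).
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(x, y) {
  if (length(x) != length(y)) stop("labelings differ in length", call. = FALSE)
  n <- length(x)
  if (n == 0) stop("empty labelings", call. = FALSE)
  tab <- base::table(x, y)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_ij <- ch2(as.vector(tab))
  a <- ch2(rowSums(tab)); b <- ch2(colSums(tab))
  tot <- n * (n - 1) / 2
  expected <- a * b / tot
  denom <- (a + b) / 2 - expected
  if (denom == 0) return(1)      # both partitions trivial and identical in structure
  (sum_ij - expected) / denom
}

#' Compare two cell partitions
#'
#' Computes the adjusted Rand index over the common cell set and a
#' best-overlap table matching each realm of the first partition to the
#' realm of the second it shares most cells with.
#'
#' @param p1,p2 Named vectors cell -> label (`NA` cells dropped).
#' @return List with `ari`, `n_cells` (size of the common set), and
#'   `best_overlap` (data.frame `realm1`, `realm2`, `n_shared`,
#'   `frac_of_realm1`).
#' @export
compare_partitions <- function(p1, p2) {
  common <- intersect(names(p1)[!is.na(p1)], names(p2)[!is.na(p2)])
  if (!length(common)) stop("partitions share no cells", call. = FALSE)
  dropped <- length(union(names(p1), names(p2))) - length(common)
  if (dropped > 0)
    message(dropped, " cell(s) outside the common set ignored")
  a <- as.character(p1[common]); b <- as.character(p2[common])
  tab <- base::table(a, b)
  best <- apply(tab, 1, which.max)
  bo <- data.frame(realm1 = rownames(tab),
                   realm2 = colnames(tab)[best],
                   n_shared = tab[cbind(seq_len(nrow(tab)), best)],
                   stringsAsFactors = FALSE)
  bo$frac_of_realm1 <- bo$n_shared / rowSums(tab)
  rownames(bo) <- NULL
  list(ari = adjusted_rand_index(a, b), n_cells = length(common),
       best_overlap = bo)
}

#' Configuration for a full pipeline run
#'
#' @param input Path to an occurrence file ([read_occurrences()] format),
#'   or a data.frame of records, or a full synthetic dataset from
#'   [simulate_occurrence_dataset()] (its ground truth is then compared
#'   automatically).
#' @param output_dir Directory for all artifacts.
#' @param grid_resolution Cell size in degrees.
#' @param index Dissimilarity index.
#' @param thresholds Percent-similarity delimitation levels.
#' @param simprof_permutations,simprof_alpha,simprof_max_cells SIMPROF
#'   gate settings.
#' @param bootstrap_n Bootstrap resamples for co-clustering support
#'   (0 disables the bootstrap stage).
#' @param min_enclave_cells Enclave absorption rule.
#' @param endemic_min_cells Minimum occupied cells for endemic status.
#' @param widespread_fraction Fraction of species for the widespread
#'   (pelagic-style) overlay.
#' @param excluded_cells Cell ids to exclude.
#' @param seed Integer seed for all stochastic stages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(input, output_dir,
                            grid_resolution = 5, index = "jaccard",
                            thresholds = 1:6,
                            simprof_permutations = 199, simprof_alpha = 0.05,
                            simprof_max_cells = 100,
                            bootstrap_n = 0,
                            min_enclave_cells = 4, endemic_min_cells = 2,
                            widespread_fraction = 0.10,
                            excluded_cells = character(), seed = 1) {
  index <- match.arg(index, .beta_indices)
  stopifnot(all(thresholds >= 0 & thresholds <= 100),
            simprof_permutations >= 1, simprof_alpha > 0, simprof_alpha < 1,
            bootstrap_n >= 0, min_enclave_cells >= 1, endemic_min_cells >= 1,
            widespread_fraction > 0, widespread_fraction <= 1)
  structure(list(input = input, output_dir = output_dir,
                 grid_resolution = grid_resolution, index = index,
                 thresholds = thresholds,
                 simprof_permutations = as.integer(simprof_permutations),
                 simprof_alpha = simprof_alpha,
                 simprof_max_cells = simprof_max_cells,
                 bootstrap_n = as.integer(bootstrap_n),
                 min_enclave_cells = min_enclave_cells,
                 endemic_min_cells = endemic_min_cells,
                 widespread_fraction = widespread_fraction,
                 excluded_cells = excluded_cells, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full bioregionalization pipeline
#'
#' Executes the stages in order -- clean names, grid indexing and
#' deduplication, dissimilarity, clustering, SIMPROF-gated realm
#' delineation (with contiguity filtering and enclave absorption),
#' endemicity statistics, widespread ranking, pelagic-style overlay, and
#' reports -- writing every artifact plus a JSON manifest (stage status,
#' input hashes, seed, package version) into `config$output_dir`.
#' Reruns with the same config and inputs produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`matrix`, `fit`,
#'   `endemicity`, `widespread`, `overlay`, `comparison` when ground
#'   truth was supplied, and `manifest`).
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- file.path(config$output_dir)
  spec <- grid_spec(config$grid_resolution)
  manifest <- list(package = "marinerealms",
                   version = as.character(utils::packageVersion("marinerealms")),
                   seed = config$seed, stages = list())
  t0 <- Sys.time()
  stage <- function(name, expr) {
    res <- tryCatch(force(expr), error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(stage = name, status = "complete")
    res
  }

  truth <- NULL
  records <- stage("read", {
    x <- config$input
    if (inherits(x, "character")) {
      manifest$input_md5 <- unname(tools::md5sum(x))
      read_occurrences(x)
    } else if (is.list(x) && !is.null(x$records)) {
      truth <- x$truth
      x$records
    } else as.data.frame(x)
  })
  cleaned <- stage("clean", clean_names(records))
  message(sprintf("[clean] %d records read, %d kept, %d rejected (%s)",
                  nrow(records), nrow(cleaned$kept), nrow(records) - nrow(cleaned$kept),
                  paste(names(cleaned$report), unlist(cleaned$report),
                        sep = "=", collapse = ", ")))
  m <- stage("grid", build_presence_matrix(cleaned$kept, spec,
                                           excluded_cells = config$excluded_cells))
  message(sprintf("[grid] %d species x %d cells, %d presences",
                  nrow(m), ncol(m), sum(m)))
  stage("export_matrix", write_presence_matrix(m, file.path(out, "presence")))

  fit <- stage("delineate", delineate_realms(
    m, spec, thresholds = config$thresholds, index = config$index,
    simprof_gate = TRUE, n_permutations = config$simprof_permutations,
    alpha = config$simprof_alpha, simprof_max_cells = config$simprof_max_cells,
    min_enclave_cells = config$min_enclave_cells, seed = config$seed))
  message(sprintf("[delineate] %d realms (%d leaf-level)",
                  nrow(fit$hierarchy),
                  length(unique(fit$cell_realm))))
  stage("export_dendrogram",
        write_dendrogram(fit$dendrogram, file.path(out, "dendrogram")))
  stage("export_realms", {
    part <- realm_partition(fit)
    write.csv(data.frame(cell_id = names(part), realm = part),
              file.path(out, "cell_realm.csv"), row.names = FALSE, quote = FALSE)
    jsonlite::write_json(fit$hierarchy, file.path(out, "hierarchy.json"),
                         dataframe = "rows", na = "null", auto_unbox = TRUE)
    realms_to_geojson(part, spec, file.path(out, "realms.geojson"))
  })

  endem <- stage("endemicity", {
    tab <- unique_species_per_realm(m, realm_partition(fit),
                                    min_cells = config$endemic_min_cells)
    write.csv(as.data.frame(tab), file.path(out, "endemicity.csv"),
              row.names = FALSE, quote = FALSE)
    tab
  })
  wr <- stage("widespread", {
    w <- widespread_ranking(m, top_fraction = config$widespread_fraction)
    write.csv(w, file.path(out, "widespread.csv"), row.names = FALSE, quote = FALSE)
    w
  })
  overlay <- stage("overlay", pelagic_realm_overlay(
    m, spec, widespread_fraction = config$widespread_fraction,
    thresholds = config$thresholds, index = config$index,
    n_permutations = config$simprof_permutations, alpha = config$simprof_alpha,
    simprof_max_cells = config$simprof_max_cells,
    min_enclave_cells = config$min_enclave_cells, seed = config$seed + 1L))

  boot <- NULL
  if (config$bootstrap_n > 0)
    boot <- stage("bootstrap", bootstrap_support(
      m, index = config$index, s = config$thresholds[1],
      n_boot = config$bootstrap_n, seed = config$seed + 2L))

  comparison <- NULL
  if (!is.null(truth)) {
    comparison <- stage("compare_truth",
                        compare_partitions(realm_partition(fit), truth$cell_realm))
    message(sprintf("[compare_truth] adjusted Rand index vs planted realms: %.3f",
                    comparison$ari))
  }

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary_json <- list(
    n_species = nrow(m), n_cells = ncol(m),
    n_realms = nrow(fit$hierarchy),
    n_leaf_realms = length(unique(fit$cell_realm)),
    mean_pct_endemicity = mean(endem$pct_endemicity, na.rm = TRUE),
    overlay_n_leaf_realms = length(unique(overlay$cell_realm)),
    ari_vs_planted = if (is.null(comparison)) NULL else comparison$ari)
  jsonlite::write_json(summary_json, file.path(out, "summary.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(matrix = m, fit = fit, endemicity = endem, widespread = wr,
                 overlay = overlay, bootstrap = boot, comparison = comparison,
                 manifest = manifest))
}
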