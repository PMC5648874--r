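.index_code <- function(index) {
  switch(match.arg(index, .beta_indices),
         jaccard = 0L, sorensen = 1L, braycurtis_binary = 1L, betasim = 2L)
}

#' SIMPROF: similarity-profile permutation test over a dendrogram
#'
#' Tests, top-down from the root, whether the samples under each internal
#' node show more multivariate structure than expected if species were
#' distributed independently of the samples. The statistic is
#' \eqn{\pi = \sum_k |s_{(k)} - \bar s_{(k)}|}, comparing the ordered
#' pairwise similarities among the node's leaves with the mean ordered
#' profile over permutations in which each species' presences are shuffled
#' independently across the node's leaves. The p-value uses the add-one
#' estimator \eqn{(1 + \#\{\pi^* \ge \pi\})/(1 + B)}. Descent stops below
#' non-significant nodes (their subtrees are homogeneous); nodes with
#' fewer than 3 leaves are untestable and marked homogeneous.
#'
#' @param matrix Species-by-cell presence matrix; columns must be the
#'   dendrogram's leaves.
#' @param dendrogram A [upgma()] tree over the matrix columns.
#' @param n_permutations Permutations per node (for both the mean-profile
#'   and the null-distribution pass).
#' @param alpha Significance level for the descent.
#' @param seed Optional integer seed for reproducibility.
#' @param index Similarity index used for the profiles.
#' @param bonferroni If `TRUE`, alpha is divided by the number of testable
#'   nodes (conservative); default is the standard sequential unadjusted
#'   test.
#' @return An object of class `simprof_result`: a data.frame with one row
#'   per internal node (`node`, `n_leaves`, `tested`, `pi`, `p_value`,
#'   `significant`, `homogeneous`) plus `alpha` and `n_permutations`
#'   attributes. Node numbers follow the dendrogram's merge order (the
#'   root is the last node).
#' @export
simprof <- function(matrix, dendrogram, n_permutations = 999, alpha = 0.05,
                    seed = NULL, index = "jaccard", bonferroni = FALSE) {
  stopifnot(inherits(dendrogram, "hclust"))
  if (!identical(sort(colnames(matrix)), sort(dendrogram$labels)))
    stop("matrix columns and dendrogram leaves differ", call. = FALSE)
  icode <- .index_code(index)
  members <- .node_members(dendrogram$merge)
  n_nodes <- length(members)
  testable <- vapply(members, length, 1L) >= 3L
  alpha_eff <- if (bonferroni) alpha / max(1L, sum(testable)) else alpha
  X <- as.matrix(matrix[, dendrogram$labels, drop = FALSE]) * 1L

  res <- data.frame(node = seq_len(n_nodes),
                    n_leaves = vapply(members, length, 1L),
                    tested = FALSE, pi = NA_real_, p_value = NA_real_,
                    significant = FALSE, homogeneous = !testable)
  with_seed(seed, {
    # top-down: start at the root (last merge), descend into significant nodes
    stack <- n_nodes
    while (length(stack)) {
      node <- stack[[1]]; stack <- stack[-1]
      if (!testable[node]) { res$homogeneous[node] <- TRUE; next }
      sub <- X[, members[[node]], drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      out <- simprof_core(sub, n_permutations, icode)
      res$tested[node] <- TRUE
      res$pi[node] <- out$pi
      res$p_value[node] <- out$p_value
      if (out$p_value <= alpha_eff) {
        res$significant[node] <- TRUE
        for (child in dendrogram$merge[node, ])
          if (child > 0) stack <- c(stack, child)
      } else {
        res$homogeneous[node] <- TRUE
      }
    }
  })
  structure(res, alpha = alpha, n_permutations = n_permutations,
            index = match.arg(index, .beta_indices),
            class = c("simprof_result", "data.frame"))
}

#' @export
print.simprof_result <- function(x, ...) {
  cat(sprintf("SIMPROF: %d nodes, %d tested, %d significant (alpha = %g, %d permutations)\n",
              nrow(x), sum(x$tested), sum(x$significant),
              attr(x, "alpha"), attr(x, "n_permutations")))
  print.data.frame(head(x[x$tested, ], 20))
  invisible(x)
}

#' SIMPROF test of a single group of cells
#'
#' The scalar form of [simprof()]: does this one set of samples contain
#' multivariate structure? Used as the gate deciding whether a realm may
#' be subdivided further. Large groups can be tested on a random
#' subsample of cells (`max_cells`) since the test's power saturates well
#' below 100 samples.
#'
#' @param matrix Species-by-cell presence matrix for the group.
#' @param n_permutations,index As in [simprof()].
#' @param max_cells Test at most this many cells (random subsample);
#'   `Inf` to disable.
#' @param seed Optional seed.
#' @return List with `pi`, `p_value`, `n_cells` (cells actually tested).
#' @export
simprof_test <- function(matrix, n_permutations = 999, index = "jaccard",
                         max_cells = 100, seed = NULL) {
  icode <- .index_code(index)
  with_seed(seed, {
    m <- matrix
    if (ncol(m) > max_cells)
      m <- m[, sort(sample.int(ncol(m), max_cells)), drop = FALSE]
    X <- as.matrix(m) * 1L
    X <- X[rowSums(X) > 0, , drop = FALSE]
    if (ncol(m) < 3 || nrow(X) == 0) {
      list(pi = 0, p_value = 1, n_cells = ncol(m))
    } else {
      core <- simprof_core(X, n_permutations, icode)
      list(pi = core$pi, p_value = core$p_value, n_cells = ncol(m))
    }
  })
}
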