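#' ANOSIM: analysis of similarities between predefined groups
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities. With mid-ranks `r` of all
#' `M = n(n-1)/2` pairwise dissimilarities,
#' `R = (mean(r_between) - mean(r_within)) / (M / 2)`,
#' so `R` is 1 when every between-group pair is more dissimilar than every
#' within-group pair, and near 0 when grouping is random. Because `R`
#' depends only on ranks it is invariant to any strictly monotone
#' transform of the dissimilarities. Significance is assessed by randomly
#' permuting the group labels.
#'
#' @param d A `dist` of dissimilarities.
#' @param groups Group labels, one per sample (in `d`'s label order), or
#'   a named vector matching `d`'s labels.
#' @param n_permutations Number of label permutations.
#' @param seed Optional integer seed.
#' @return Object of class `anosim_result`: list with `R`, `p_value`,
#'   `n_permutations`, `group_sizes`, `permuted_R`.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL) {
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(groups)) && !is.null(labs)) {
    if (!all(labs %in% names(groups)))
      stop("`groups` names do not cover the dissimilarity labels", call. = FALSE)
    groups <- groups[labs]
  }
  groups <- as.character(groups)
  if (length(groups) != n) stop("one group label per sample required", call. = FALSE)
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2)) stop("every group needs at least 2 members", call. = FALSE)

  r <- rank(as.vector(d))                       # mid-ranks for ties
  M <- n * (n - 1) / 2
  ij <- which(lower.tri(matrix(0L, n, n)), arr.ind = TRUE)  # dist ordering
  stat <- function(g) {
    between <- g[ij[, 1]] != g[ij[, 2]]
    (mean(r[between]) - mean(r[!between])) / (M / 2)
  }
  R <- stat(groups)
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(k) stat(sample(groups)), 0.0)
  })
  p <- (1 + sum(perm >= R)) / (1 + n_permutations)
  structure(list(R = R, p_value = p, n_permutations = n_permutations,
                 group_sizes = as.integer(sizes), permuted_R = perm),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.3f, p = %.4g (%d permutations; group sizes %s)\n",
              x$R, x$p_value, x$n_permutations,
              paste(x$group_sizes, collapse = ", ")))
  invisible(x)
}

#' Bootstrap co-clustering support for leaf pairs
#'
#' Resamples species (matrix rows) with replacement, recomputes the
#' dissimilarity matrix, re-clusters, cuts at `s` percent similarity, and
#' records how often each pair of cells falls in the same group. Cells
#' left with no species in a resample have their pairs marked missing for
#' that replicate.
#'
#' @param matrix Species-by-cell presence matrix (3+ cells).
#' @param index Dissimilarity index.
#' @param s Percent-similarity cut level.
#' @param n_boot Number of resamples.
#' @param seed Optional integer seed.
#' @return List with `support` (percent co-clustering per pair, diagonal
#'   100) and `n_replicates` (valid replicates per pair).
#' @export
bootstrap_support <- function(matrix, index = "jaccard", s, n_boot = 1000,
                              seed = NULL) {
  n <- ncol(matrix)
  if (n < 3) stop("need at least 3 cells", call. = FALSE)
  cells <- colnames(matrix)
  co <- matrix(0, n, n, dimnames = list(cells, cells))
  cnt <- matrix(0, n, n, dimnames = list(cells, cells))
  dropped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      rows <- sample.int(nrow(matrix), nrow(matrix), replace = TRUE)
      m <- matrix[rows, , drop = FALSE]
      occ <- Matrix::colSums(m) > 0
      if (!all(occ)) dropped <- dropped + sum(!occ)
      m <- m[, occ, drop = FALSE]
      if (ncol(m) < 2) next
      grp <- cut_at_similarity(upgma(pairwise_dissimilarity(m, index)), s)
      idx <- match(names(grp), cells)
      same <- outer(grp, grp, "==")
      co[idx, idx] <- co[idx, idx] + same
      cnt[idx, idx] <- cnt[idx, idx] + 1
    }
  })
  if (dropped > 0)
    message(dropped, " empty-cell instances across resamples were marked missing")
  support <- ifelse(cnt > 0, 100 * co / cnt, NA_real_)
  diag(support) <- 100
  list(support = support, n_replicates = cnt)
}
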