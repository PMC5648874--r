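#' Group-average (UPGMA) agglomerative clustering
#'
#' Clusters samples from a dissimilarity matrix by unweighted pair-group
#' average linkage: the height at which two clusters merge is the
#' arithmetic mean of all between-cluster pairwise dissimilarities.
#' Group-average linkage is preferred over single or complete linkage for
#' occurrence data because it is less sensitive to individual
#' well- or poorly-sampled cells. Ties in the minimum merge height are
#' broken deterministically by the lexicographically smallest
#' (left-label, right-label) pair.
#'
#' @param d A `dist` object (e.g. from [pairwise_dissimilarity()]) or a
#'   symmetric matrix with labels.
#' @return An object of class `c("realm_dendrogram", "hclust")`; standard
#'   `hclust` tooling (`plot`, `cophenetic`, `cutree`) applies.
#' @examples
#' d <- as.dist(matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3,
#'                     dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
#' h <- upgma(d)
#' h$height  # 0.2, then (0.6 + 0.8) / 2 = 0.7
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop("`d` must be square", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite values in dissimilarity matrix", call. = FALSE)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  res <- upgma_cpp(m, labels)
  out <- list(merge = res$merge, height = as.numeric(res$height),
              order = .leaf_order(res$merge), labels = labels,
              method = "average",
              dist.method = attr(d, "index") %||% attr(d, "method"),
              call = match.call())
  class(out) <- c("realm_dendrogram", "hclust")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# left-to-right leaf ordering of an hclust merge matrix
.leaf_order <- function(merge) {
  rec <- vector("list", nrow(merge))
  get <- function(k) if (k < 0) -k else rec[[k]]
  for (i in seq_len(nrow(merge)))
    rec[[i]] <- c(get(merge[i, 1]), get(merge[i, 2]))
  rec[[nrow(merge)]]
}

# leaf index members of every internal node
.node_members <- function(merge) {
  rec <- vector("list", nrow(merge))
  get <- function(k) if (k < 0) -k else rec[[k]]
  for (i in seq_len(nrow(merge)))
    rec[[i]] <- c(get(merge[i, 1]), get(merge[i, 2]))
  rec
}

#' Cut a dendrogram at a percent-similarity threshold
#'
#' Cuts at dissimilarity `1 - s/100`. Two leaves share a group label iff
#' their merge height is strictly below the cut, so at `s = 0` completely
#' disjoint cells (merge height exactly 1) remain separate, and at
#' `s = 100` every leaf is its own group. Groups are numbered by
#' first-seen leaf order.
#'
#' @param dendrogram A [upgma()] tree.
#' @param s Percent similarity in `[0, 100]`.
#' @return Named integer vector: leaf label -> group number.
#' @export
cut_at_similarity <- function(dendrogram, s) {
  stopifnot(inherits(dendrogram, "hclust"), s >= 0, s <= 100)
  cut <- similarity_to_dissim(s)
  n <- length(dendrogram$labels)
  uf <- seq_len(n)
  find <- function(x) { while (uf[x] != x) x <- uf[x]; x }
  merge <- dendrogram$merge; height <- dendrogram$height
  reps <- integer(nrow(merge))           # representative leaf per internal node
  for (i in seq_len(nrow(merge))) {
    l <- merge[i, 1]; r <- merge[i, 2]
    lr <- if (l < 0) -l else reps[l]
    rr <- if (r < 0) -r else reps[r]
    reps[i] <- lr
    if (height[i] < cut) uf[find(rr)] <- find(lr)
  }
  root <- vapply(seq_len(n), find, 1L)
  grp <- match(root, unique(root))
  names(grp) <- dendrogram$labels
  grp
}

#' Export a dendrogram as Newick and as a merge table
#'
#' @param dendrogram A [upgma()] tree.
#' @param prefix Output path prefix; writes `<prefix>.nwk` (branch lengths
#'   from merge-height differences) and `<prefix>.merges.csv`.
#' @return Invisibly, the paths written.
#' @export
write_dendrogram <- function(dendrogram, prefix) {
  paths <- paste0(prefix, c(".nwk", ".merges.csv"))
  phy <- ape::as.phylo(stats::as.hclust(dendrogram))
  ape::write.tree(phy, paths[1])
  mt <- data.frame(node = seq_along(dendrogram$height),
                   left = dendrogram$merge[, 1],
                   right = dendrogram$merge[, 2],
                   height = dendrogram$height)
  write.csv(mt, paths[2], row.names = FALSE)
  invisible(paths)
}
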