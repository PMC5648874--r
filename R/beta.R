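#' Shared and unique species counts for a pair of samples
#'
#' The building blocks of presence-absence beta diversity: `a` species
#' shared by both samples, `b` unique to the first, `c` unique to the
#' second. Joint absences are never counted, so similarity between two
#' samples does not depend on what occurs elsewhere.
#'
#' @param col_i,col_j Logical/binary vectors over a common species axis,
#'   or two column names/indices together with `matrix`.
#' @param matrix Optional species-by-sample presence matrix from which to
#'   take the two columns.
#' @return Named list with integer `a`, `b`, `c`.
#' @examples
#' pair_counts(c(1, 1, 1, 0), c(0, 1, 1, 1))  # a = 2, b = 1, c = 1
#' @export
pair_counts <- function(col_i, col_j, matrix = NULL) {
  if (!is.null(matrix)) {
    col_i <- as.logical(matrix[, col_i])
    col_j <- as.logical(matrix[, col_j])
  }
  col_i <- as.logical(col_i); col_j <- as.logical(col_j)
  if (length(col_i) != length(col_j))
    stop("columns must share the same species axis", call. = FALSE)
  list(a = sum(col_i & col_j),
       b = sum(col_i & !col_j),
       c = sum(!col_i & col_j))
}

.beta_indices <- c("jaccard", "sorensen", "betasim", "braycurtis_binary")

#' Presence-absence dissimilarity from pair counts
#'
#' Implemented indices (all on a 0-1 dissimilarity scale):
#' \describe{
#'   \item{jaccard}{`1 - a / (a + b + c)`; the similarity form
#'     `100 a / (a + b + c)` is the percent shown to users.}
#'   \item{sorensen}{`1 - 2a / (2a + b + c)`.}
#'   \item{betasim}{`min(b, c) / (a + min(b, c))`; pure turnover,
#'     blind to nestedness and richness differences.}
#'   \item{braycurtis_binary}{Bray-Curtis on presence-absence data,
#'     identical to the Sorensen dissimilarity.}
#' }
#'
#' @param counts A list with `a`, `b`, `c` as from [pair_counts()].
#' @param index One of `"jaccard"`, `"sorensen"`, `"betasim"`,
#'   `"braycurtis_binary"`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
dissimilarity <- function(counts, index = "jaccard") {
  index <- match.arg(index, .beta_indices)
  a <- counts$a; b <- counts$b; cc <- counts$c
  if (a + b + cc == 0)
    stop("undefined pair: both samples are empty", call. = FALSE)
  switch(index,
         jaccard = 1 - a / (a + b + cc),
         sorensen = ,
         braycurtis_binary = 1 - 2 * a / (2 * a + b + cc),
         betasim = {
           m <- min(b, cc)
           if (a + m == 0) 0 else m / (a + m)
         })
}

#' Pairwise dissimilarity matrix among cells or regions
#'
#' Computes all pairwise presence-absence dissimilarities between the
#' columns (samples) of a presence matrix via sparse cross-products;
#' counts are exact.
#'
#' @param matrix Species-by-sample presence matrix (see
#'   [build_presence_matrix()]); at least two columns, none empty.
#' @param index Dissimilarity index, see [dissimilarity()].
#' @return A [stats::dist] object with `Labels` from the matrix columns
#'   and an `index` attribute.
#' @export
pairwise_dissimilarity <- function(matrix, index = "jaccard") {
  index <- match.arg(index, .beta_indices)
  if (ncol(matrix) < 2) stop("need at least 2 samples", call. = FALSE)
  rich <- Matrix::colSums(matrix)
  if (any(rich == 0))
    stop("empty sample column(s): ",
         paste(head(colnames(matrix)[rich == 0], 5), collapse = ", "),
         call. = FALSE)
  a <- as.matrix(Matrix::crossprod(matrix * 1))   # shared species counts
  b <- rich - a                                   # b[i,j] = rich[i] - a[i,j]
  cc <- t(b)
  d <- switch(index,
              jaccard = 1 - a / (a + b + cc),
              sorensen = ,
              braycurtis_binary = 1 - 2 * a / (2 * a + b + cc),
              betasim = {
                m <- pmin(b, cc)
                ifelse(a + m == 0, 0, m / (a + m))
              })
  diag(d) <- 0
  out <- as.dist(d)
  attr(out, "index") <- index
  out
}

#' Convert between percent similarity and dissimilarity
#'
#' Thresholds are quoted as "percent similarity" (e.g. realms delimited
#' at 1-6% similarity); internally everything is dissimilarity on
#' `[0, 1]`: `dissim = 1 - s / 100`.
#'
#' @param s Percent similarity in `[0, 100]`.
#' @return Dissimilarity in `[0, 1]`.
#' @export
similarity_to_dissim <- function(s) {
  stopifnot(all(s >= 0 & s <= 100))
  1 - s / 100
}

#' Export a dissimilarity matrix as labeled CSV
#'
#' Writes the full square form with labels, plus the condensed vector and
#' a sidecar label file.
#'
#' @param d A `dist` from [pairwise_dissimilarity()].
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_dissimilarity <- function(d, prefix) {
  m <- as.matrix(d)
  paths <- paste0(prefix, c(".square.csv", ".condensed.txt", ".labels.txt"))
  write.csv(data.frame(id = rownames(m), m, check.names = FALSE), paths[1],
            row.names = FALSE, quote = FALSE)
  writeLines(format(as.vector(d), digits = 15), paths[2])
  writeLines(attr(d, "Labels"), paths[3])
  invisible(paths)
}
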