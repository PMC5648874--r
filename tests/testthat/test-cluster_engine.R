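dist3 <- function(ab, ac, bc) {
  as.dist(matrix(c(0, ab, ac, ab, 0, bc, ac, bc, 0), 3,
                 dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
}

test_that("group-average heights follow the merge arithmetic", {
  d2 <- as.dist(matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), NULL)))
  h2 <- upgma(d2)
  expect_equal(h2$height, 0.4)

  h3 <- upgma(dist3(0.2, 0.6, 0.8))
  expect_equal(h3$height, c(0.2, 0.7))        # (0.6 + 0.8) / 2
  expect_s3_class(h3, "hclust")
})

test_that("heights match the brute-force agglomeration oracle on small instances", {
  set.seed(99)
  for (rep in 1:60) {
    n <- sample(3:7, 1)
    m <- matrix(0, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
    v <- runif(n * (n - 1) / 2)
    if (rep %% 5 == 0) v <- round(v, 1)       # force ties
    m[lower.tri(m)] <- v
    m <- m + t(m)
    fit <- upgma(as.dist(m))
    expect_equal(fit$height, oracle_upgma_heights(as.dist(m)), tolerance = 1e-12)
  }
})

test_that("heights agree with stats::hclust average linkage on tie-free data", {
  set.seed(4)
  m <- matrix(runif(20 * 40), 40)
  d <- dist(m)
  attr(d, "Labels") <- sprintf("s%02d", 1:40)
  a <- upgma(d)
  b <- hclust(d, method = "average")
  expect_equal(sort(a$height), sort(b$height), tolerance = 1e-10)
  expect_equal(as.matrix(cophenetic(a))[a$labels, a$labels],
               as.matrix(cophenetic(b))[a$labels, a$labels], tolerance = 1e-10)
})

test_that("similarity cuts use strict merge-height comparison", {
  h <- upgma(dist3(0.2, 0.6, 0.8))
  expect_equal(unname(cut_at_similarity(h, 50)), c(1, 1, 2))   # cut 0.5
  expect_equal(unname(cut_at_similarity(h, 100)), 1:3)
  expect_equal(unname(cut_at_similarity(h, 10)), c(1, 1, 1))
  # completely disjoint cells merge at exactly 1.0 and stay separate at s = 0
  hd <- upgma(dist3(1, 1, 1))
  expect_equal(unname(cut_at_similarity(hd, 0)), 1:3)
})

test_that("newick and merge-table exports are readable", {
  h <- upgma(dist3(0.2, 0.6, 0.8))
  paths <- write_dendrogram(h, tempfile())
  tr <- ape::read.tree(paths[1])
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  mt <- read.csv(paths[2])
  expect_equal(mt$height, c(0.2, 0.7))
})

test_that("SIMPROF finds no structure when all profiles are identical", {
  sets <- rep(list(sprintf("Aus %s", letters[1:10])), 5)
  names(sets) <- sprintf("r0c%d", 1:5)
  m <- presence_from_sets(sets)
  h <- upgma(pairwise_dissimilarity(m, "jaccard"))
  sp <- simprof(m, h, n_permutations = 99, seed = 1)
  root <- which.max(sp$n_leaves)
  expect_equal(sp$pi[root], 0)
  expect_equal(sp$p_value[root], 1)
})

test_that("SIMPROF detects a planted two-block structure at the root", {
  m <- two_block_matrix(10, 50, seed = 8)
  h <- upgma(pairwise_dissimilarity(m, "jaccard"))
  sp <- simprof(m, h, n_permutations = 999, seed = 2)
  root <- nrow(sp)
  expect_true(sp$tested[root])
  expect_lte(sp$p_value[root], 0.05)
  # nodes with < 3 leaves are never tested
  expect_true(all(!sp$tested[sp$n_leaves < 3]))
  expect_true(all(sp$homogeneous[sp$n_leaves < 3]))
})

test_that("SIMPROF is reproducible given a seed", {
  m <- two_block_matrix(5, 40, seed = 3)
  h <- upgma(pairwise_dissimilarity(m, "jaccard"))
  a <- simprof(m, h, n_permutations = 99, seed = 7)
  b <- simprof(m, h, n_permutations = 99, seed = 7)
  expect_identical(a$p_value, b$p_value)
  t1 <- simprof_test(m, n_permutations = 99, seed = 5)
  t2 <- simprof_test(m, n_permutations = 99, seed = 5)
  expect_identical(t1, t2)
})

test_that("ANOSIM separates fully distinct groups with R = 1 exactly", {
  m <- two_block_matrix(5, 40, seed = 6)
  d <- pairwise_dissimilarity(m, "jaccard")
  g <- rep(c("A", "B"), each = 5)
  res <- anosim(d, g, n_permutations = 199, seed = 1)
  expect_equal(res$R, 1.0)
  expect_lt(res$p_value, 0.05)
  # renaming groups leaves R unchanged
  res2 <- anosim(d, ifelse(g == "A", "Z", "Y"), n_permutations = 199, seed = 1)
  expect_equal(res2$R, res$R)
})

test_that("ANOSIM R is rank-based and centred near zero for random labels", {
  set.seed(10)
  m <- two_block_matrix(6, 40, seed = 9)
  d <- pairwise_dissimilarity(m, "jaccard")
  # monotone transform invariance
  d2 <- d; d2[] <- d[]^3
  g <- rep(c("A", "B"), each = 6)
  expect_equal(anosim(d, g, n_permutations = 9, seed = 1)$R,
               anosim(d2, g, n_permutations = 9, seed = 1)$R)
  # distribution under random labels
  rs <- vapply(1:200, function(i)
    anosim(d, sample(g), n_permutations = 9, seed = i)$R, 0.0)
  expect_lt(abs(mean(rs)), 0.02)
  expect_error(anosim(d, rep("A", 12)), "2 groups")
  expect_error(anosim(d, c("B", rep("A", 11))), "2 members")
})

test_that("ANOSIM statistic matches vegan", {
  skip_if_not_installed("vegan")
  m <- two_block_matrix(6, 50, seed = 12)
  d <- pairwise_dissimilarity(m, "jaccard")
  g <- factor(rep(c("A", "B"), each = 6))
  mine <- anosim(d, as.character(g), n_permutations = 99, seed = 1)
  theirs <- suppressWarnings(vegan::anosim(d, g, permutations = 99))
  expect_equal(mine$R, unname(theirs$statistic), tolerance = 1e-12)
})

test_that("bootstrap support is 100% for duplicated cells and symmetric", {
  m <- presence_from_sets(list(
    r0c1 = sprintf("Aus %s", letters[1:10]),
    r0c2 = sprintf("Aus %s", letters[1:10]),
    r0c3 = sprintf("Bus %s", letters[11:20])))
  bs <- bootstrap_support(m, s = 20, n_boot = 50, seed = 1)
  expect_equal(bs$support["r0c1", "r0c2"], 100)
  expect_equal(diag(bs$support), c(r0c1 = 100, r0c2 = 100, r0c3 = 100))
  expect_equal(bs$support, t(bs$support))
})
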