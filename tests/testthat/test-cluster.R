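test_that("binary distances match hand enumeration", {
  m <- matrix(c(1, 1, 0,   # strain A
                0, 1, 1),  # strain B
              nrow = 3,
              dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  expect_equal(as.matrix(binary_distance(m, "jaccard"))["A", "B"], 1 - 1 / 3)
  expect_equal(as.matrix(binary_distance(m, "hamming"))["A", "B"], 2 / 3)

  ident <- cbind(A = c(1L, 0L, 1L), B = c(1L, 0L, 1L))
  rownames(ident) <- paste0("f", 1:3)
  expect_equal(as.matrix(binary_distance(ident))["A", "B"], 0)

  disjoint <- cbind(A = c(1L, 0L), B = c(0L, 1L))
  rownames(disjoint) <- paste0("f", 1:2)
  expect_equal(as.matrix(binary_distance(disjoint))["A", "B"], 1)

  # empty-vs-empty profiles are defined as distance zero
  zero <- cbind(A = c(0L, 0L), B = c(0L, 0L))
  rownames(zero) <- paste0("f", 1:2)
  expect_equal(as.matrix(binary_distance(zero))["A", "B"], 0)

  one <- matrix(1L, 2, 1, dimnames = list(c("f1", "f2"), "A"))
  expect_error(binary_distance(one), "2 strains")

  # agrees with base R's binary distance on random matrices
  set.seed(10)
  m <- rand_presence(60, 7)
  expect_equal(as.matrix(binary_distance(m, "jaccard")),
               as.matrix(dist(t(m), method = "binary")),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("forced merge orders and degenerate ties are deterministic", {
  d <- as.dist(matrix(c(0, 1, 10,
                        1, 0, 10,
                        10, 10, 0), 3,
                      dimnames = list(c("A", "B", "C"), c("A", "B", "C"))))
  dend <- hierarchical_cluster(d, "average")
  expect_equal(dend$height[1], 1)
  expect_setequal(dend$labels[-dend$merge[1, ]], c("A", "B"))

  # all distances equal: n-1 merges at one height, lexicographic topology
  n <- 5
  dm <- matrix(1, n, n, dimnames = list(letters[1:n], letters[1:n]))
  diag(dm) <- 0
  dend <- hierarchical_cluster(as.dist(dm), "average")
  expect_equal(length(dend$height), n - 1)
  expect_true(all(dend$height == 1))
  # first merge is the lexicographically smallest pair (a, b)
  expect_setequal(dend$labels[-dend$merge[1, ]], c("a", "b"))

  bad <- matrix(c(0, 1, 2, 0), 2)
  expect_error(hierarchical_cluster(bad), "symmetric")
})

test_that("cophenetic distances agree with stats::hclust on tie-free instances", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- sprintf("S%02d", seq_len(n))
    d <- dist(x)
    for (link in c("average", "complete")) {
      ours <- hierarchical_cluster(d, link)
      theirs <- stats::hclust(d, method = link)
      expect_equal(cophenetic_matrix(ours),
                   as.matrix(cophenetic(theirs)),
                   tolerance = 1e-12)
    }
  }
})

test_that("merge heights are monotone and cophenetics are relabeling-invariant", {
  set.seed(8)
  m <- rand_presence(50, 9)
  for (link in c("average", "complete")) {
    dend <- hierarchical_cluster(binary_distance(m), link)
    expect_true(all(diff(dend$height) >= -1e-12))
  }
  # permute strain labels; cophenetic matrix permutes with them
  perm <- sample(ncol(m))
  m2 <- m[, perm]
  c1 <- cophenetic_matrix(hierarchical_cluster(binary_distance(m), "average"))
  c2 <- cophenetic_matrix(hierarchical_cluster(binary_distance(m2), "average"))
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-12)
})

test_that("ward linkage matches stats::hclust ward.D2", {
  set.seed(5)
  x <- matrix(rnorm(8 * 3), 8)
  rownames(x) <- sprintf("S%d", 1:8)
  d <- dist(x)
  ours <- hierarchical_cluster(d, "ward")
  theirs <- stats::hclust(d, method = "ward.D2")
  expect_equal(sort(ours$height), sort(theirs$height), tolerance = 1e-12)
  expect_equal(cophenetic_matrix(ours), as.matrix(cophenetic(theirs)),
               tolerance = 1e-12)
})

test_that("focal cluster evaluation covers the edge cuts", {
  set.seed(2)
  m <- rand_presence(40, 8)
  dend <- hierarchical_cluster(binary_distance(m), "average")
  focal <- c("S1", "S2", "S3")

  expect_true(evaluate_focal_cluster(dend, focal, k = 1)$focal_single_cluster)
  expect_false(evaluate_focal_cluster(dend, focal, k = 8)$focal_single_cluster)
  expect_true(evaluate_focal_cluster(dend, "S5", k = 8)$focal_single_cluster)
  expect_error(evaluate_focal_cluster(dend, focal, k = 9), "between 1 and n")
  expect_error(evaluate_focal_cluster(dend, c("S1", "ZZ"), k = 2), "ZZ")

  sweep <- focal_cluster_sweep(dend, focal, ks = 2:5)
  expect_equal(sweep$k, 2:5)
  expect_true(all(sweep$focal_purity >= 1 / 3 & sweep$focal_purity <= 1))
})

test_that("planted convergent loss, not phylogeny, drives focal co-clustering", {
  # scaled-down version of the headline contrast: with the focal regime on,
  # the polyphyletic focal group collapses into one cluster; with it off
  # the two focal clades stay with their phylogenetic neighbours
  single <- function(extra, seed) {
    b <- simulate_dataset(small_config(seed = seed, focal_extra_loss = extra))
    dend <- hierarchical_cluster(binary_distance(b$presence), "average")
    evaluate_focal_cluster(dend, b$truth$focal_ids, k = 6)$focal_single_cluster
  }
  on <- sum(vapply(1:8, function(s) single(0.5, 300 + s), TRUE))
  off <- sum(vapply(1:8, function(s) single(0, 300 + s), TRUE))
  expect_gte(on, 6)
  expect_lte(off, 3)
})
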