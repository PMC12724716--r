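test_that("p-distance counts mismatches and applies the pairwise gap rule", {
  expect_equal(sequence_distance(c(a = "ACGT", b = "ACGT"))[1, 2], 0)
  expect_equal(sequence_distance(c(a = "AAAAAAAAAA", b = "AAAAAAAAAC"))[1, 2], 0.1)
  # gap in either sequence removes the site from both counts
  expect_equal(sequence_distance(c(a = "AC-GT", b = "ACTGA"))[1, 2], 0.25)
  expect_error(sequence_distance(c(a = "ACG", b = "ACGT")), "equal length")
  expect_error(sequence_distance(c(a = "---", b = "AC-")), "comparable")
  expect_error(sequence_distance(c(a = "ACGT")), "at least 2")
})

test_that("p-distance agrees with ape's raw pairwise-deletion distance", {
  set.seed(20)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T", "-"), 60, replace = TRUE,
                 prob = c(rep(0.23, 4), 0.08)), collapse = "")
  }, character(1))
  names(seqs) <- paste0("s", 1:5)
  mine <- sequence_distance(seqs)
  bin <- ape::as.DNAbin(strsplit(tolower(seqs), ""))
  ref <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(mine, ref[rownames(mine), colnames(mine)], tolerance = 1e-12)
})

test_that("hcluster reproduces hand agglomeration and is order invariant", {
  m <- matrix(c(0, 1, 5, 1, 0, 5, 5, 5, 0), 3)
  h <- tree_from_dist(m, c("A", "B", "C"))
  expect_equal(h$height, c(1, 5))
  cm <- cophenetic_matrix(h)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "C"], 5)
  expect_equal(cm["B", "C"], 5)
  # two items: single merge at their distance
  h2 <- tree_from_dist(matrix(c(0, 3, 3, 0), 2), c("X", "Y"))
  expect_equal(h2$height, 3)
  expect_equal(cophenetic_matrix(h2)["X", "Y"], 3)
  # cut assignments invariant to input row order
  set.seed(21)
  x <- matrix(rnorm(40), 8, dimnames = list(paste0("i", 1:8), NULL))
  c1 <- stats::cutree(hcluster(x), k = 3)
  c2 <- stats::cutree(hcluster(x[sample(8), ]), k = 3)
  tab <- table(c1[names(c2)], c2)
  expect_equal(sum(tab > 0), 3)  # a pure relabeling
  expect_error(hcluster(rbind(x, NA)), "missing")
})

test_that("cophenetic matrices of average/complete linkage are ultrametric", {
  set.seed(22)
  for (linkage in c("average", "complete")) {
    x <- matrix(rnorm(36), 6, dimnames = list(paste0("i", 1:6), NULL))
    cm <- cophenetic_matrix(hcluster(x, linkage = linkage))
    labs <- rownames(cm)
    for (tri in utils::combn(labs, 3, simplify = FALSE)) {
      d3 <- sort(c(cm[tri[1], tri[2]], cm[tri[1], tri[3]], cm[tri[2], tri[3]]))
      expect_lte(d3[3], d3[2] + 1e-10)  # max attained at least twice
    }
  }
})

test_that("cpcc is 1 on identical trees, scale invariant, and oracle-checked", {
  set.seed(23)
  x <- matrix(rnorm(32), 8, dimnames = list(paste0("i", 1:8), NULL))
  h <- hcluster(x)
  expect_equal(cpcc(h, h), 1.0)
  h2 <- h
  h2$height <- h2$height * 2
  expect_equal(cpcc(h, h2), 1.0)
  # 4-leaf pair against a direct correlation computation
  y <- matrix(rnorm(16), 4, dimnames = list(paste0("i", 1:4), NULL))
  z <- matrix(rnorm(16), 4, dimnames = list(paste0("i", 1:4), NULL))
  t1 <- hcluster(y); t2 <- hcluster(z)
  m1 <- cophenetic_matrix(t1); m2 <- cophenetic_matrix(t2)
  labs <- sort(rownames(m1))
  ref <- stats::cor(m1[labs, labs][lower.tri(m1)], m2[labs, labs][lower.tri(m2)])
  expect_equal(cpcc(t1, t2), ref, tolerance = 1e-12)
  bad <- t2; bad$labels <- paste0("z", 1:4)
  expect_error(cpcc(t1, bad), "label")
})

test_that("entanglement matches hand-computed values and its invariances", {
  expect_equal(entanglement(c("a", "b", "c"), c("a", "b", "c")), 0)
  expect_equal(entanglement(letters[1:5], rev(letters[1:5])), 1)
  # n = 3 adjacent transposition at L = 1.5: 2 / (2 * 2^1.5)
  expect_equal(entanglement(c("a", "b", "c"), c("a", "c", "b")),
               2 / (2 * 2^1.5), tolerance = 1e-12)
  expect_equal(entanglement(c("a", "b", "c"), c("a", "c", "b")), 0.3536,
               tolerance = 2e-4)
  # symmetry and relabeling invariance
  set.seed(24)
  o1 <- sample(letters[1:7]); o2 <- sample(letters[1:7])
  expect_equal(entanglement(o1, o2), entanglement(o2, o1))
  map <- stats::setNames(LETTERS[1:7], letters[1:7])
  expect_equal(entanglement(unname(map[o1]), unname(map[o2])),
               entanglement(o1, o2))
  expect_error(entanglement(c("a", "b"), c("a", "c")), "permutations")
})

test_that("untangle reaches zero on identical trees and is deterministic", {
  set.seed(25)
  x <- matrix(rnorm(48), 8, dimnames = list(paste0("i", 1:8), NULL))
  h <- hcluster(x)
  u <- untangle(h, h)
  expect_equal(u$entanglement, 0)
  expect_equal(u$entanglement_exhaustive, 0)
  u2 <- untangle(h, h)
  expect_identical(u, u2)
})

test_that("greedy untangling never beats and usually equals the exhaustive optimum", {
  set.seed(26)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 4), n, dimnames = list(paste0("i", 1:n), NULL))
    y <- matrix(rnorm(n * 4), n, dimnames = list(paste0("i", 1:n), NULL))
    u <- untangle(hcluster(x), hcluster(y))
    expect_gte(u$entanglement, u$entanglement_exhaustive - 1e-12)
  }
  # shipped 4-leaf fixture: greedy equals the exhaustive oracle
  m1 <- matrix(c(0, 1, 4, 6, 1, 0, 4, 6, 4, 4, 0, 6, 6, 6, 6, 0), 4)
  m2 <- matrix(c(0, 6, 4, 1, 6, 0, 5, 6, 4, 5, 0, 4, 1, 6, 4, 0), 4)
  t1 <- tree_from_dist(m1, letters[1:4])
  t2 <- tree_from_dist(m2, letters[1:4])
  u <- untangle(t1, t2)
  expect_equal(u$entanglement, u$entanglement_exhaustive, tolerance = 1e-12)
})

test_that("trait/sequence comparison recovers identical structure exactly", {
  set.seed(27)
  pts <- matrix(rnorm(16), 8, 2, dimnames = list(LETTERS[1:8], NULL))
  D <- as.matrix(dist(scale(pts)))
  cmp <- compare_trait_sequence_trees(pts, D, exhaustive_max = 8)
  expect_equal(cmp$entanglement, 0, tolerance = 1e-12)
  expect_equal(cmp$cpcc, 1.0, tolerance = 1e-6)
  expect_error(compare_trait_sequence_trees(pts[1:2, , drop = FALSE], D),
               "3 shared")
})

test_that("random trait matrices give cpcc centered near zero", {
  set.seed(28)
  ds <- generate_dataset(tiny_config())
  D <- sequence_distance(ds$founder_sequences)
  cp <- vapply(1:60, function(i) {
    pts <- matrix(rnorm(24), 8, 3, dimnames = list(LETTERS[1:8], NULL))
    compare_trait_sequence_trees(pts, D)$cpcc
  }, numeric(1))
  expect_lt(abs(mean(cp)), 0.15)
})

test_that("newick export round-trips to the same cophenetic structure", {
  set.seed(29)
  x <- matrix(rnorm(30), 6, dimnames = list(paste0("i", 1:6), NULL))
  h <- hcluster(x)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(h, f)
  tr <- ape::read.tree(f)
  ref <- cophenetic_matrix(h)
  got <- ape::cophenetic.phylo(tr)[rownames(ref), colnames(ref)]
  # as.phylo halves merge heights so leaf-to-leaf path length = merge height
  expect_equal(got, ref, tolerance = 1e-8)
})
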