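test_that("max-abs aggregation keeps the signed extreme statistic", {
  m <- rbind(g1 = c(1.2, -3.4), g2 = c(0.5, 0.1), g3 = c(-2.0, 2.0))
  colnames(m) <- c("c1", "c2")
  r <- aggregate_ranks_maxabs(m)
  expect_equal(r$score[r$gene_id == "g1"], -3.4)
  expect_equal(r$score[r$gene_id == "g2"], 0.5)
  expect_equal(r$score[r$gene_id == "g3"], -2.0)  # tie |.|: first contrast wins
  expect_equal(r$gene_id, c("g2", "g3", "g1"))    # sorted descending
  # single contrast: identity ordering
  one <- matrix(c(3, -1, 2), dimnames = list(c("a", "b", "c"), "z"))
  expect_equal(aggregate_ranks_maxabs(one)$gene_id, c("a", "c", "b"))
  # all-missing gene dropped and reported
  m2 <- rbind(m, g4 = c(NA, NA))
  r2 <- aggregate_ranks_maxabs(m2)
  expect_false("g4" %in% r2$gene_id)
  expect_equal(attr(r2, "dropped"), "g4")
})

test_that("median aggregation uses the midpoint convention", {
  m <- rbind(g1 = c(-1, 0, 5), g2 = c(-1, 3, NA), g3 = c(2, 2, 2))
  r <- aggregate_ranks_median(m)
  expect_equal(r$score[r$gene_id == "g1"], 0)
  expect_equal(r$score[r$gene_id == "g2"], 1)  # even count midpoint
  expect_equal(r$score[r$gene_id == "g3"], 2)
})

test_that("GSEA running-sum ES matches a brute-force walk", {
  set.seed(10)
  for (i in 1:20) {
    N <- 10
    genes <- paste0("g", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    set <- sample(genes, 3)
    ranked <- data.frame(gene_id = genes, score = scores)
    for (w in c(1, 0)) {
      res <- gsea_preranked(ranked, list(S = set), n_perm = 50, seed = i,
                            min_size = 1, weight = w)
      expect_equal(res$ES, gsea_walk_oracle(scores, genes, set, weight = w),
                   tolerance = 1e-12)
    }
  }
})

test_that("a top-k set is positively enriched with small p", {
  set.seed(4)
  N <- 100
  genes <- paste0("g", 1:N)
  ranked <- data.frame(gene_id = genes, score = sort(rnorm(N), decreasing = TRUE))
  res <- gsea_preranked(ranked, list(top = genes[1:10]), n_perm = 1000, seed = 1)
  expect_gt(res$ES, 0)
  expect_lt(res$p, 0.05)
  expect_equal(strsplit(res$leading_edge, ",")[[1]][1], "g1")
})

test_that("random sets give NES centered near zero", {
  set.seed(5)
  N <- 200
  genes <- paste0("g", 1:N)
  ranked <- data.frame(gene_id = genes, score = sort(rnorm(N), decreasing = TRUE))
  nes <- vapply(1:200, function(i) {
    gsea_preranked(ranked, list(S = sample(genes, 15)), n_perm = 100,
                   seed = i)$NES
  }, numeric(1))
  expect_lt(abs(mean(nes, na.rm = TRUE)), 0.2)
})

test_that("GSEA respects size bounds, BH adjustment, and is reproducible", {
  set.seed(6)
  genes <- paste0("g", 1:50)
  ranked <- data.frame(gene_id = genes, score = sort(rnorm(50), decreasing = TRUE))
  sets <- list(tiny = genes[1:2], ok = genes[1:10], huge = genes)
  res <- gsea_preranked(ranked, sets, n_perm = 200, seed = 3, min_size = 5,
                        max_size = 40)
  expect_equal(res$set, "ok")
  expect_setequal(attr(res, "skipped"), c("tiny", "huge"))
  expect_true(all(res$padj >= res$p))
  expect_true(all(sign(res$NES) == sign(res$ES)))
  res2 <- gsea_preranked(ranked, sets, n_perm = 200, seed = 3, min_size = 5,
                         max_size = 40)
  expect_identical(res, res2)
})

test_that("GSEA agrees with fgsea on direction and rough magnitude", {
  skip_if_not_installed("fgsea")
  set.seed(8)
  N <- 300
  genes <- paste0("g", 1:N)
  scores <- sort(rnorm(N, sd = 2), decreasing = TRUE)
  ranked <- data.frame(gene_id = genes, score = scores)
  sets <- list(A = genes[seq(1, 60, by = 2)], B = sample(genes, 30))
  mine <- gsea_preranked(ranked, sets, n_perm = 500, seed = 2)
  ref <- suppressWarnings(fgsea::fgsea(sets, stats::setNames(scores, genes),
                                       nPermSimple = 2000))
  for (s in c("A", "B")) {
    expect_equal(mine$ES[mine$set == s], ref$ES[ref$pathway == s],
                 tolerance = 1e-6)
  }
})

test_that("hypergeometric over-representation matches closed form and summation", {
  # C(5,4)*C(5,0)/C(10,4) = 5/210
  r <- overrepresentation_test(paste0("g", 1:4), paste0("g", 1:10),
                               paste0("g", c(1:4, 6)))
  expect_equal(r$overlap, 4L)
  expect_equal(r$p, 5 / 210, tolerance = 1e-12)
  # annotation == universe: p = 1
  expect_equal(overrepresentation_test(paste0("g", 1:3), paste0("g", 1:10),
                                       paste0("g", 1:10))$p, 1)
  expect_warning(r0 <- overrepresentation_test(character(0), paste0("g", 1:10),
                                               "g1"), "empty")
  expect_equal(r0$p, 1)
  expect_error(overrepresentation_test("zz", paste0("g", 1:10), "g1"), "subset")
  # 50 random configurations against direct summation of the pmf
  set.seed(9)
  for (i in 1:50) {
    N <- sample(10:60, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    universe <- paste0("u", 1:N)
    annot <- sample(universe, K)
    hits <- sample(universe, n)
    x <- length(intersect(hits, annot))
    direct <- sum(stats::dhyper(x:min(K, n), K, N - K, n))
    expect_equal(overrepresentation_test(hits, universe, annot)$p, direct,
                 tolerance = 1e-10)
  }
})

test_that("overlap below expectation gives p of at least one half", {
  set.seed(12)
  N <- 40; K <- 20; n <- 10
  universe <- paste0("u", 1:N)
  annot <- universe[1:K]
  hits <- c(universe[1:floor(K * n / N)], universe[(K + 1):(K + n - floor(K * n / N))])
  expect_gte(overrepresentation_test(hits, universe, annot)$p, 0.5)
})

test_that("rank-shift test: exact example, ties path, and shift invariance", {
  expect_equal(rank_shift_test(1:3, 4:6), 0.1, tolerance = 1e-12)
  expect_equal(rank_shift_test(c(1, 2, 2, 3), c(1, 2, 2, 3)), 1)
  set.seed(13)
  a <- rnorm(5); b <- rnorm(7)
  expect_equal(rank_shift_test(a, b), rank_shift_test(a + 10, b + 10))
  expect_error(rank_shift_test(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Wilcoxon paths agree for moderate groups", {
  set.seed(14)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    approx <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(exact - approx), 0.02)
    expect_equal(rank_shift_test(a, b), exact)
  }
})

test_that("overlap_candidates intersects, annotates, and sorts by p", {
  hits <- data.frame(
    feature_id = c("g1", "g2", "g3"), n_markers = 4L,
    min_p = c(1e-4, 1e-6, 1e-5), best_marker = c("M1", "M2", "M1"),
    best_position = c(100, 200, 100), best_beta = 1, best_statistic = c(3, 5, 4),
    markers_significant = c("M1", "M2,M3", "M1"),
    positions_significant = c("100", "200,300", "100"),
    n_significant = c(1L, 2L, 1L), stringsAsFactors = FALSE)
  ext <- data.frame(gene_id = c("g2", "g3", "g9"),
                    external_trait = c("HR", "EF", "HR"))
  annot <- data.frame(gene_id = c("g1", "g2", "g3"),
                      is_mitocarta = c(FALSE, TRUE, FALSE))
  trait_hits <- data.frame(feature_id = "dEF", markers_significant = "M2",
                           stringsAsFactors = FALSE)
  out <- overlap_candidates(hits, ext, annot, trait_hits)
  expect_equal(out$gene_id, c("g2", "g3"))  # ascending p
  expect_equal(out$mito_gwas_traits, c("dEF", ""))
  expect_equal(out$external_traits, c("HR", "EF"))
  expect_equal(out$is_mitocarta, c(TRUE, FALSE))
  expect_equal(out$positions, c("200,300", "100"))
  # disjoint lists: empty; empty external list: warning + empty
  expect_equal(nrow(overlap_candidates(hits, data.frame(gene_id = "zz",
                                                        external_trait = "x"))), 0)
  expect_warning(e <- overlap_candidates(hits, NULL), "empty external")
  expect_equal(nrow(e), 0)
})

test_that("GMT round-trips", {
  sets <- list(A = c("g1", "g2"), B = c("g3", "g4", "g5"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
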