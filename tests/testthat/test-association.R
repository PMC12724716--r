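test_that("single-marker OLS matches the closed-form hand example", {
  y <- c(0.1, -0.1, 0.0, 1.1, 0.9, 1.0)
  d <- c(0, 0, 0, 1, 1, 1)
  rec <- fit_marker_association(y, d)
  orc <- ols_oracle(y, d)
  expect_equal(rec$beta, 1.0)
  expect_equal(rec$beta, orc$beta, tolerance = 1e-12)
  expect_equal(rec$se, orc$se, tolerance = 1e-12)
  expect_equal(rec$statistic, orc$t, tolerance = 1e-12)
  expect_equal(rec$p, orc$p, tolerance = 1e-12)
  expect_equal(rec$df2, 4L)
  expect_equal(abs(rec$statistic), abs(rec$beta / rec$se))
})

test_that("monomorphic and underpowered markers are skipped with reasons", {
  y <- rnorm(10)
  expect_equal(fit_marker_association(y, rep(0, 10))$reason, "monomorphic")
  expect_equal(fit_marker_association(y, c(rep(0, 8), 1, 1))$reason, "underpowered")
  rec <- fit_marker_association(y, c(rep(0, 7), 1, 1, 1))
  expect_true(is.na(rec$reason))
})

test_that("multi-allelic markers use a joint F-test matching aov", {
  set.seed(3)
  y <- rnorm(24)
  d <- rep(0:2, each = 8)
  rec <- fit_marker_association(y, d)
  expect_equal(rec$test, "F")
  fit <- stats::anova(stats::lm(y ~ factor(d)))
  expect_equal(rec$statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_equal(rec$p, fit$`Pr(>F)`[1], tolerance = 1e-10)
})

test_that("null p-values are uniform (KS over many replicates)", {
  set.seed(7)
  n <- 63
  reps <- 2000
  d <- rep(c(0, 1), length.out = n)
  Y <- matrix(rnorm(n * reps), n, reps,
              dimnames = list(NULL, paste0("f", seq_len(reps))))
  res <- ccmito:::ols_scan_column(Y, d)
  expect_gt(stats::ks.test(res$p, "punif")$p.value, 0.01)
})

test_that("scan emits one record per feature and testable marker, in order", {
  ds <- generate_dataset(sim_config(seed = 23, n_genes = 0, n_gene_sets = 0,
                                    n_external_genes = 0))
  g <- ds$genotypes
  feats <- prepare_trait_matrix(ds$trait_table, ds$sample_table, "Ctrl")
  sc <- scan_markers(feats, g, arm = "Ctrl")
  expect_equal(nrow(sc), ncol(feats) * 21)
  expect_equal(nrow(attr(sc, "skipped")), 0)
  # p identical within a strain-distribution pattern group
  pat <- distinct_patterns(g)
  one <- sc[sc$feature_id == colnames(feats)[1], ]
  for (grp in split(pat$marker_id, pat$group)) {
    expect_equal(length(unique(signif(one$p[one$marker_id %in% grp], 12))), 1)
  }
  # a feature equal to a dosage column attains the scan-row minimum there
  feats2 <- cbind(feats, exact = g$dosage[rownames(feats), "Mit002"])
  sc2 <- scan_markers(feats2, g, arm = "Ctrl")
  ex <- sc2[sc2$feature_id == "exact", ]
  expect_equal(ex$marker_id[which.min(ex$p)], "Mit002")
})

test_that("scan is invariant to strain order and errors without shared strains", {
  ds <- generate_dataset(tiny_config(seed = 31))
  g <- ds$genotypes
  feats <- prepare_trait_matrix(ds$trait_table, ds$sample_table, "Iso")
  sc1 <- scan_markers(feats, g, arm = "Iso")
  sc2 <- scan_markers(feats[rev(seq_len(nrow(feats))), ], g, arm = "Iso")
  expect_equal(sc1$p, sc2$p, tolerance = 1e-12)
  expect_equal(sc1$beta, sc2$beta, tolerance = 1e-12)
  bad <- feats
  rownames(bad) <- paste0("XX", seq_len(nrow(bad)))
  expect_error(scan_markers(bad, g), "shared strains")
})

test_that("permutation threshold is reproducible and validates inputs", {
  ds <- generate_dataset(tiny_config(seed = 1))
  g <- ds$genotypes
  t1 <- permutation_threshold(g, 0.05, 400, seed = 9)
  t2 <- permutation_threshold(g, 0.05, 400, seed = 9)
  expect_identical(t1$p_threshold, t2$p_threshold)
  expect_gt(t1$p_threshold, 0)
  expect_lt(t1$p_threshold, 1)
  expect_error(permutation_threshold(g, 0.05, 50), "n_perm")
  expect_error(permutation_threshold(g, 0.001, 500), "increase n_perm")
})

test_that("with one effective marker the threshold approaches the FWER level", {
  ds <- generate_dataset(sim_config(seed = 6, n_patterns = 1, n_genes = 0,
                                    n_gene_sets = 0, n_external_genes = 0))
  th <- permutation_threshold(ds$genotypes, 0.05, 4000, seed = 2)
  expect_lt(abs(th$p_threshold - 0.05), 0.012)
})

test_that("hit calling is strict at the threshold and checks fingerprints", {
  ds <- generate_dataset(tiny_config(seed = 51))
  g <- ds$genotypes
  feats <- prepare_trait_matrix(ds$trait_table, ds$sample_table, "Iso")
  sc <- scan_markers(feats, g, arm = "Iso")
  # exact-threshold feature is not a hit
  th <- structure(list(fwer_level = 0.05, p_threshold = min(sc$p),
                       n_perm = 100L, seed = 1L,
                       fingerprint = attr(sc, "fingerprint")),
                  class = "perm_threshold")
  expect_equal(nrow(significant_hits(sc, th)), 0)
  th$p_threshold <- min(sc$p) * (1 + 1e-9)
  expect_equal(nrow(significant_hits(sc, th)), 1)
  # empty records give an empty summary
  expect_equal(nrow(significant_hits(sc[0, ], th)), 0)
  th$fingerprint <- "deadbeef"
  expect_error(significant_hits(sc, th), "fingerprint")
})

test_that("best marker ties break by lowest genome position", {
  records <- data.frame(
    feature_id = "f", marker_id = c("Mb", "Ma"), position_bp = c(500, 100),
    arm = NA, n = 10L, beta = c(1, -1), se = 1, statistic = c(1, -1),
    df1 = 1L, df2 = 8L, p = c(1e-6, 1e-6), test = "t",
    stringsAsFactors = FALSE)
  th <- structure(list(fwer_level = 0.05, p_threshold = 1e-3, n_perm = 100L,
                       seed = 1L, fingerprint = NULL),
                  class = "perm_threshold")
  h <- significant_hits(records, th)
  expect_equal(h$best_marker, "Ma")
  expect_equal(h$n_significant, 2L)
})

test_that("label-permutation mode reproduces the fresh-normal threshold", {
  ds <- generate_dataset(tiny_config(seed = 61))
  g <- ds$genotypes
  set.seed(1)
  y <- rnorm(length(g$strain_ids))
  t_norm <- permutation_threshold(g, 0.05, 2000, seed = 3)
  t_perm <- permutation_threshold(g, 0.05, 2000, seed = 3, observed = y)
  expect_lt(abs(t_norm$p_threshold - t_perm$p_threshold),
            0.5 * t_norm$p_threshold + 0.01)
})
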