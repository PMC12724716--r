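#' Single marker-feature association test
#'
#' Ordinary least squares of a strain-level feature on marker dosage. For
#' biallelic markers the model is `y = a + b * dosage` with a two-sided p-value
#' from the t distribution on n-2 degrees of freedom. Markers with more than
#' two alleles are tested with a joint F-test on the allele factor. Markers
#' whose dosage is constant among the scanned strains are skipped with reason
#' `"monomorphic"`; markers with any allele class smaller than `min_class`
#' strains are skipped with reason `"underpowered"`.
#'
#' @param y numeric strain-level values (NAs dropped pairwise).
#' @param dosage numeric dosage codes aligned with `y`.
#' @param min_class minimum strains per dosage class (default 3).
#' @return one-row data.frame: `n`, `beta`, `se`, `statistic`, `df1`, `df2`,
#'   `p`, `test` ("t" or "F"), `reason` (NA unless skipped).
#' @export
fit_marker_association <- function(y, dosage, min_class = 3) {
  ok <- !is.na(y) & !is.na(dosage)
  y <- y[ok]; dosage <- dosage[ok]
  n <- length(y)
  skipped <- function(reason) {
    data.frame(n = n, beta = NA_real_, se = NA_real_, statistic = NA_real_,
               df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
               test = NA_character_, reason = reason, stringsAsFactors = FALSE)
  }
  classes <- table(dosage)
  if (length(classes) < 2) return(skipped("monomorphic"))
  if (any(classes < min_class)) return(skipped("underpowered"))
  if (length(classes) == 2) {
    x <- as.numeric(dosage)
    sxx <- sum((x - mean(x))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    syy <- sum((y - mean(y))^2)
    beta <- sxy / sxx
    df <- n - 2L
    rss <- max(syy - beta * sxy, 0)
    se <- sqrt(rss / df / sxx)
    tstat <- beta / se
    p <- 2 * stats::pt(-abs(tstat), df)
    data.frame(n = n, beta = beta, se = se, statistic = tstat,
               df1 = 1L, df2 = df, p = clamp_p(p), test = "t",
               reason = NA_character_, stringsAsFactors = FALSE)
  } else {
    g <- factor(dosage)
    k <- nlevels(g) - 1L
    df2 <- n - nlevels(g)
    fit <- stats::lm.fit(stats::model.matrix(~ g), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    fstat <- ((tss - rss) / k) / (rss / df2)
    p <- stats::pf(fstat, k, df2, lower.tail = FALSE)
    data.frame(n = n, beta = NA_real_, se = NA_real_, statistic = fstat,
               df1 = k, df2 = df2, p = clamp_p(p), test = "F",
               reason = NA_character_, stringsAsFactors = FALSE)
  }
}

clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

#' Scan all features against all markers
#'
#' Runs [fit_marker_association()] for every feature x marker pair on the
#' strains shared between the feature matrix and the genotype matrix.
#' Biallelic markers use a vectorized closed-form OLS path so that
#' transcriptome-wide scans are cheap. Skipped markers produce no records but
#' are reported in the `"skipped"` attribute; the genotype fingerprint is
#' attached so hit-calling can verify that a permutation threshold was
#' computed on the same genotypes.
#'
#' @param features strain x feature numeric matrix (strain ids as rownames).
#' @param genotypes a `genotype_matrix`.
#' @param arm arm label copied into the records (bookkeeping only).
#' @param min_class minimum strains per dosage class.
#' @param min_shared minimum shared strains (default 10).
#' @return data.frame of association records ordered by (feature, position):
#'   `feature_id`, `marker_id`, `position_bp`, `arm`, `n`, `beta`, `se`,
#'   `statistic`, `df1`, `df2`, `p`, `test`.
#' @export
scan_markers <- function(features, genotypes, arm = NA_character_,
                         min_class = 3, min_shared = 10) {
  shared <- intersect(rownames(features), genotypes$strain_ids)
  if (length(shared) < min_shared) {
    stop(sprintf("only %d shared strains (need >= %d)", length(shared), min_shared),
         call. = FALSE)
  }
  Y <- features[shared, , drop = FALSE]
  D <- genotypes$dosage[shared, , drop = FALSE]
  feats <- colnames(Y)
  out <- vector("list", ncol(D))
  skipped <- list()
  for (m in seq_len(ncol(D))) {
    d <- D[, m]
    classes <- table(d)
    mid <- genotypes$marker_ids[m]
    if (length(classes) < 2) {
      skipped[[mid]] <- "monomorphic"; next
    }
    if (any(classes < min_class)) {
      skipped[[mid]] <- "underpowered"; next
    }
    if (length(classes) == 2) {
      res <- ols_scan_column(Y, as.numeric(d))
      out[[m]] <- data.frame(feature_id = feats, marker_id = mid,
                             position_bp = unname(genotypes$position_bp[m]),
                             arm = arm, n = res$n, beta = res$beta, se = res$se,
                             statistic = res$statistic, df1 = 1L, df2 = res$df,
                             p = res$p, test = "t", stringsAsFactors = FALSE)
    } else {
      recs <- lapply(feats, function(f) fit_marker_association(Y[, f], d, min_class))
      recs <- do.call(rbind, recs)
      out[[m]] <- data.frame(feature_id = feats, marker_id = mid,
                             position_bp = unname(genotypes$position_bp[m]),
                             arm = arm, n = recs$n, beta = recs$beta, se = recs$se,
                             statistic = recs$statistic, df1 = recs$df1,
                             df2 = recs$df2, p = recs$p, test = recs$test,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(feature_id = character(), marker_id = character(),
                      position_bp = numeric(), arm = character(), n = integer(),
                      beta = numeric(), se = numeric(), statistic = numeric(),
                      df1 = integer(), df2 = integer(), p = numeric(),
                      test = character(), stringsAsFactors = FALSE)
  }
  res <- res[order(match(res$feature_id, feats), res$position_bp), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- if (length(skipped)) {
    data.frame(marker_id = names(skipped), reason = unlist(skipped),
               stringsAsFactors = FALSE)
  } else {
    data.frame(marker_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  attr(res, "fingerprint") <- genotype_fingerprint(genotypes)
  attr(res, "strains") <- shared
  res
}

# Closed-form simple OLS of every column of Y on x, with per-column NA masks.
ols_scan_column <- function(Y, x) {
  M <- !is.na(Y)
  Y0 <- Y; Y0[!M] <- 0
  n <- colSums(M)
  sx <- crossprod(M, x)[, 1]
  sxx_raw <- crossprod(M, x^2)[, 1]
  sy <- colSums(Y0)
  syy <- colSums(Y0^2)
  sxy <- crossprod(Y0, x)[, 1]
  Sxx <- sxx_raw - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  beta <- Sxy / Sxx
  df <- n - 2
  rss <- pmax(Syy - beta * Sxy, 0)
  se <- sqrt(rss / df / Sxx)
  tstat <- beta / se
  p <- clamp_p(2 * stats::pt(-abs(tstat), df))
  list(n = as.integer(n), beta = beta, se = se, statistic = tstat,
       df = as.integer(df), p = p)
}

#' Fingerprint of a genotype matrix
#'
#' MD5 of a canonical text serialization of the dosage matrix (with strain and
#' marker ids). Used to guarantee that hit-calling never mixes a scan with a
#' permutation threshold computed on different genotypes.
#' @param genotypes a `genotype_matrix`.
#' @return character MD5 string.
#' @export
genotype_fingerprint <- function(genotypes) {
  f <- tempfile()
  on.exit(unlink(f))
  utils::write.table(genotypes$dosage, f, sep = "\t", quote = FALSE,
                     col.names = NA)
  unname(tools::md5sum(f))
}

#' Permutation family-wise error threshold
#'
#' Estimates the genome-wide p-value threshold controlling the family-wise
#' error rate across the marker family. `n_perm` standard-normal strain
#' phenotypes are drawn (a child stream of `seed`), each is scanned against
#' every non-skipped marker, and the minimum p-value per permutation is
#' recorded; the threshold is the `fwer_level` empirical quantile (type-7
#' interpolation) of that min-p distribution. Because z-transformed,
#' residualized phenotypes are exchangeable normals under the null, the null
#' min-p distribution depends only on the genotype correlation structure, so
#' one threshold serves every trait and every gene scanned against the same
#' genotype matrix.
#'
#' @param genotypes a `genotype_matrix`.
#' @param fwer_level target family-wise error rate in (0,1).
#' @param n_perm number of permutations (>= 100, and `n_perm * fwer_level >= 5`).
#' @param seed integer seed for the permutation stream.
#' @param min_class minimum strains per dosage class (as in the real scan).
#' @param observed optional numeric vector of observed strain values; when
#'   supplied, permutations of these labels replace the fresh normal draws
#'   (the per-feature label-permutation mode, equivalent under the null).
#' @return object of class `perm_threshold` with fields `fwer_level`,
#'   `p_threshold`, `n_perm`, `seed`, `fingerprint`, and the `min_p` vector.
#' @export
permutation_threshold <- function(genotypes, fwer_level = 0.05, n_perm = 1000,
                                  seed = 1L, min_class = 3, observed = NULL) {
  if (fwer_level <= 0 || fwer_level >= 1) stop("fwer_level must be in (0,1)",
                                               call. = FALSE)
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  if (n_perm * fwer_level < 5) {
    stop(sprintf(paste("n_perm * fwer_level = %.2f < 5: too few permutations to",
                       "estimate the %.3g quantile; increase n_perm"),
                 n_perm * fwer_level, fwer_level), call. = FALSE)
  }
  n <- length(genotypes$strain_ids)
  set.seed(seed)
  if (is.null(observed)) {
    Y <- matrix(stats::rnorm(n * n_perm), n, n_perm)
  } else {
    if (length(observed) != n) {
      stop("'observed' must have one value per strain", call. = FALSE)
    }
    Y <- vapply(seq_len(n_perm), function(i) sample(observed), numeric(n))
  }
  P <- null_scan_pmat(Y, genotypes, min_class)
  if (is.null(P)) stop("no testable marker (all monomorphic or underpowered)",
                       call. = FALSE)
  min_p <- apply(P, 1, min)
  structure(list(fwer_level = fwer_level,
                 p_threshold = unname(stats::quantile(min_p, fwer_level, type = 7)),
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 fingerprint = genotype_fingerprint(genotypes),
                 min_p = min_p),
            class = "perm_threshold")
}

#' @export
print.perm_threshold <- function(x, ...) {
  cat(sprintf("perm_threshold: p < %.6g controls FWER at %.3g (%d permutations)\n",
              x$p_threshold, x$fwer_level, x$n_perm))
  invisible(x)
}

# p-value matrix (permutations x testable markers) for normal null phenotypes.
# Only one marker per distinct strain-distribution pattern is computed.
null_scan_pmat <- function(Y, genotypes, min_class) {
  D <- genotypes$dosage
  pat <- distinct_patterns(genotypes)
  reps <- unique(pat$representative)
  cols <- list()
  for (mid in reps) {
    d <- D[, mid]
    classes <- table(d)
    if (length(classes) < 2 || any(classes < min_class)) next
    if (length(classes) == 2) {
      res <- ols_scan_column(Y, as.numeric(d))
      cols[[mid]] <- res$p
    } else {
      cols[[mid]] <- vapply(seq_len(ncol(Y)), function(j) {
        fit_marker_association(Y[, j], d, min_class)$p
      }, numeric(1))
    }
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

#' Call significant features from a scan
#'
#' A feature is a hit when its minimum p-value across markers is strictly
#' below the permutation threshold. For each hit the summary reports the best
#' marker (lowest p, ties broken by lowest genome position), its statistics,
#' and every marker passing the threshold. Refuses to combine a scan and a
#' threshold computed on different genotype matrices.
#'
#' @param records scan table from [scan_markers()].
#' @param threshold a `perm_threshold`.
#' @return data.frame, one row per hit feature: `feature_id`, `n_markers`,
#'   `min_p`, `best_marker`, `best_position`, `best_beta`, `best_statistic`,
#'   `markers_significant`, `positions_significant`, `n_significant`.
#' @export
significant_hits <- function(records, threshold) {
  fp <- attr(records, "fingerprint")
  if (!is.null(fp) && !identical(fp, threshold$fingerprint)) {
    stop("genotype fingerprint mismatch between scan and threshold", call. = FALSE)
  }
  empty <- data.frame(feature_id = character(), n_markers = integer(),
                      min_p = numeric(), best_marker = character(),
                      best_position = numeric(), best_beta = numeric(),
                      best_statistic = numeric(),
                      markers_significant = character(),
                      positions_significant = character(),
                      n_significant = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) return(empty)
  thr <- threshold$p_threshold
  sp <- split(seq_len(nrow(records)), records$feature_id)
  rows <- lapply(names(sp), function(f) {
    ix <- sp[[f]]
    r <- records[ix, , drop = FALSE]
    best <- ix[order(r$p, r$position_bp)[1]]
    if (records$p[best] >= thr) return(NULL)  # strict inequality at threshold
    sig <- r[r$p < thr, , drop = FALSE]
    sig <- sig[order(sig$position_bp), , drop = FALSE]
    data.frame(feature_id = f, n_markers = nrow(r),
               min_p = records$p[best], best_marker = records$marker_id[best],
               best_position = records$position_bp[best],
               best_beta = records$beta[best],
               best_statistic = records$statistic[best],
               markers_significant = paste(sig$marker_id, collapse = ","),
               positions_significant = paste(sig$position_bp, collapse = ","),
               n_significant = nrow(sig), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$min_p, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
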