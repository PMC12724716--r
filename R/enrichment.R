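#' Aggregate per-contrast statistics by maximum absolute value
#'
#' For each gene, keeps the signed statistic of the contrast with the largest
#' absolute value (ties resolved in favor of the earlier contrast column) and
#' sorts the result in descending score order. Used to capture the strongest
#' haplotype-specific expression signal per gene across contrasts before
#' preranked enrichment.
#'
#' @param stats numeric matrix, genes x contrasts, rownames = gene ids.
#' @return data.frame (`gene_id`, `score`) sorted descending; genes with no
#'   finite statistic are dropped and reported in attribute `"dropped"`.
#' @export
aggregate_ranks_maxabs <- function(stats) {
  agg <- apply(stats, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    v[which.max(abs(v))]
  })
  build_ranked(agg, "maxabs")
}

#' Aggregate per-marker statistics by median
#'
#' Per-gene median of the signed statistics across markers (midpoint of the
#' two central values for even counts), sorted descending. The many-markers,
#' few-patterns structure of the mitochondrial genome makes the median a
#' robust single score per gene for the trans-eQTL ranking.
#'
#' @param stats numeric matrix, genes x markers, rownames = gene ids.
#' @return data.frame (`gene_id`, `score`) sorted descending.
#' @export
aggregate_ranks_median <- function(stats) {
  agg <- apply(stats, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    stats::median(v)
  })
  build_ranked(agg, "median")
}

build_ranked <- function(agg, rule) {
  dropped <- names(agg)[is.na(agg)]
  agg <- agg[!is.na(agg)]
  ord <- order(-agg, names(agg))
  out <- data.frame(gene_id = names(agg)[ord], score = unname(agg[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "aggregation") <- rule
  attr(out, "dropped") <- dropped
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for one set,
# given sorted |score|^w weights and the (sorted) positions of set members.
# Returns the signed extremum and the index of the hit attaining it.
running_sum_es <- function(w, pos, N) {
  nh <- length(pos)
  wh <- w[pos]
  W <- sum(wh)
  if (W == 0) wh <- rep(1 / nh, nh) * (W <- 1)  # all-zero scores: uniform steps
  phit <- cumsum(wh) / W
  miss_at <- (pos - seq_len(nh)) / (N - nh)       # misses strictly before hit i
  dev_at <- phit - miss_at                        # running sum just after hit i
  # running sum just before hit i (after the misses preceding it)
  dev_before <- c(0, phit[-nh]) - (pos - 1 - (seq_len(nh) - 1)) / (N - nh)
  i_max <- which.max(dev_at)
  i_min <- which.min(dev_before)
  # on an (exact or floating-point) magnitude tie the positive extremum wins
  if (dev_at[i_max] >= -dev_before[i_min] - 1e-12) {
    list(es = dev_at[i_max], peak_hit = i_max, positive = TRUE)
  } else {
    list(es = dev_before[i_min], peak_hit = i_min, positive = FALSE)
  }
}

#' Preranked gene-set enrichment
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment on a signed,
#' sorted gene list. Hits advance the running sum by `|score|^weight`
#' (normalized over the set), misses retreat by `1/(N - Nh)`; the enrichment
#' score (ES) is the signed extremum. The null distribution comes from
#' `n_perm` gene-label permutations (random sets of the same size);
#' NES = ES / mean(|null ES| of matching sign); the p-value is the fraction of
#' matching-sign null ES at least as extreme (with the +1 permutation
#' correction); Benjamini-Hochberg adjustment across sets. The leading edge is
#' the run of set genes up to the ES extremum.
#'
#' @param ranked data.frame (`gene_id`, `score`) sorted descending, e.g. from
#'   [aggregate_ranks_maxabs()].
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @param min_size,max_size set-size bounds after intersection with the
#'   ranked universe.
#' @param weight exponent on |score| (1 = classic weighted; 0 = unweighted KS).
#' @return data.frame: `set`, `size`, `ES`, `NES`, `p`, `padj`,
#'   `leading_edge` (comma-separated); skipped sets in attribute `"skipped"`.
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, seed = 1L,
                           min_size = 5, max_size = 500, weight = 1) {
  genes <- ranked$gene_id
  N <- length(genes)
  w <- abs(ranked$score)^weight
  set.seed(seed)
  rows <- list(); skipped <- character(0)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], genes)
    nh <- length(members)
    if (nh < min_size || nh > max_size || nh >= N) {
      skipped <- c(skipped, nm); next
    }
    pos <- sort(match(members, genes))
    obs <- running_sum_es(w, pos, N)
    null_es <- vapply(seq_len(n_perm), function(i) {
      running_sum_es(w, sort(sample.int(N, nh)), N)$es
    }, numeric(1))
    same <- null_es[sign(null_es) == sign(obs$es)]
    if (length(same) == 0) {
      nes <- NA_real_
      p <- 1 / (n_perm + 1)
    } else {
      nes <- obs$es / mean(abs(same))
      p <- (sum(abs(same) >= abs(obs$es)) + 1) / (length(same) + 1)
    }
    le <- if (obs$positive) genes[pos[seq_len(obs$peak_hit)]] else {
      genes[pos[seq(obs$peak_hit, nh)]]
    }
    rows[[nm]] <- data.frame(set = nm, size = nh, ES = obs$es, NES = nes,
                             p = p, leading_edge = paste(le, collapse = ","),
                             stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(set = character(), size = integer(), ES = numeric(),
               NES = numeric(), p = numeric(), leading_edge = character(),
               stringsAsFactors = FALSE)
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out <- out[, c("set", "size", "ES", "NES", "p", "padj", "leading_edge")]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' One-sided hypergeometric over-representation test
#'
#' Tests whether an annotation (e.g. MitoCarta membership) is over-represented
#' among a hit list drawn from a gene universe:
#' p = P(X >= overlap) with X ~ Hypergeometric(N = |universe|,
#' K = |annotation in universe|, n = |hits|).
#'
#' @param hits character vector of hit genes (must lie in `universe`).
#' @param universe all tested genes.
#' @param annotation annotated genes (intersected with `universe`).
#' @return list with `p`, `overlap`, `n_hits`, `n_annotation`, `n_universe`.
#' @export
overrepresentation_test <- function(hits, universe, annotation) {
  hits <- unique(hits); universe <- unique(universe)
  if (length(setdiff(hits, universe))) {
    stop("hits must be a subset of the universe", call. = FALSE)
  }
  K <- length(intersect(annotation, universe))
  n <- length(hits)
  N <- length(universe)
  if (n == 0) {
    warning("empty hit list; over-representation p = 1 by convention")
    return(list(p = 1, overlap = 0L, n_hits = 0L, n_annotation = K,
                n_universe = N))
  }
  x <- length(intersect(hits, annotation))
  p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = x, n_hits = n, n_annotation = K, n_universe = N)
}

#' Two-sided rank-shift (Wilcoxon rank-sum) test
#'
#' Mann-Whitney/Wilcoxon rank-sum comparison of two rank distributions (e.g.
#' the ranks of MitoCarta genes in the stressed vs control ranked lists).
#' Exact enumeration when both groups have at most 8 values and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param ranks_a,ranks_b numeric vectors (both non-empty).
#' @return two-sided p-value.
#' @export
rank_shift_test <- function(ranks_a, ranks_b) {
  if (length(ranks_a) == 0 || length(ranks_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  no_ties <- !anyDuplicated(c(ranks_a, ranks_b))
  exact <- length(ranks_a) <= 8 && length(ranks_b) <= 8 && no_ties
  suppressWarnings(
    stats::wilcox.test(ranks_a, ranks_b, exact = exact, correct = TRUE)$p.value
  )
}

#' Overlap trans-eQTL hits with an external candidate gene list
#'
#' Intersects the mitochondrial trans-eQTL hit genes with an externally
#' reported gene list (e.g. nuclear-genome mitochondrial eQTL genes) to
#' produce a high-confidence dual-genome candidate table: per gene its best
#' model p-value and statistic, every associated mitochondrial marker
#' position, the mito-GWAS traits sharing those markers, the external trait
#' labels, and its MitoCarta flag. Sorted ascending by p.
#'
#' @param eqtl_hits hits summary from [significant_hits()] (gene features).
#' @param external_list data.frame with `gene_id` and `external_trait`.
#' @param annotation optional gene table with `gene_id`, `is_mitocarta`.
#' @param trait_hits optional trait-GWAS hits summary used to label each
#'   candidate with the traits associated to the same markers.
#' @return data.frame, one row per overlapping gene.
#' @export
overlap_candidates <- function(eqtl_hits, external_list, annotation = NULL,
                               trait_hits = NULL) {
  empty <- data.frame(gene_id = character(), p = numeric(), statistic = numeric(),
                      positions = character(), mito_gwas_traits = character(),
                      external_traits = character(), is_mitocarta = logical(),
                      stringsAsFactors = FALSE)
  if (is.null(external_list) || nrow(external_list) == 0) {
    warning("empty external gene list; no overlap candidates")
    return(empty)
  }
  common <- intersect(eqtl_hits$feature_id, external_list$gene_id)
  if (!length(common)) return(empty)
  marker_traits <- NULL
  if (!is.null(trait_hits) && nrow(trait_hits) > 0) {
    marker_traits <- do.call(rbind, lapply(seq_len(nrow(trait_hits)), function(i) {
      data.frame(marker = strsplit(trait_hits$markers_significant[i], ",")[[1]],
                 trait = trait_hits$feature_id[i], stringsAsFactors = FALSE)
    }))
  }
  rows <- lapply(common, function(g) {
    h <- eqtl_hits[eqtl_hits$feature_id == g, , drop = FALSE][1, ]
    mks <- strsplit(h$markers_significant, ",")[[1]]
    gtr <- if (!is.null(marker_traits)) {
      sort(unique(marker_traits$trait[marker_traits$marker %in% mks]))
    } else character(0)
    ext <- sort(unique(external_list$external_trait[external_list$gene_id == g]))
    mito <- if (!is.null(annotation)) {
      isTRUE(annotation$is_mitocarta[match(g, annotation$gene_id)])
    } else NA
    data.frame(gene_id = g, p = h$min_p, statistic = h$best_statistic,
               positions = h$positions_significant,
               mito_gwas_traits = paste(gtr, collapse = ","),
               external_traits = paste(ext, collapse = ","),
               is_mitocarta = mito, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets from a GMT file
#' @param path GMT path (name, description, then gene ids, tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) strsplit(l, "\t", fixed = TRUE)[[1]][1],
                       character(1))
  out
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
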