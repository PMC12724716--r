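#' Trait-GWAS over mitochondrial markers
#'
#' The full trait path: impute genotypes, compute one permutation threshold
#' per family-wise error level, then per treatment arm z-transform each trait,
#' residualize on sex and experimenter, collapse to strain means, scan every
#' trait against every marker, and call hits at each threshold. The two arms
#' are processed independently.
#'
#' @param ds a `cc_dataset` (or any list with the same components).
#' @param fwer_levels FWER levels (default `c(0.01, 0.05)`).
#' @param n_perm permutations per threshold.
#' @param seed integer seed for the permutation streams.
#' @param out_dir optional directory for TSV outputs.
#' @return list: `genotypes`, `thresholds` (one per level), `scans` (per arm),
#'   `hits` (per arm, per level).
#' @export
run_trait_gwas <- function(ds, fwer_levels = c(0.01, 0.05), n_perm = 1000,
                           seed = 1L, out_dir = NULL) {
  g <- ds$genotypes
  if (is.null(g)) g <- impute_genotypes(ds$strain_table, ds$marker_table)
  thresholds <- lapply(fwer_levels, function(a) {
    permutation_threshold(g, fwer_level = a, n_perm = n_perm, seed = seed)
  })
  names(thresholds) <- sprintf("fwer_%g", fwer_levels)
  arms <- ds$config$arms
  scans <- list(); hits <- list()
  for (arm in arms) {
    feats <- prepare_trait_matrix(ds$trait_table, ds$sample_table, arm)
    sc <- scan_markers(feats, g, arm = arm)
    scans[[arm]] <- sc
    hits[[arm]] <- lapply(thresholds, function(th) significant_hits(sc, th))
  }
  res <- list(genotypes = g, thresholds = thresholds, scans = scans, hits = hits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (arm in arms) {
      write_tsv(scans[[arm]], file.path(out_dir, sprintf("gwas_scan_%s.tsv", arm)))
      for (lvl in names(hits[[arm]])) {
        write_tsv(hits[[arm]][[lvl]],
                  file.path(out_dir, sprintf("gwas_hits_%s_%s.tsv", arm, lvl)))
      }
    }
    thr_tab <- data.frame(level = names(thresholds),
                          fwer = fwer_levels,
                          p_threshold = vapply(thresholds, `[[`, numeric(1),
                                               "p_threshold"),
                          n_perm = n_perm, seed = seed)
    write_tsv(thr_tab, file.path(out_dir, "gwas_thresholds.tsv"))
  }
  res
}

#' Trans-eQTL scan with enrichment and dual-genome overlap
#'
#' The expression path: filter and normalize counts, residualize on sex and
#' plate, collapse to strain means, scan every retained gene against every
#' marker per arm, and call hits at each FWER level. Downstream, per arm:
#' median-rank aggregation of the signed t statistics across markers, the
#' preranked gene-set enrichment on that ranking, and the hypergeometric
#' MitoCarta over-representation among hits. Across arms: a Wilcoxon
#' rank-shift test on the ranking positions of MitoCarta genes. When an
#' external gene list is present, hits of the stress arm are intersected with
#' it into the candidate table.
#'
#' @param ds a `cc_dataset`.
#' @param fwer_levels FWER levels; `hits_level` selects the level used for
#'   enrichment/overlap (default 0.05).
#' @param n_perm permutations for the association threshold.
#' @param gsea_n_perm label permutations for the enrichment null.
#' @param seed integer seed.
#' @param hits_level FWER level driving hit-based stages.
#' @param trait_gwas optional result of [run_trait_gwas()] used to label
#'   overlap candidates with mito-GWAS traits (hits at `hits_level`).
#' @param out_dir optional directory for TSV outputs.
#' @return list with elements `genotypes`, `thresholds`, `scans`, `hits`,
#'   `ranked`, `gsea`, `overrepresentation`, `rank_shift_p`, `mitocarta_counts`,
#'   `candidates`.
#' @export
run_trans_eqtl <- function(ds, fwer_levels = c(0.01, 0.05), n_perm = 1000,
                           gsea_n_perm = 1000, seed = 1L, hits_level = 0.05,
                           trait_gwas = NULL, out_dir = NULL) {
  if (is.null(ds$counts)) stop("dataset has no count matrix", call. = FALSE)
  g <- ds$genotypes
  if (is.null(g)) g <- impute_genotypes(ds$strain_table, ds$marker_table)
  thresholds <- lapply(fwer_levels, function(a) {
    permutation_threshold(g, fwer_level = a, n_perm = n_perm, seed = seed)
  })
  names(thresholds) <- sprintf("fwer_%g", fwer_levels)
  lvl_key <- sprintf("fwer_%g", hits_level)
  if (!lvl_key %in% names(thresholds)) {
    stop("hits_level must be one of fwer_levels", call. = FALSE)
  }
  arms <- ds$config$arms
  scans <- list(); hits <- list(); ranked <- list(); gsea <- list(); over <- list()
  mito_genes <- if (!is.null(ds$gene_table)) {
    ds$gene_table$gene_id[ds$gene_table$is_mitocarta]
  } else character(0)
  for (arm in arms) {
    feats <- prepare_expression_matrix(ds$counts, ds$sample_table, arm)
    sc <- scan_markers(feats, g, arm = arm)
    scans[[arm]] <- sc
    hits[[arm]] <- lapply(thresholds, function(th) significant_hits(sc, th))
    tmat <- stats::xtabs(statistic ~ feature_id + marker_id, data = sc)
    tmat <- as.matrix(unclass(tmat))  # genes x markers signed t
    ranked[[arm]] <- aggregate_ranks_median(tmat)
    if (length(ds$gene_sets)) {
      gsea[[arm]] <- gsea_preranked(ranked[[arm]], ds$gene_sets,
                                    n_perm = gsea_n_perm, seed = seed)
    }
    universe <- colnames(feats)
    over[[arm]] <- overrepresentation_test(hits[[arm]][[lvl_key]]$feature_id,
                                           universe, mito_genes)
  }
  # rank positions of MitoCarta genes in each arm's ranking, compared across arms
  rank_shift_p <- NA_real_
  if (length(mito_genes) && length(arms) == 2) {
    pos <- lapply(arms, function(arm) {
      which(ranked[[arm]]$gene_id %in% mito_genes)
    })
    if (all(lengths(pos) > 0)) {
      rank_shift_p <- rank_shift_test(pos[[2]], pos[[1]])
    }
  }
  mito_counts <- do.call(rbind, lapply(arms, function(arm) {
    h <- hits[[arm]][[lvl_key]]$feature_id
    data.frame(arm = arm, n_hits = length(h),
               n_mitocarta = length(intersect(h, mito_genes)),
               n_other = length(setdiff(h, mito_genes)),
               overrepresentation_p = over[[arm]]$p,
               stringsAsFactors = FALSE)
  }))
  stress_arm <- arms[2]
  candidates <- NULL
  if (!is.null(ds$external_genes)) {
    trait_hits <- if (!is.null(trait_gwas)) {
      trait_gwas$hits[[stress_arm]][[lvl_key]]
    } else NULL
    candidates <- overlap_candidates(hits[[stress_arm]][[lvl_key]],
                                     ds$external_genes, ds$gene_table,
                                     trait_hits)
  } else {
    warning("no external gene list; overlap stage skipped")
  }
  res <- list(genotypes = g, thresholds = thresholds, scans = scans,
              hits = hits, ranked = ranked, gsea = gsea,
              overrepresentation = over, rank_shift_p = rank_shift_p,
              mitocarta_counts = mito_counts, candidates = candidates)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (arm in arms) {
      write_tsv(scans[[arm]], file.path(out_dir, sprintf("eqtl_scan_%s.tsv", arm)))
      write_tsv(hits[[arm]][[lvl_key]],
                file.path(out_dir, sprintf("eqtl_hits_%s.tsv", arm)))
      write_tsv(ranked[[arm]], file.path(out_dir, sprintf("eqtl_ranked_%s.tsv", arm)))
      if (!is.null(gsea[[arm]])) {
        write_tsv(gsea[[arm]], file.path(out_dir, sprintf("eqtl_gsea_%s.tsv", arm)))
      }
    }
    write_tsv(mito_counts, file.path(out_dir, "eqtl_mitocarta_counts.tsv"))
    if (!is.null(candidates)) {
      write_tsv(candidates, file.path(out_dir, "eqtl_overlap_candidates.tsv"))
    }
  }
  res
}

#' Trait/sequence dendrogram comparison
#'
#' For each trait class (static, dynamic) and each treatment arm: build the
#' haplotype-level trait matrix (mean of preprocessed strain means per
#' haplotype), cluster it, cluster the founder sequence p-distances, untangle,
#' and report the entanglement score and tree-vs-tree cophenetic correlation.
#'
#' @param ds a `cc_dataset`.
#' @param L entanglement exponent.
#' @param linkage linkage for both trees.
#' @param out_dir optional directory; writes the stats table and Newick trees.
#' @return list: `stats` (data.frame with one row per class x arm),
#'   `details` (full comparison objects, named `<class>_<arm>`).
#' @export
run_dendro_compare <- function(ds, L = 1.5, linkage = "average",
                               out_dir = NULL) {
  D <- sequence_distance(ds$founder_sequences)
  hap_of <- stats::setNames(ds$strain_table$haplotype, ds$strain_table$strain_id)
  classes <- list(static = ds$config$traits_static,
                  dynamic = ds$config$traits_dynamic)
  classes <- classes[lengths(classes) > 0]
  rows <- list(); details <- list()
  for (cls in names(classes)) {
    for (arm in ds$config$arms) {
      sm <- prepare_trait_matrix(ds$trait_table, ds$sample_table, arm,
                                 traits = classes[[cls]])
      hap <- hap_of[rownames(sm)]
      hm <- apply(sm, 2, function(v) tapply(v, hap, mean, na.rm = TRUE))
      cmp <- compare_trait_sequence_trees(hm, D, L = L, linkage = linkage)
      key <- sprintf("%s_%s", cls, arm)
      details[[key]] <- cmp
      rows[[key]] <- data.frame(trait_class = cls, arm = arm,
                                entanglement = cmp$entanglement,
                                cpcc = cmp$cpcc, stringsAsFactors = FALSE)
    }
  }
  stats_tab <- do.call(rbind, rows)
  rownames(stats_tab) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(stats_tab, file.path(out_dir, "dendro_stats.tsv"))
    for (key in names(details)) {
      write_newick(details[[key]]$tree_traits,
                   file.path(out_dir, sprintf("tree_traits_%s.nwk", key)))
      write_newick(details[[key]]$tree_sequences,
                   file.path(out_dir, sprintf("tree_sequences_%s.nwk", key)))
    }
  }
  list(stats = stats_tab, details = details)
}

#' Run the full pipeline on a synthetic configuration
#'
#' Generates (or accepts) a dataset, runs the trait-GWAS, the trans-eQTL +
#' enrichment + overlap analysis, and the dendrogram comparison, writes all
#' tables under `out_dir`, and finishes with a run manifest (JSON) recording
#' the configuration echo, package version, seeds, timestamps, and the MD5
#' hash of every file written. Two runs with the same config and seed produce
#' identical file hashes.
#'
#' @param config a [sim_config()] (ignored when `ds` is supplied).
#' @param out_dir output directory.
#' @param seed integer seed for permutation/enrichment streams.
#' @param n_perm,gsea_n_perm permutation counts.
#' @param fwer_levels FWER levels.
#' @param ds optional pre-generated `cc_dataset`.
#' @return invisibly, a list with all stage results and the manifest.
#' @export
run_all <- function(config = sim_config(), out_dir, seed = 1L, n_perm = 1000,
                    gsea_n_perm = 500, fwer_levels = c(0.01, 0.05), ds = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(ds)) ds <- generate_dataset(config)
  write_dataset(ds, file.path(out_dir, "data"))
  gwas <- run_trait_gwas(ds, fwer_levels = fwer_levels, n_perm = n_perm,
                         seed = seed, out_dir = file.path(out_dir, "gwas"))
  eqtl <- if (!is.null(ds$counts)) {
    run_trans_eqtl(ds, fwer_levels = fwer_levels, n_perm = n_perm,
                   gsea_n_perm = gsea_n_perm, seed = seed,
                   trait_gwas = gwas, out_dir = file.path(out_dir, "eqtl"))
  }
  dendro <- run_dendro_compare(ds, out_dir = file.path(out_dir, "dendro"))
  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  hashes <- tools::md5sum(files)
  manifest <- list(
    package = "ccmito",
    version = as.character(utils::packageVersion("ccmito")),
    seed = seed, n_perm = n_perm, gsea_n_perm = gsea_n_perm,
    fwer_levels = fwer_levels,
    config = ds$config[!vapply(ds$config, is.null, logical(1))],
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    file_hashes = as.list(stats::setNames(unname(hashes),
                                          sub(paste0("^", out_dir, "/?"), "",
                                              files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dataset = ds, gwas = gwas, eqtl = eqtl, dendro = dendro,
                 manifest = manifest))
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file whose keys are [sim_config()] arguments plus optional
#' run parameters (`n_perm`, `gsea_n_perm`, `fwer_levels`, `seed`,
#' `out_dir`). Planted effect tables may be given as lists of mappings.
#'
#' @param path YAML path.
#' @return list with elements `config` (a `sim_config`) and `run` (the run
#'   parameters).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_keys <- c("n_perm", "gsea_n_perm", "fwer_levels", "out_dir")
  run <- y[intersect(names(y), run_keys)]
  cfg_args <- y[setdiff(names(y), run_keys)]
  for (k in c("planted_trait_effects", "planted_eqtl_effects")) {
    if (!is.null(cfg_args[[k]])) {
      cfg_args[[k]] <- do.call(rbind, lapply(cfg_args[[k]], as.data.frame))
    }
  }
  if (!is.null(cfg_args$strains_per_haplotype)) {
    cfg_args$strains_per_haplotype <- unlist(cfg_args$strains_per_haplotype)
  }
  if (!is.null(cfg_args$haplotype_trait_alignment)) {
    cfg_args$haplotype_trait_alignment <- unlist(cfg_args$haplotype_trait_alignment)
  }
  list(config = do.call(sim_config, cfg_args), run = run)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
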