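#' Simulation configuration for a CC-like cohort
#'
#' Builds and validates the configuration object consumed by
#' [generate_dataset()]. The defaults mirror the structure of a Collaborative
#' Cross heart-failure cohort: 63 inbred strains carrying one of 8 maternally
#' inherited mitochondrial founder haplotypes (A-H), 21 mitochondrial markers
#' falling into a small number of distinct strain-distribution patterns, two
#' treatment arms (saline control vs isoproterenol stress), and animal-level
#' nuisance structure (sex, experimenter, library plate).
#'
#' Planted effects are the simulation's ground truth: each row of
#' `planted_trait_effects` adds `effect * noise_sd` to the trait of every
#' animal in `arm` whose strain carries the minor allele at `marker`; each row
#' of `planted_eqtl_effects` multiplies the expected count of `gene` by
#' `2^log2_effect` for minor-allele strains in `arm`.
#'
#' @param n_strains number of CC strains.
#' @param founders ordered haplotype labels (length 8 by convention).
#' @param strains_per_haplotype named integer vector summing to `n_strains`;
#'   default spreads strains as evenly as possible across founders.
#' @param n_markers number of mitochondrial markers.
#' @param n_patterns number of distinct founder strain-distribution patterns
#'   among the markers; markers within a pattern are perfectly correlated.
#' @param animals_per_strain_arm animals per strain per treatment arm.
#' @param arms treatment arm labels (fixed pair, control first).
#' @param n_experimenters,n_plates nuisance factor levels.
#' @param traits_static,traits_dynamic trait names for the two trait classes
#'   (organ weights/structure vs longitudinal echocardiography deltas).
#' @param n_genes number of nuclear genes in the count matrix.
#' @param mitocarta_fraction fraction of genes flagged as MitoCarta members.
#' @param planted_trait_effects data.frame with columns
#'   `marker`, `trait`, `arm`, `effect` (residual-SD units), or NULL.
#' @param planted_eqtl_effects data.frame with columns
#'   `marker`, `gene`, `arm`, `log2_effect`, or NULL.
#' @param haplotype_trait_alignment named numeric (one entry per arm): strength
#'   of haplotype-level trait effects aligned with founder sequence distances
#'   (0 disables; used to emulate an arm whose traits track mt-DNA relatedness).
#' @param strain_sd,noise_sd,sex_effect_sd,batch_effect_sd standard deviations
#'   of the trait model components (trait units).
#' @param nb_dispersion negative-binomial dispersion (1/size) shared by genes.
#' @param planted_gene_base_mean baseline mean count forced for planted eQTL
#'   genes so they survive expression filtering.
#' @param mt_genome_length circular mitochondrial genome length in bp.
#' @param sequence_length length of the simulated founder mt-DNA alignment.
#' @param n_private_mutations private substitutions per founder sequence.
#' @param n_gene_sets,gene_set_size synthetic gene-set collection shape.
#' @param n_external_genes size of the simulated external nuclear eQTL list.
#' @param seed integer seed; all randomness flows from it via per-stage
#'   child seeds.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 63,
                       founders = LETTERS[1:8],
                       strains_per_haplotype = NULL,
                       n_markers = 21,
                       n_patterns = 4,
                       animals_per_strain_arm = 2,
                       arms = c("Ctrl", "Iso"),
                       n_experimenters = 3,
                       n_plates = 5,
                       traits_static = c("THW", "LVW", "RVW", "LAW", "RAW", "CSA"),
                       traits_dynamic = c("dEF", "dFS", "dHR"),
                       n_genes = 200,
                       mitocarta_fraction = 0.1,
                       planted_trait_effects = NULL,
                       planted_eqtl_effects = NULL,
                       haplotype_trait_alignment = NULL,
                       strain_sd = 0.5,
                       noise_sd = 1,
                       sex_effect_sd = 0.25,
                       batch_effect_sd = 0.25,
                       nb_dispersion = 0.1,
                       planted_gene_base_mean = 500,
                       mt_genome_length = 16299,
                       sequence_length = 400,
                       n_private_mutations = 4,
                       n_gene_sets = 10,
                       gene_set_size = 20,
                       n_external_genes = 30,
                       seed = 1L) {
  if (is.null(strains_per_haplotype)) {
    base <- n_strains %/% length(founders)
    extra <- n_strains %% length(founders)
    strains_per_haplotype <- stats::setNames(
      rep(base, length(founders)) + c(rep(1L, extra), rep(0L, length(founders) - extra)),
      founders
    )
  }
  if (is.null(haplotype_trait_alignment)) {
    haplotype_trait_alignment <- stats::setNames(rep(0, length(arms)), arms)
  }
  cfg <- list(
    n_strains = as.integer(n_strains), founders = founders,
    strains_per_haplotype = strains_per_haplotype,
    n_markers = as.integer(n_markers), n_patterns = as.integer(n_patterns),
    animals_per_strain_arm = as.integer(animals_per_strain_arm), arms = arms,
    n_experimenters = as.integer(n_experimenters), n_plates = as.integer(n_plates),
    traits_static = traits_static, traits_dynamic = traits_dynamic,
    n_genes = as.integer(n_genes), mitocarta_fraction = mitocarta_fraction,
    planted_trait_effects = planted_trait_effects,
    planted_eqtl_effects = planted_eqtl_effects,
    haplotype_trait_alignment = haplotype_trait_alignment,
    strain_sd = strain_sd, noise_sd = noise_sd,
    sex_effect_sd = sex_effect_sd, batch_effect_sd = batch_effect_sd,
    nb_dispersion = nb_dispersion,
    planted_gene_base_mean = planted_gene_base_mean,
    mt_genome_length = as.integer(mt_genome_length),
    sequence_length = as.integer(sequence_length),
    n_private_mutations = as.integer(n_private_mutations),
    n_gene_sets = as.integer(n_gene_sets), gene_set_size = as.integer(gene_set_size),
    n_external_genes = as.integer(n_external_genes),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
  }
  if (cfg$n_strains < 1) fail("n_strains", "must be >= 1")
  if (length(cfg$founders) < 2) fail("founders", "need at least 2 haplotype labels")
  if (anyDuplicated(cfg$founders)) fail("founders", "labels must be unique")
  sph <- cfg$strains_per_haplotype
  if (!setequal(names(sph), cfg$founders)) {
    fail("strains_per_haplotype", "names must match the founder labels")
  }
  if (sum(sph) != cfg$n_strains) {
    fail("strains_per_haplotype", sprintf("must sum to n_strains (%d), got %d",
                                          cfg$n_strains, sum(sph)))
  }
  if (cfg$n_patterns > cfg$n_markers) fail("n_patterns", "cannot exceed n_markers")
  if (cfg$n_patterns < 1) fail("n_patterns", "must be >= 1")
  if (length(cfg$arms) != 2) fail("arms", "exactly two treatment arms expected")
  for (f in c("strain_sd", "noise_sd", "sex_effect_sd", "batch_effect_sd")) {
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  if (cfg$nb_dispersion <= 0) fail("nb_dispersion", "must be > 0")
  if (cfg$sequence_length < cfg$n_markers) {
    fail("sequence_length", "must be >= n_markers")
  }
  traits <- c(cfg$traits_static, cfg$traits_dynamic)
  if (anyDuplicated(traits)) fail("traits_static", "trait names must be unique")
  pte <- cfg$planted_trait_effects
  if (!is.null(pte)) {
    need <- c("marker", "trait", "arm", "effect")
    if (!all(need %in% names(pte))) {
      fail("planted_trait_effects", "needs columns marker, trait, arm, effect")
    }
    if (!all(pte$trait %in% traits)) {
      fail("planted_trait_effects", "references an undeclared trait")
    }
    if (!all(pte$arm %in% cfg$arms)) fail("planted_trait_effects", "unknown arm")
    if (!all(marker_index_ok(pte$marker, cfg$n_markers))) {
      fail("planted_trait_effects", "references an undeclared marker")
    }
  }
  pee <- cfg$planted_eqtl_effects
  if (!is.null(pee)) {
    need <- c("marker", "gene", "arm", "log2_effect")
    if (!all(need %in% names(pee))) {
      fail("planted_eqtl_effects", "needs columns marker, gene, arm, log2_effect")
    }
    if (!all(pee$gene %in% gene_ids(cfg$n_genes))) {
      fail("planted_eqtl_effects", "references an undeclared gene")
    }
    if (!all(pee$arm %in% cfg$arms)) fail("planted_eqtl_effects", "unknown arm")
    if (!all(marker_index_ok(pee$marker, cfg$n_markers))) {
      fail("planted_eqtl_effects", "references an undeclared marker")
    }
  }
  if (!all(cfg$arms %in% names(cfg$haplotype_trait_alignment))) {
    fail("haplotype_trait_alignment", "needs one named entry per arm")
  }
  invisible(cfg)
}

marker_ids <- function(n) sprintf("Mit%03d", seq_len(n))
gene_ids <- function(n) sprintf("G%04d", seq_len(n))
marker_index_ok <- function(marker, n_markers) marker %in% marker_ids(n_markers)

# Per-stage child seeds, all derived from the master seed.
child_seeds <- function(seed, n = 8L) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Founder allele bipartitions used as marker strain-distribution patterns
#'
#' The first seven patterns are balanced, mutually orthogonal 4/4 splits of the
#' eight founders (parity patterns); they make dosage columns of distinct
#' patterns uncorrelated under balanced strain counts, the regime in which the
#' permutation threshold has a closed-form Sidak limit. Patterns beyond seven
#' are random non-constant subsets.
#' @noRd
founder_patterns <- function(n_patterns, founders, seed) {
  n_f <- length(founders)
  pats <- list()
  if (n_f == 8) {
    for (m in 1:7) {
      if (length(pats) >= n_patterns) break
      # parity of the bits of (i AND m): balanced, mutually orthogonal splits
      bits <- vapply(0:7, function(i) {
        x <- bitwAnd(i, m)
        (sum(bitwAnd(x, 1L) > 0, bitwAnd(x, 2L) > 0, bitwAnd(x, 4L) > 0)) %% 2
      }, numeric(1))
      pats[[length(pats) + 1L]] <- as.logical(bits)
    }
  }
  set.seed(seed)
  canon <- function(p) {
    # complementary columns carry the same pattern; canonicalise on first entry
    if (p[1]) paste(!p, collapse = "") else paste(p, collapse = "")
  }
  seen <- vapply(pats, canon, character(1))
  while (length(pats) < n_patterns) {
    k <- sample(seq_len(n_f - 1L), 1L)
    p <- rep(FALSE, n_f)
    p[sample.int(n_f, k)] <- TRUE
    key <- canon(p)
    if (!key %in% seen) {
      pats[[length(pats) + 1L]] <- p
      seen <- c(seen, key)
    }
  }
  lapply(pats[seq_len(n_patterns)], function(p) stats::setNames(p, founders))
}

#' Generate aligned founder mitochondrial sequences
#'
#' Produces one sequence per founder on a common random backbone. Marker
#' alleles are written at dedicated alignment columns (one per marker), so
#' pairwise sequence differences embed the marker strain-distribution
#' patterns; each founder additionally receives a fixed number of private
#' substitutions. All sequences are equal length over {A,C,G,T}.
#'
#' @param config a [sim_config()] object.
#' @param marker_table optional marker table (as built by [generate_dataset()]);
#'   generated from the config when omitted.
#' @return named character vector of aligned sequences, one per founder.
#' @export
generate_founder_sequences <- function(config, marker_table = NULL) {
  if (config$sequence_length < config$n_markers) {
    stop("sequence_length must be >= n_markers", call. = FALSE)
  }
  seeds <- child_seeds(config$seed)
  if (is.null(marker_table)) marker_table <- build_marker_table(config)
  set.seed(seeds[3])
  L <- config$sequence_length
  bases <- c("A", "C", "G", "T")
  backbone <- sample(bases, L, replace = TRUE)
  sites <- sort(sample.int(L, config$n_markers))
  founders <- config$founders
  seqs <- lapply(founders, function(f) {
    s <- backbone
    s[sites] <- marker_table[[paste0("allele_", f)]]
    s
  })
  names(seqs) <- founders
  # per-founder private substitution counts vary around n_private_mutations
  # (mt lineages diverge unequally -- wild-derived founders carry many more
  # private variants than classical ones); unequal counts also keep pairwise
  # distances generically untied so the founder tree is well determined
  free_sites <- setdiff(seq_len(L), sites)
  n_f <- length(founders)
  n_priv <- config$n_private_mutations
  counts <- if (n_priv == 0) rep(0L, n_f) else {
    sample(0:(2L * n_priv), n_f, replace = (2L * n_priv + 1L) < n_f)
  }
  for (i in seq_along(founders)) {
    f <- founders[i]
    if (counts[i] == 0) next
    mut <- sample(free_sites, min(counts[i], length(free_sites)))
    for (m in mut) {
      cur <- seqs[[f]][m]
      seqs[[f]][m] <- sample(setdiff(bases, cur), 1L)
    }
    free_sites <- setdiff(free_sites, mut)
  }
  vapply(seqs, paste, character(1), collapse = "")
}

# Haplotype effect matrix (founders x n_traits) whose per-column z-scored
# euclidean row distances are proportional to the given distance matrix.
# Construction: factor the doubly centered Gram matrix B = -J D^2 J / 2 as
# U diag(lambda) U', draw a random row-orthonormal mixing matrix R (column
# rotations leave the Gram, hence the distances, unchanged), then equalize the
# column energies e_j = sum_k lambda_k R_kj^2 by pairwise column rotations so
# that the final per-column standardization is a uniform rescaling. With
# n_traits below the embedding dimension the top axes are kept (approximate).
align_effect_matrix <- function(D, n_traits) {
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% (D^2) %*% J
  ev <- eigen(B, symmetric = TRUE)
  keep <- ev$values > max(ev$values) * 1e-9
  lam <- ev$values[keep]
  U <- ev$vectors[, keep, drop = FALSE]
  if (n_traits < length(lam)) {
    lam <- lam[seq_len(n_traits)]
    U <- U[, seq_len(n_traits), drop = FALSE]
  }
  k <- length(lam)
  R <- t(qr.Q(qr(matrix(stats::rnorm(n_traits * k), n_traits, k))))  # k x T
  energy <- function(col) sum(lam * col^2)
  for (it in seq_len(500)) {
    e <- colSums(lam * R^2)
    hi <- which.max(e); lo <- which.min(e)
    if (e[hi] - e[lo] < 1e-10 * mean(e)) break
    u <- R[, hi]; v <- R[, lo]
    tgt <- (e[hi] + e[lo]) / 2
    f <- function(th) energy(cos(th) * u + sin(th) * v) - tgt
    th <- stats::uniroot(f, c(0, pi / 2), tol = 1e-12)$root
    R[, hi] <- cos(th) * u + sin(th) * v
    R[, lo] <- -sin(th) * u + cos(th) * v
  }
  E <- U %*% (sqrt(lam) * R)
  E <- sweep(E, 2, apply(E, 2, stats::sd), "/")
  rownames(E) <- rownames(D)
  E
}

build_marker_table <- function(config) {
  seeds <- child_seeds(config$seed)
  set.seed(seeds[1])
  n_m <- config$n_markers
  pats <- founder_patterns(config$n_patterns, config$founders, seeds[2])
  pattern_of <- ((seq_len(n_m) - 1L) %% config$n_patterns) + 1L
  pos <- sort(sample.int(config$mt_genome_length, n_m))
  bases <- c("A", "C", "G", "T")
  tab <- data.frame(marker_id = marker_ids(n_m), position_bp = pos,
                    stringsAsFactors = FALSE)
  allele_cols <- matrix("", n_m, length(config$founders))
  for (i in seq_len(n_m)) {
    ra <- sample(bases, 2L)
    p <- pats[[pattern_of[i]]]
    allele_cols[i, ] <- ifelse(p, ra[2], ra[1])
  }
  colnames(allele_cols) <- paste0("allele_", config$founders)
  tab <- cbind(tab, as.data.frame(allele_cols, stringsAsFactors = FALSE))
  tab$pattern <- pattern_of
  tab
}

build_strain_table <- function(config) {
  hap <- rep(names(config$strains_per_haplotype), config$strains_per_haplotype)
  data.frame(strain_id = sprintf("CC%03d", seq_len(config$n_strains)),
             haplotype = hap, stringsAsFactors = FALSE)
}

build_sample_table <- function(config, strain_table) {
  rows <- expand.grid(animal = seq_len(config$animals_per_strain_arm),
                      arm = config$arms, strain_id = strain_table$strain_id,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$strain_id, rows$arm, rows$animal), , drop = FALSE]
  # sex alternates within strain; experimenter and plate are round-robin,
  # which keeps every covariate estimable in every arm
  within_strain <- stats::ave(seq_len(nrow(rows)), rows$strain_id, FUN = seq_along)
  sex <- ifelse(within_strain %% 2 == 1, "M", "F")
  data.frame(
    sample_id = sprintf("%s_%s_%d", rows$strain_id, rows$arm, rows$animal),
    strain_id = rows$strain_id,
    sex = sex,
    treatment = rows$arm,
    experimenter = paste0("E", ((seq_len(nrow(rows)) - 1L) %% config$n_experimenters) + 1L),
    plate = paste0("P", ((seq_len(nrow(rows)) - 1L) %% config$n_plates) + 1L),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic CC-like dataset
#'
#' Simulates the full input bundle of the mito-nuclear analysis: strain and
#' marker tables, animal-level sample metadata, trait values, a
#' negative-binomial nuclear expression count matrix, aligned founder
#' mitochondrial sequences, a synthetic gene-set collection, an external
#' nuclear eQTL gene list, and a truth registry of every planted effect.
#'
#' Trait model per animal: per-trait sex coefficient + experimenter batch
#' effect + per-(strain, trait) random effect + planted marker effects (via
#' the strain's haplotype allele, in the planted arm only) + optional
#' haplotype effects aligned with founder sequence distances + Gaussian noise.
#' Counts are negative binomial with log-normal gene baselines and log-scale
#' sex/plate/planted-eQTL effects. A fixed seed yields a bit-identical dataset.
#'
#' @param config a [sim_config()] object.
#' @return a list of class `cc_dataset`.
#' @export
generate_dataset <- function(config) {
  validate_sim_config(config)
  seeds <- child_seeds(config$seed)
  strain_table <- build_strain_table(config)
  marker_table <- build_marker_table(config)
  sample_table <- build_sample_table(config, strain_table)
  founder_sequences <- generate_founder_sequences(config, marker_table)
  genotypes <- impute_genotypes(strain_table, marker_table,
                                founders = config$founders)

  traits <- c(config$traits_static, config$traits_dynamic)
  n_samp <- nrow(sample_table)
  hap_of_strain <- stats::setNames(strain_table$haplotype, strain_table$strain_id)

  # haplotype-level alignment effects embedding the sequence relatedness.
  # The planted target is the cophenetic (ultrametric) distance of the founder
  # sequence UPGMA tree: ultrametrics embed exactly in euclidean space, and
  # average-linkage clustering of the embedded points reproduces the sequence
  # tree. One embedding block is drawn per trait class so that each class on
  # its own (and any union of classes) carries distances proportional to the
  # planted structure.
  align_mat <- NULL
  if (any(config$haplotype_trait_alignment > 0) && length(traits) > 0) {
    D <- sequence_distance(founder_sequences)
    C <- cophenetic_matrix(hcluster(D, distance = "precomputed",
                                    linkage = "average"))
    C <- C[rownames(D), rownames(D)]
    set.seed(seeds[8])
    blocks <- lapply(list(config$traits_static, config$traits_dynamic),
                     function(tr) {
                       if (length(tr) == 0) return(NULL)
                       align_effect_matrix(C, length(tr))
                     })
    align_mat <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
  }

  set.seed(seeds[4])
  trait_mat <- matrix(NA_real_, n_samp, length(traits),
                      dimnames = list(sample_table$sample_id, traits))
  dos <- genotypes$dosage
  for (j in seq_along(traits)) {
    tr <- traits[j]
    sex_coef <- stats::rnorm(1, 0, config$sex_effect_sd)
    exp_lev <- sort(unique(sample_table$experimenter))
    exp_eff <- stats::setNames(stats::rnorm(length(exp_lev), 0, config$batch_effect_sd),
                               exp_lev)
    strain_eff <- stats::setNames(stats::rnorm(config$n_strains, 0, config$strain_sd),
                                  strain_table$strain_id)
    y <- sex_coef * (sample_table$sex == "M") +
      exp_eff[sample_table$experimenter] +
      strain_eff[sample_table$strain_id] +
      stats::rnorm(n_samp, 0, config$noise_sd)
    pte <- config$planted_trait_effects
    if (!is.null(pte)) {
      for (r in which(pte$trait == tr)) {
        d <- dos[sample_table$strain_id, pte$marker[r]]
        in_arm <- sample_table$treatment == pte$arm[r]
        y <- y + pte$effect[r] * config$noise_sd * d * in_arm
      }
    }
    if (!is.null(align_mat)) {
      hap_eff <- align_mat[, j]
      names(hap_eff) <- rownames(align_mat)
      for (arm in config$arms) {
        s <- config$haplotype_trait_alignment[[arm]]
        if (s > 0) {
          in_arm <- sample_table$treatment == arm
          y[in_arm] <- y[in_arm] +
            s * config$noise_sd * hap_eff[hap_of_strain[sample_table$strain_id[in_arm]]]
        }
      }
    }
    trait_mat[, j] <- y
  }
  trait_table <- data.frame(sample_id = sample_table$sample_id,
                            trait_mat, stringsAsFactors = FALSE,
                            check.names = FALSE)

  # expression counts: genes x samples
  set.seed(seeds[5])
  genes <- gene_ids(config$n_genes)
  counts <- NULL
  gene_table <- NULL
  base_mean <- numeric(0)
  if (config$n_genes > 0) {
    base_mean <- exp(stats::rnorm(config$n_genes, log(100), 1.2))
    names(base_mean) <- genes
    pee <- config$planted_eqtl_effects
    if (!is.null(pee)) base_mean[unique(pee$gene)] <- config$planted_gene_base_mean
    sex_coef_g <- stats::rnorm(config$n_genes, 0, config$sex_effect_sd)
    plate_lev <- sort(unique(sample_table$plate))
    plate_eff <- matrix(stats::rnorm(config$n_genes * length(plate_lev), 0,
                                     config$batch_effect_sd),
                        config$n_genes, length(plate_lev),
                        dimnames = list(genes, plate_lev))
    log2mu <- matrix(log2(base_mean), config$n_genes, n_samp) +
      outer(sex_coef_g, as.numeric(sample_table$sex == "M")) +
      plate_eff[, sample_table$plate]
    if (!is.null(pee)) {
      for (r in seq_len(nrow(pee))) {
        d <- dos[sample_table$strain_id, pee$marker[r]]
        in_arm <- sample_table$treatment == pee$arm[r]
        log2mu[pee$gene[r], ] <- log2mu[pee$gene[r], ] +
          pee$log2_effect[r] * d * in_arm
      }
    }
    counts <- matrix(stats::rnbinom(length(log2mu), mu = 2^log2mu,
                                    size = 1 / config$nb_dispersion),
                     config$n_genes, n_samp,
                     dimnames = list(genes, sample_table$sample_id))
    is_mito <- stats::runif(config$n_genes) < config$mitocarta_fraction
    gene_table <- data.frame(
      gene_id = genes,
      chromosome = sample(c(as.character(1:19), "X"), config$n_genes, replace = TRUE),
      is_mitocarta = is_mito,
      is_mt_encoded = FALSE,
      stringsAsFactors = FALSE
    )
  }

  # synthetic gene sets; one set seeded with the planted eQTL genes when present
  set.seed(seeds[6])
  gene_sets <- list()
  if (config$n_genes > 0 && config$n_gene_sets > 0) {
    sz <- min(config$gene_set_size, config$n_genes)
    for (i in seq_len(config$n_gene_sets)) {
      gene_sets[[sprintf("SET_%02d", i)]] <- sample(genes, sz)
    }
    pee <- config$planted_eqtl_effects
    if (!is.null(pee)) {
      pg <- unique(pee$gene)
      gene_sets[["SET_PLANTED"]] <-
        unique(c(pg, sample(setdiff(genes, pg), max(0L, sz - length(pg)))))
    }
  }

  # external nuclear eQTL list, guaranteed to include the planted genes
  set.seed(seeds[7])
  external_genes <- NULL
  if (config$n_genes > 0 && config$n_external_genes > 0) {
    pg <- if (!is.null(config$planted_eqtl_effects)) {
      unique(config$planted_eqtl_effects$gene)
    } else character(0)
    pool <- setdiff(genes, pg)
    ext <- c(pg, sample(pool, min(length(pool),
                                  max(0L, config$n_external_genes - length(pg)))))
    vocab <- c("EjectionFraction", "FractionalShortening", "HeartRate",
               "Fibrosis", "HeartWeight", "CellSurfaceArea")
    external_genes <- data.frame(
      gene_id = ext,
      external_trait = sample(vocab, length(ext), replace = TRUE),
      stringsAsFactors = FALSE
    )
  }

  truth <- list(
    trait_effects = config$planted_trait_effects,
    eqtl_effects = config$planted_eqtl_effects,
    gene_base_means = base_mean,
    variance_components = list(strain_sd = config$strain_sd,
                               noise_sd = config$noise_sd,
                               sex_effect_sd = config$sex_effect_sd,
                               batch_effect_sd = config$batch_effect_sd,
                               nb_dispersion = config$nb_dispersion),
    haplotype_trait_alignment = config$haplotype_trait_alignment
  )

  structure(list(config = config, strain_table = strain_table,
                 marker_table = marker_table, sample_table = sample_table,
                 trait_table = trait_table, counts = counts,
                 gene_table = gene_table, gene_sets = gene_sets,
                 founder_sequences = founder_sequences,
                 external_genes = external_genes,
                 genotypes = genotypes, truth = truth),
            class = "cc_dataset")
}

#' @export
print.cc_dataset <- function(x, ...) {
  cat(sprintf("cc_dataset: %d strains / %d haplotypes, %d markers, %d samples, %d genes\n",
              nrow(x$strain_table), length(unique(x$strain_table$haplotype)),
              nrow(x$marker_table), nrow(x$sample_table),
              if (is.null(x$counts)) 0L else nrow(x$counts)))
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits the standard on-disk representation: CSV tables for strains, markers,
#' samples, traits, gene annotation and the external gene list; a TSV count
#' matrix (genes x samples); an aligned FASTA of founder sequences; a GMT
#' gene-set file; and the truth registry as JSON.
#'
#' @param ds a `cc_dataset`.
#' @param dir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  utils::write.csv(ds$strain_table, p("strains.csv"), row.names = FALSE)
  utils::write.csv(ds$marker_table, p("markers.csv"), row.names = FALSE)
  utils::write.csv(ds$sample_table, p("samples.csv"), row.names = FALSE)
  utils::write.csv(ds$trait_table, p("traits.csv"), row.names = FALSE)
  if (!is.null(ds$counts)) {
    utils::write.table(ds$counts, p("counts.tsv"), sep = "\t", quote = FALSE,
                       col.names = NA)
    utils::write.csv(ds$gene_table, p("gene_annotation.csv"), row.names = FALSE)
  }
  if (length(ds$gene_sets)) write_gmt(ds$gene_sets, p("gene_sets.gmt"))
  if (!is.null(ds$external_genes)) {
    utils::write.csv(ds$external_genes, p("external_genes.csv"), row.names = FALSE)
  }
  seqs <- lapply(strsplit(tolower(ds$founder_sequences), ""), identity)
  names(seqs) <- names(ds$founder_sequences)
  ape::write.FASTA(ape::as.DNAbin(seqs), p("founder_sequences.fasta"))
  truth <- ds$truth
  truth$gene_base_means <- as.list(truth$gene_base_means)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(list.files(dir, full.names = TRUE))
}
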