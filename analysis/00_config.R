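# Shared study configuration for the analysis scripts.
#
# A Collaborative Cross-like cohort: 63 strains in 8 mitochondrial haplotypes,
# 21 mitochondrial markers falling into 4 strain-distribution patterns, two
# treatment arms (Ctrl = saline, Iso = isoproterenol stress), 2 animals per
# strain per arm. Planted ground truth drives every downstream stage:
#  - a 1.5-SD effect of marker Mit001 on the change in ejection fraction (dEF),
#    stress arm only (the arm-asymmetric trait association);
#  - 1.5 log2-unit trans-eQTL effects of Mit002 on two nuclear genes, stress
#    arm only.
# The dendrogram stage uses a separate variant whose stress-arm traits are
# aligned with founder mt-DNA relatedness (strength 2): that alignment
# structures every trait by haplotype, which is exactly the signal the
# tanglegram comparison looks for but would swamp the single-trait GWAS demo.

library(ccmito)

STUDY_SEED <- 20260921L
RESULTS <- "results"

study_config <- sim_config(
  n_genes = 400,
  planted_trait_effects = data.frame(
    marker = "Mit001", trait = "dEF", arm = "Iso", effect = 1.5),
  planted_eqtl_effects = data.frame(
    marker = "Mit002", gene = c("G0010", "G0020"), arm = "Iso",
    log2_effect = 1.5),
  seed = STUDY_SEED
)

dendro_config <- sim_config(
  n_genes = 0, n_gene_sets = 0, n_external_genes = 0,
  haplotype_trait_alignment = c(Ctrl = 0, Iso = 2),
  seed = STUDY_SEED
)

study_dataset <- function() generate_dataset(study_config)
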