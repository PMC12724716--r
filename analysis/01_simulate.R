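#!/usr/bin/env Rscript
# Stage 1 -- simulate the cohort and write the raw data bundle.
#
# Generates the synthetic CC-like dataset defined in 00_config.R and writes
# every input table the downstream stages consume (strain/marker/sample
# tables, traits, counts, gene annotation, gene sets, founder FASTA, external
# gene list, truth registry) under results/data/.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_config.R"))

ds <- study_dataset()
print(ds)
files <- write_dataset(ds, file.path(RESULTS, "data"))
cat(sprintf("wrote %d files to %s\n", length(files), file.path(RESULTS, "data")))
cat(sprintf("  distinct marker patterns: %d\n",
            length(unique(distinct_patterns(ds$genotypes)$group))))
cat(sprintf("  planted trait effect: %s -> %s (%s, %.1f SD)\n",
            ds$truth$trait_effects$marker, ds$truth$trait_effects$trait,
            ds$truth$trait_effects$arm, ds$truth$trait_effects$effect))
cat(sprintf("  planted eQTL genes: %s\n",
            paste(ds$truth$eqtl_effects$gene, collapse = ", ")))
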