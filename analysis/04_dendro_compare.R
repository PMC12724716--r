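#!/usr/bin/env Rscript
# Stage 4 -- trait vs mt-DNA sequence dendrogram comparison.
#
# Clusters haplotype-level trait profiles (static and dynamic classes, per
# arm) and founder mt-DNA sequence p-distances, untangles each tree pair, and
# reports the entanglement score and tree-vs-tree cophenetic correlation.
# Because the dendro variant of the study config aligns stress-arm traits
# with sequence relatedness, the Iso rows should show lower entanglement and
# higher CPCC than the Ctrl rows.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_config.R"))

ds <- generate_dataset(dendro_config)
res <- run_dendro_compare(ds, out_dir = file.path(RESULTS, "dendro"))
print(res$stats, row.names = FALSE)
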