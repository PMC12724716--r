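#!/usr/bin/env Rscript
# Stage 2 -- mitochondrial trait-GWAS.
#
# Per treatment arm: z-transform each trait, correct for sex and experimenter,
# collapse to strain means, scan against all 21 markers, and call hits at
# permutation FWER thresholds of 1% and 5%. The planted dEF effect should
# surface in the Iso arm and in the Iso arm only.

source(file.path(dirname(sub("--file=", "", grep("--file=", commandArgs(), value = TRUE))),
                 "00_config.R"))

ds <- study_dataset()
res <- run_trait_gwas(ds, fwer_levels = c(0.01, 0.05), n_perm = 2000,
                      seed = STUDY_SEED + 1L,
                      out_dir = file.path(RESULTS, "gwas"))

for (lvl in names(res$thresholds)) {
  cat(sprintf("%s: p < %.5g\n", lvl, res$thresholds[[lvl]]$p_threshold))
}
for (arm in names(res$hits)) {
  h <- res$hits[[arm]]$fwer_0.01
  cat(sprintf("%s arm, FWER 1%%: %d trait hit(s)%s\n", arm, nrow(h),
              if (nrow(h)) paste0(" -- ", paste(sprintf("%s (p=%.3g, %s)",
                                                        h$feature_id, h$min_p,
                                                        h$best_marker),
                                                collapse = "; ")) else ""))
}
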