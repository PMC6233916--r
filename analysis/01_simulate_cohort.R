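#!/usr/bin/env Rscript
# Simulate the study-shaped cohort: 461 children x 112 allergen components
# (ISU), seven family blocks plus active singletons and rare components,
# an interaction-only asthma signal planted on three singleton pairs.
# Writes the raw inputs every later stage consumes.

library(crdnet)

seed <- 20260927L
outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- emulate_paper_shape(seed = seed)
coh <- generate_cohort(cfg)

write_crd(coh$crd, file.path(outdir, "isu_matrix.csv"))
write.csv(coh$outcomes, file.path(outdir, "outcomes.csv"), row.names = FALSE)
jsonlite::write_json(
  list(component_blocks = coh$truth$component_blocks,
       differential_pairs = coh$truth$differential_pairs,
       seed = seed),
  file.path(outdir, "planted_truth.json"), auto_unbox = TRUE, pretty = TRUE)

message(sprintf("cohort: %d participants x %d components; asthma prevalence %.1f%%",
                nrow(coh$crd), ncol(coh$crd),
                100 * mean(coh$outcomes$asthma)))
message(sprintf("planted differential pairs: %s",
                paste(coh$truth$differential_pairs$comp_i,
                      coh$truth$differential_pairs$comp_j,
                      sep = "-", collapse = ", ")))
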