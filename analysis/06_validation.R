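#!/usr/bin/env Rscript
# External narrow validation: an independent draw from the same generator
# (standing in for the second, younger sample of the cohort) is analysed
# from scratch - its own active set, its own fits - and the resulting
# differential edges are compared with the primary run's.

library(crdnet)

seed_primary <- 20260927L
seed_validation <- 20270101L

coh1 <- generate_cohort(emulate_paper_shape(seed = seed_primary))
coh2 <- generate_cohort(emulate_paper_shape(seed = seed_validation))

cfg <- pipeline_config(seed = seed_primary, jdinac_T = 25,
                       cv_repetitions = 10, cv_folds = 10)
primary_dir <- "results/pipeline_primary"
run <- run_pipeline(coh1$crd, coh1$outcomes, cfg, primary_dir)

val <- validate_pipeline(primary_dir, coh2$crd, coh2$outcomes,
                         pipeline_config(seed = seed_validation, jdinac_T = 25,
                                         cv_repetitions = 10, cv_folds = 10),
                         "results/pipeline_validation")

message(sprintf("primary: %d active components, %d differential edges",
                run$summary$p_after, run$summary$n_differential_edges))
message(sprintf("validation: %d active components, %d differential edges",
                val$run$summary$p_after, val$run$summary$n_differential_edges))
message(sprintf("edge overlap (Jaccard): %.2f", val$edge_jaccard))
message("shared edges: ",
        paste(intersect(val$frozen_edges, val$validation_edges), collapse = ", "))
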