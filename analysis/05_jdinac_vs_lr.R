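#!/usr/bin/env Rscript
# JDINAC vs penalised logistic regression on the filtered cohort, plus the
# differential network of pairwise sIgE interactions. Both models are
# class-weighted and L1-penalised; evaluation uses stratified outer
# cross-validation on averaged probabilities.

library(crdnet)

crd <- read_crd("results/filtered/isu_active.csv")
outcomes <- read_outcomes("results/data/outcomes.csv")
x <- log1p(unclass(crd))
y <- outcomes$asthma[match(rownames(x), outcomes$participant_id)]

seed <- 20260927L
lr <- repeated_cv_evaluate(penalised_lr_spec(), x, y,
                           folds = 5, repetitions = 1, seed = seed)
jd_cv <- suppressWarnings(
  repeated_cv_evaluate(jdinac_spec(T = 10), x, y,
                       folds = 5, repetitions = 1, seed = seed))

fit <- jdinac_fit(x, y, T = 25, seed = seed)
net <- extract_network(fit, min_fraction = 0.25)

dir.create("results/jdinac", recursive = TRUE, showWarnings = FALSE)
write_jdinac_outputs(net, fit, "results/jdinac")
cmp <- compare_models(lr, jd_cv)
write.csv(cmp, "results/jdinac/model_comparison.csv", row.names = FALSE)
write.csv(lr$roc, "results/jdinac/roc_lr.csv", row.names = FALSE)
write.csv(jd_cv$roc, "results/jdinac/roc_jdinac.csv", row.names = FALSE)

print(lr)
print(jd_cv)
message(sprintf("differential network: %d pairs at >= 25%% inclusion", nrow(net)))
if (nrow(net) > 0) {
  for (i in seq_len(nrow(net))) {
    message(sprintf("  %s - %s: weight %d/%d (%s)",
                    net$comp_i[i], net$comp_j[i], net$differential_weight[i],
                    fit$n_models, net$direction[i]))
  }
}
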