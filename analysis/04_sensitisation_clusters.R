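#!/usr/bin/env Rscript
# Sensitisation clusters: Ward (D2) on Jaccard distances between binary
# profiles, number of clusters by the Calinski-Harabasz criterion, then
# chi-squared / odds-ratio / Kruskal-Wallis associations with asthma.

library(crdnet)

profile <- read_crd("results/filtered/profile_active.csv")
profile <- dichotomise(profile, threshold = 0.5)      # back to 0/1 integer
outcomes <- read_outcomes("results/data/outcomes.csv")

wc <- ward_cluster(jaccard_matrix(profile), k_range = 2:8)
sel <- select_k_calinski_harabasz(profile, wc)
assoc <- associate_outcomes(sel$labels, outcomes)

dir.create("results/subjects", recursive = TRUE, showWarnings = FALSE)
write.csv(data.frame(participant_id = names(sel$labels),
                     cluster_id = unname(sel$labels)),
          "results/subjects/subject_clusters.csv", row.names = FALSE)
jsonlite::write_json(
  list(k = sel$k, ch_trace = as.list(sel$trace)),
  "results/subjects/ch_selection.json", auto_unbox = TRUE, pretty = TRUE)

message(sprintf("Calinski-Harabasz selects k = %d (trace: %s)",
                sel$k, paste(sprintf("%s=%.1f", names(sel$trace), sel$trace),
                             collapse = ", ")))
ast <- assoc$binary$asthma
message(sprintf("asthma vs cluster: chi-squared %.2f, p = %.3g",
                ast$chisq$statistic, ast$chisq$p))
for (nm in names(ast$odds_ratios)) {
  or <- ast$odds_ratios[[nm]]
  message(sprintf("  %s: OR %.2f (95%% CI %.2f-%.2f)",
                  nm, or$or, or$ci_low, or$ci_high))
}
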