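#!/usr/bin/env Rscript
# Dichotomise at 0.30 ISU and keep active components (positive in >= 5% of
# children) and sensitised participants (>= 1 active positive).

library(crdnet)

crd <- read_crd("results/data/isu_matrix.csv")
flt <- filter_active(dichotomise(crd, threshold = 0.30), m = crd,
                     min_prevalence = 0.05)

dir.create("results/filtered", recursive = TRUE, showWarnings = FALSE)
write_crd(flt$crd, "results/filtered/isu_active.csv")
write_crd(flt$profile, "results/filtered/profile_active.csv")
write_filter_report(flt, "results/filtered/filter_report.json")

rep <- flt$report
message(sprintf("%d/%d components active; %d/%d (%.1f%%) children sensitised",
                rep$p_after, rep$p_before, rep$n_after, rep$n_before,
                100 * rep$n_after / rep$n_before))
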