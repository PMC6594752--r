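#!/usr/bin/env Rscript
# Step 05 — TE activation calls, superfamily enrichment, H1 repression,
# TSS methylation heatmap and the Group I-IV mechanistic classification,
# scored against the planted truth table.

source("analysis/00_common.R")

b <- load_bundle()
cfg <- default_thresholds()
tes <- b$elements[kind == "TE"]

activated <- call_activated_tes(b$expr_te_pollen_leaf, cfg$activation_fc, cfg$de_p)
act_tes <- tes[id %in% activated]
enr <- superfamily_enrichment(activated, tes)
fwrite(enr, file.path(RESULTS_DIR, "05_superfamily_enrichment.tsv"), sep = "\t")

dme <- call_dme_targets(b$sperm, b$vc, cfg)
hyper <- call_h1_hyperdmrs(b$h1_vc, b$vc, cfg)
calls <- build_element_calls(act_tes, b$expr_te_h1, dme, hyper, b$h1_vc, b$vc, cfg)
cls <- classify_groups(calls)
hm <- tss_methylation_heatmap(act_tes[id %in% cls[h1_repressed == TRUE, id]],
                              b$h1_vc, b$vc)
fwrite(cls, file.path(RESULTS_DIR, "05_element_calls.tsv"), sep = "\t")
fwrite(hm, file.path(RESULTS_DIR, "05_tss_heatmap_h1_repressed.tsv"), sep = "\t")

truth <- b$truth_tes[match(cls$id, id)]
confusion <- table(planted = truth$group, called = cls$group)
acc <- mean(cls$group == truth$group)
prox <- proximity_flags(act_tes, dme, cfg$tss_proximity_bp)

summary_tab <- data.table(
  quantity = c("n_te", "n_activated", "n_h1_repressed",
               "activated_with_dme_within_500bp", "activated_with_dme_at_tss",
               "h1_repressed_hypermethylated", "group_recovery_fraction"),
  value = c(nrow(tes), length(activated), sum(cls$h1_repressed),
            sum(prox$within), sum(prox$overlap), sum(hm$hypermeth), acc))
fwrite(summary_tab, file.path(RESULTS_DIR, "05_classification_summary.tsv"), sep = "\t")
write_manifest("05_classify_tes", bundle_files(),
               settings = cfg[c("activation_fc", "de_fc", "de_p",
                                "tss_proximity_bp", "heatmap_diff", "heatmap_p")])

cat(length(activated), "of", nrow(tes), "TEs are pollen-activated;",
    sum(cls$h1_repressed), "of those are repressed by VC-expressed H1.\n")
cat(sum(prox$within), "of", nrow(act_tes),
    "activated TEs have a DME target within 500 bp of the TSS;",
    sum(prox$overlap), "overlap one at the TSS.\n\n")
cat("Superfamily enrichment among activated TEs (top rows):\n")
print(head(enr, 3))
cat("\nPlanted vs called mechanistic groups:\n")
print(confusion)
cat("\nGroup recovery:", round(acc, 4), "\n")
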