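# Shared setup for the analysis drivers. Each numbered script is a thin
# narrative over the package: 01 simulates the study-condition bundle,
# 02-05 analyse it. Large intermediates live under scratch/ (not part of the
# deliverable); small result tables go to results/.

suppressPackageStartupMessages({
  library(vcdme)
  library(data.table)
  library(jsonlite)
})

SIM_SEED <- 20260101L
SIM_DIR <- "scratch/sim_bundle"
RESULTS_DIR <- "results"
dir.create(SIM_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

# every driver writes a manifest next to its outputs: resolved settings,
# input digests, package version, seed
write_manifest <- function(step, inputs = character(), settings = list()) {
  manifest <- list(
    step = step,
    package_version = as.character(utils::packageVersion("vcdme")),
    seed = SIM_SEED,
    settings = settings,
    input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  write_json(manifest, file.path(RESULTS_DIR, paste0(step, "_manifest.json")),
             auto_unbox = TRUE, pretty = TRUE)
}

# the bundle is regenerated deterministically when a later driver is run
# before 01 (same seed -> byte-identical inputs)
load_bundle <- function() {
  if (!file.exists(file.path(SIM_DIR, "sperm.cx.tsv"))) {
    message("bundle not on disk yet; simulating (seed ", SIM_SEED, ")")
    write_sim_bundle(simulate_bundle(sim_config(seed = SIM_SEED)), SIM_DIR)
  }
  cl <- NULL
  list(
    sperm = read_cytosine_report(file.path(SIM_DIR, "sperm.cx.tsv"), "sperm", cl),
    vc = read_cytosine_report(file.path(SIM_DIR, "vc.cx.tsv"), "VC", cl),
    h1_vc = read_cytosine_report(file.path(SIM_DIR, "h1_vc.cx.tsv"), "pVC_H1_VC", cl),
    leaf = read_cytosine_report(file.path(SIM_DIR, "leaf.cx.tsv"), "leaf", cl),
    elements = read_annotation(file.path(SIM_DIR, "elements.gff3")),
    h3k9me2 = read_score_track(file.path(SIM_DIR, "h3k9me2.bedGraph")),
    expr_te_pollen_leaf = read_expression(file.path(SIM_DIR, "expr_te_pollen_leaf.tsv")),
    expr_te_h1 = read_expression(file.path(SIM_DIR, "expr_te_h1.tsv")),
    expr_gene = read_expression(file.path(SIM_DIR, "expr_gene.tsv")),
    truth_sites = fread(file.path(SIM_DIR, "truth_sites.tsv")),
    truth_tes = fread(file.path(SIM_DIR, "truth_tes.tsv")))
}

bundle_files <- function() {
  list.files(SIM_DIR, full.names = TRUE)
}
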